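#' Prediction-ellipse scale factor
#'
#' Small-sample scale factor for a bivariate prediction ellipse at the
#' given coverage: `k = 2 (n + 1)(n - 1) / (n (n - 2)) * F(coverage; 2, n - 2)`.
#' For n in the thousands this is within 0.1% of the chi-square factor
#' `qchisq(coverage, 2)`.
#'
#' @param n sample count (> 2).
#' @param coverage coverage probability, default 0.95.
#' @return Dimensionless scale factor applied to the sample covariance.
#' @export
pea_scale_factor <- function(n, coverage = 0.95) {
  if (n <= 2) stop("pea_scale_factor: need n > 2", call. = FALSE)
  2 * (n + 1) * (n - 1) / (n * (n - 2)) * stats::qf(coverage, 2, n - 2)
}

#' 95% prediction ellipse area of a CoP trace
#'
#' Fits the prediction ellipse expected to contain a future CoP
#' observation with probability `coverage`, assuming bivariate normality:
#' the ellipse is centred at the sample mean, oriented along the
#' eigenvectors of the sample covariance S, with squared semi-axes
#' `k * eigenvalues(S)` and area `pi * k * sqrt(det(S))`.
#'
#' @param trace a [cop_trace()], or any list with numeric `x` and `y`.
#' @param coverage coverage probability in (0, 1); default 0.95.
#' @return An object of class `pea_result`: list with `area` (cm^2),
#'   `center`, `semi_axes` (a >= b, cm), `orientation` (radians, major
#'   axis), `n`, `scale_factor`, `coverage`.
#' @export
compute_pea <- function(trace, coverage = 0.95) {
  x <- trace$x; y <- trace$y
  n <- length(x)
  if (n < 3) stop("compute_pea: need at least 3 samples", call. = FALSE)
  if (coverage <= 0 || coverage >= 1)
    stop("compute_pea: coverage must be in (0, 1)", call. = FALSE)
  S <- stats::cov(cbind(x, y))
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(detS) || detS <= 0 || S[1, 1] <= 0 || S[2, 2] <= 0)
    stop("compute_pea: degenerate trace (singular covariance)", call. = FALSE)
  k <- pea_scale_factor(n, coverage)
  e <- eigen(S, symmetric = TRUE)
  semi <- sqrt(k * e$values)            # a >= b: eigen() sorts decreasing
  structure(list(
    area = pi * k * sqrt(detS),
    center = c(mean(x), mean(y)),
    semi_axes = semi,
    orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
    n = n,
    scale_factor = k,
    coverage = coverage), class = "pea_result")
}

#' @export
print.pea_result <- function(x, ...) {
  cat(sprintf("<pea_result> area %.3f cm^2 (%.0f%% coverage, n = %d)\n",
              x$area, 100 * x$coverage, x$n))
  invisible(x)
}

#' Fraction of trace samples inside a fitted prediction ellipse
#'
#' Brute-force point-in-ellipse count; mainly a diagnostic that the
#' nominal coverage is honoured.
#'
#' @param trace the [cop_trace()] (or any x/y list).
#' @param pea a `pea_result` from [compute_pea()].
#' @return Fraction in [0, 1].
#' @export
pea_containment <- function(trace, pea) {
  xy <- cbind(trace$x - pea$center[1], trace$y - pea$center[2])
  th <- pea$orientation
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)  # columns: major, minor
  uv <- xy %*% R
  mean((uv[, 1] / pea$semi_axes[1])^2 + (uv[, 2] / pea$semi_axes[2])^2 <= 1)
}

#' Mean sway area across trials
#'
#' The dependent variable per stance and vision condition is the mean of
#' the per-trial prediction-ellipse areas (three 30 s trials per stance).
#'
#' @param trials list of `pea_result` objects, or a numeric vector of
#'   areas in cm^2.
#' @return Mean area in cm^2.
#' @export
mean_pea <- function(trials) {
  if (length(trials) == 0L)
    stop("mean_pea: need at least one trial", call. = FALSE)
  areas <- if (is.numeric(trials)) trials
           else vapply(trials, function(p) p$area, numeric(1))
  mean(areas)
}
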