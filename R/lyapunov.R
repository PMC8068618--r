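#' Largest Lyapunov exponent by Rosenstein's algorithm
#'
#' For every state vector the nearest neighbour outside a Theiler window is
#' located; the mean log distance between the pair after k steps forms the
#' divergence curve, and the largest Lyapunov exponent is the least-squares
#' slope of that curve over `fit_range`, scaled to the requested time unit.
#' Pairs whose trajectory leaves the series are dropped from the mean at
#' that step (Rosenstein's convention).
#'
#' @param states state matrix (rows = delay-embedded vectors), e.g. from
#'   [delay_embed()].
#' @param fs_effective samples per time unit in which the exponent is to be
#'   expressed: 100 for stride-normalized gait data gives the exponent per
#'   stride; 1 gives it per sample/iteration.
#' @param theiler Theiler window in samples (temporal exclusion around each
#'   vector in the neighbour search).
#' @param fit_range integer vector `c(first, last)` of divergence-curve
#'   steps used for the slope fit (0 = the initial separation).
#' @param max_steps how far to follow each pair; defaults to
#'   `max(fit_range)`.
#' @return An object of class `lle_result`: list with `lle` (slope per time
#'   unit), `slope_per_step`, `divergence_curve` (data.frame `step`,
#'   `mean_log_dist`, `n_pairs`), `fit_range`, `n_state_vectors`,
#'   `embedding` (tau/d attributes when present).
#' @export
rosenstein_lle <- function(states, fs_effective = 1, theiler = 0,
                           fit_range = c(0, 50), max_steps = max(fit_range)) {
  states <- as.matrix(states)
  n <- nrow(states)
  if (n < 100L) stop("rosenstein_lle: too few state vectors", call. = FALSE)
  theiler <- as.integer(theiler)
  spread <- stats::sd(as.vector(states))
  if (!is.finite(spread) || spread == 0)
    stop("rosenstein_lle: no valid neighbour pairs (degenerate states)", call. = FALSE)
  nn <- nearest_neighbors(states, theiler = theiler)
  i <- seq_len(n); j <- nn$index
  valid <- is.finite(nn$dist)
  if (!any(valid)) stop("rosenstein_lle: no valid neighbour pairs", call. = FALSE)
  i <- i[valid]; j <- j[valid]
  # exact recurrences (periodic signals) get a tiny distance floor so the
  # divergence curve is defined and flat instead of undefined
  d_floor <- 1e-12 * spread
  steps <- 0:max_steps
  mean_log <- numeric(length(steps))
  n_pairs <- integer(length(steps))
  for (s in seq_along(steps)) {
    k <- steps[s]
    ok <- (i + k <= n) & (j + k <= n)
    if (!any(ok)) { mean_log[s] <- NA_real_; n_pairs[s] <- 0L; next }
    d <- sqrt(rowSums((states[i[ok] + k, , drop = FALSE] -
                       states[j[ok] + k, , drop = FALSE])^2))
    d <- pmax(d, d_floor)
    n_pairs[s] <- length(d)
    mean_log[s] <- mean(log(d))
  }
  lo <- fit_range[1]; hi <- fit_range[2]
  sel <- steps >= lo & steps <= hi & is.finite(mean_log)
  if (sum(sel) < 2L) stop("rosenstein_lle: fit range too short", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, steps[sel]), mean_log[sel])
  slope <- fit$coefficients[2]
  structure(list(
    lle = unname(slope * fs_effective),
    slope_per_step = unname(slope),
    divergence_curve = data.frame(step = steps, mean_log_dist = mean_log,
                                  n_pairs = n_pairs),
    fit_range = c(lo, hi),
    n_state_vectors = n,
    embedding = list(tau = attr(states, "tau"),
                     d_per_channel = attr(states, "d_per_channel"),
                     channels = attr(states, "channels"),
                     total_dim = ncol(states))), class = "lle_result")
}

#' @export
print.lle_result <- function(x, ...) {
  cat(sprintf("<lle_result> lle = %.4f (fit steps %d-%d, %d state vectors, dim %d)\n",
              x$lle, x$fit_range[1], x$fit_range[2], x$n_state_vectors,
              x$embedding$total_dim))
  invisible(x)
}

#' Logistic-map series (chaos oracle)
#'
#' Iterates x <- r x (1 - x). At r = 4 the analytic largest Lyapunov
#' exponent is ln 2 per iteration, making this the standard closed-form
#' check for Lyapunov estimators.
#'
#' @param n length of the returned series.
#' @param r map parameter (default 4).
#' @param x0 initial value in (0, 1).
#' @param burn iterations discarded before recording.
#' @return Numeric series of length `n`.
#' @export
logistic_map <- function(n, r = 4, x0 = 0.2, burn = 100) {
  x <- x0
  for (b in seq_len(burn)) x <- r * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) { out[i] <- x; x <- r * x * (1 - x) }
  out
}

#' Lorenz-system trajectory (chaos oracle)
#'
#' Integrates the Lorenz equations (sigma = 10, rho = 28, beta = 8/3) with
#' a fixed-step RK4 integrator; the literature largest Lyapunov exponent
#' for these parameters is about 0.9 nats per time unit.
#'
#' @param n number of recorded points.
#' @param dt integration/recording step (default 0.01).
#' @param burn transient time units discarded.
#' @param state0 initial state.
#' @return Matrix n x 3 (columns x, y, z).
#' @export
lorenz_series <- function(n, dt = 0.01, burn = 20,
                          state0 = c(x = 1, y = 1, z = 1)) {
  f <- function(t, s, p) {
    list(c(10 * (s[2] - s[1]),
           s[1] * (28 - s[3]) - s[2],
           s[1] * s[2] - 8 / 3 * s[3]))
  }
  times <- seq(0, burn + n * dt, by = dt)
  out <- deSolve::ode(y = state0, times = times, func = f, parms = NULL,
                      method = "rk4")
  keep <- out[, 1] > burn - dt / 2
  m <- out[keep, 2:4, drop = FALSE]
  m[seq_len(n), , drop = FALSE]
}
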