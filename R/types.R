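#' Construct a center-of-pressure trace
#'
#' A `cop_trace` holds the 2-D center-of-pressure (CoP) trajectory recorded
#' on a force plate: medial-lateral (`x`) and anterior-posterior (`y`)
#' displacement in cm, sampled at `fs` Hz.
#'
#' @param t numeric vector of time stamps in seconds, strictly increasing.
#' @param x numeric vector, medial-lateral CoP displacement (cm).
#' @param y numeric vector, anterior-posterior CoP displacement (cm).
#' @param fs sampling rate in Hz (default 180, the force-plate rate).
#' @return An object of class `cop_trace`: a list with fields `t`, `x`,
#'   `y`, `fs`.
#' @export
cop_trace <- function(t, x, y, fs = 180) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 2L || length(t) != length(x) || length(t) != length(y))
    stop("cop_trace: t, x, y must have equal length >= 2", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("cop_trace: fs must be a positive scalar", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("cop_trace: t must be strictly increasing", call. = FALSE)
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("cop_trace: NA values not allowed", call. = FALSE)
  structure(list(t = t, x = x, y = y, fs = fs), class = "cop_trace")
}

#' @export
print.cop_trace <- function(x, ...) {
  cat(sprintf("<cop_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$t), x$fs, x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' Construct a foot angular-velocity trace
#'
#' A `gyro_trace` holds a 3-axis angular-velocity signal (rad/s) from a
#' foot-mounted inertial sensor, together with hallway-bout annotations
#' (half-open index ranges, each one 25 m pass) and a per-sample exclusion
#' mask flagging non-stationary segments.
#'
#' @param t numeric time stamps (s).
#' @param w numeric matrix, one row per sample, 3 columns (rad/s).
#' @param fs sampling rate in Hz (default 100, the IMU rate).
#' @param bouts two-column integer matrix of half-open `[start, end)`
#'   sample-index ranges (1-based start, exclusive end), non-overlapping and
#'   ordered; defaults to a single bout spanning the whole trace.
#' @param exclusion_mask logical vector, `TRUE` marks samples to discard.
#' @return An object of class `gyro_trace`.
#' @export
gyro_trace <- function(t, w, fs = 100, bouts = NULL, exclusion_mask = NULL) {
  t <- as.numeric(t)
  w <- as.matrix(w)
  n <- length(t)
  if (nrow(w) != n || ncol(w) != 3L)
    stop("gyro_trace: w must be an n x 3 matrix matching t", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("gyro_trace: fs must be > 0", call. = FALSE)
  if (is.null(bouts)) bouts <- matrix(c(1L, n + 1L), nrow = 1L)
  bouts <- matrix(as.integer(bouts), ncol = 2L)
  if (any(bouts[, 2] <= bouts[, 1]))
    stop("gyro_trace: each bout must satisfy start < end", call. = FALSE)
  if (nrow(bouts) > 1L) {
    o <- order(bouts[, 1])
    bouts <- bouts[o, , drop = FALSE]
    if (any(bouts[-1L, 1] < bouts[-nrow(bouts), 2]))
      stop("gyro_trace: bouts must be non-overlapping and ordered", call. = FALSE)
  }
  if (is.null(exclusion_mask)) exclusion_mask <- rep(FALSE, n)
  if (length(exclusion_mask) != n)
    stop("gyro_trace: exclusion_mask length must match t", call. = FALSE)
  structure(list(t = t, w = w, fs = fs, bouts = bouts,
                 exclusion_mask = as.logical(exclusion_mask)),
            class = "gyro_trace")
}

#' @export
print.gyro_trace <- function(x, ...) {
  cat(sprintf("<gyro_trace> %d samples @ %g Hz, %d bout(s), %d masked\n",
              length(x$t), x$fs, nrow(x$bouts), sum(x$exclusion_mask)))
  invisible(x)
}

#' Construct a triangle-completion trial
#'
#' Participants are guided along two legs of a triangle (A -> B -> C) and
#' must return unaided to the origin A; `P` is where they stopped. All
#' coordinates in cm.
#'
#' @param A,B,C 2-vectors, the triangle vertices (guided path A->B->C).
#' @param P 2-vector, the participant's stopping point.
#' @param direction `"clockwise"` or `"counterclockwise"` presentation.
#' @param triangle_id 1 (equilateral) or 2 (30-60-90 right triangle).
#' @return An object of class `triangle_trial`.
#' @export
triangle_trial <- function(A, B, C, P,
                           direction = c("clockwise", "counterclockwise"),
                           triangle_id = 1L) {
  direction <- match.arg(direction)
  A <- as.numeric(A); B <- as.numeric(B); C <- as.numeric(C); P <- as.numeric(P)
  for (v in list(A, B, C, P))
    if (length(v) != 2L || anyNA(v)) stop("triangle_trial: points must be finite 2-vectors", call. = FALSE)
  cross <- (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])
  if (abs(cross) < 1e-9)
    stop("triangle_trial: A, B, C are collinear", call. = FALSE)
  structure(list(A = A, B = B, C = C, P = P, direction = direction,
                 triangle_id = as.integer(triangle_id)),
            class = "triangle_trial")
}
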