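# Signed planar angle from vector u to vector v, degrees in (-180, 180].
signed_angle_deg <- function(u, v) {
  a <- atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2]) * 180 / pi
  if (a <= -180) a <- a + 360
  a
}

#' Score a triangle-completion trial
#'
#' The participant walks A -> B -> C guided, then turns at C and walks
#' unaided toward where they believe A is, stopping at P. Two error
#' components are scored at the turning point C:
#' * angle (turn) error: the signed difference between the produced turn
#'   (heading B->C to heading C->P) and the correct turn (heading B->C to
#'   heading C->A), wrapped to (-180, 180];
#' * distance (path-length) error: walked length |C->P| minus the correct
#'   homing length |C->A| (negative = underestimated path).
#' The Euclidean miss distance |P - A| is reported as an auxiliary metric.
#'
#' @param trial a [triangle_trial()].
#' @return An object of class `trial_score`: list with `angle_error`
#'   (deg, absolute), `signed_angle_error`, `distance_error` (cm,
#'   absolute), `signed_distance_error`, `endpoint_miss` (cm).
#' @export
score_trial <- function(trial) {
  stopifnot(inherits(trial, "triangle_trial"))
  A <- trial$A; B <- trial$B; C <- trial$C; P <- trial$P
  if (sqrt(sum((P - C)^2)) < 1e-12)
    stop("score_trial: degenerate trial, stopping point equals turning point",
         call. = FALSE)
  inbound <- C - B
  correct <- signed_angle_deg(inbound, A - C)
  produced <- signed_angle_deg(inbound, P - C)
  sae <- produced - correct
  if (sae > 180) sae <- sae - 360
  if (sae <= -180) sae <- sae + 360
  sde <- sqrt(sum((P - C)^2)) - sqrt(sum((A - C)^2))
  structure(list(angle_error = abs(sae),
                 signed_angle_error = sae,
                 distance_error = abs(sde),
                 signed_distance_error = sde,
                 endpoint_miss = sqrt(sum((P - A)^2))), class = "trial_score")
}

#' Mean errors across triangle-completion trials
#'
#' @param scores list of `trial_score` objects (study design: 4 trials,
#'   the two triangles once clockwise and once counterclockwise).
#' @return Named vector `c(mean_angle_error = , mean_distance_error = )`
#'   in degrees and cm (absolute errors).
#' @export
summarize_trials <- function(scores) {
  if (length(scores) == 0L)
    stop("summarize_trials: need at least one scored trial", call. = FALSE)
  c(mean_angle_error = mean(vapply(scores, `[[`, numeric(1), "angle_error")),
    mean_distance_error = mean(vapply(scores, `[[`, numeric(1), "distance_error")))
}

#' The two study triangles
#'
#' Triangle 1 is equilateral with 300 cm sides (interior angles 60 deg);
#' triangle 2 is the 30-60-90 right triangle with a 300 cm hypotenuse
#' (legs 150 and 150*sqrt(3) cm). All segments fall in the 150-300 cm
#' design range; sizes are set at the range maximum and are configurable
#' via `scale`.
#'
#' @param scale multiplier on the default dimensions (default 1).
#' @return List of two lists, each with vertices `A`, `B`, `C` (cm) and
#'   `angles` (interior angles at A, B, C in degrees).
#' @export
reference_triangles <- function(scale = 1) {
  eq <- list(A = c(0, 0), B = c(300, 0), C = c(150, 150 * sqrt(3)),
             angles = c(60, 60, 60))
  rt <- list(A = c(0, 0), B = c(150 * sqrt(3), 0), C = c(150 * sqrt(3), 150),
             angles = c(30, 90, 60))
  lapply(list(triangle1 = eq, triangle2 = rt), function(tr) {
    tr$A <- tr$A * scale; tr$B <- tr$B * scale; tr$C <- tr$C * scale
    tr
  })
}
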