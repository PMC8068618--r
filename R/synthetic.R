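#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the study's measurement battery: 14 participants
#' per group (blind/visually-impaired vs. sighted), a latent weekly
#' "exercise" factor per participant (lognormal), dv-level loadings that
#' map the latent factor onto each outcome's mean (negative for sway
#' area, stride-time sd, Lyapunov exponent and navigation errors —
#' more exercise, better performance — positive for single-leg stance
#' time), group offsets reproducing the direction of the reported group
#' differences, and trace-level parameters for the raw signals
#' (Ornstein-Uhlenbeck CoP, templated gait, noisy triangle homing).
#'
#' @param n_per_group participants per group (default 14, the study size).
#' @param exercise_meanlog,exercise_sdlog lognormal parameters of the
#'   latent exercise factor (min/week); `exercise_meanlog` is a named
#'   vector per group — sighted children report about 160 min/week more
#'   activity.
#' @param loadings named vector: change in each dv per doubling of
#'   exercise minutes (dv units).
#' @param group_offset named vector: BVI-minus-sighted shift of each dv.
#' @param baseline named vector: sighted-group dv means at the median
#'   exercise level.
#' @param noise_sd named vector: residual sd per dv.
#' @param cop named list `theta`, `sigma` (OU parameters), `duration_s`,
#'   `fs`.
#' @param gait named list `stride_time_mean`, `stride_time_sd`,
#'   `noise_sd`, `n_strides`, `fs`, `n_bouts`.
#' @param triangle named list `turn_bias_deg`, `turn_sd_deg`, `dist_gain`,
#'   `dist_sd_frac`.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(
    n_per_group = 14,
    exercise_meanlog = c(BVI = log(240), sighted = log(400)),
    exercise_sdlog = 0.6,
    loadings = c(pea = -3.0, sls_time = 3.5, stride_time_sd = -0.012,
                 lle = -0.45, angle_error = -6, distance_error = -20),
    group_offset = c(pea = 7.0, sls_time = -5.6, stride_time_sd = 0.003,
                     lle = 0.3, angle_error = 5, distance_error = 2),
    baseline = c(pea = 10, sls_time = 12, stride_time_sd = 0.030,
                 lle = 2.0, angle_error = 25, distance_error = 60),
    noise_sd = c(pea = 4, sls_time = 4, stride_time_sd = 0.010,
                 lle = 0.5, angle_error = 10, distance_error = 30),
    cop = list(theta = 1.0, sigma = 1.5, duration_s = 30, fs = 180),
    gait = list(stride_time_mean = 1.1, stride_time_sd = 0.030,
                noise_sd = 0.05, n_strides = 70, fs = 100, n_bouts = 1),
    triangle = list(turn_bias_deg = 5, turn_sd_deg = 12, dist_gain = 0.9,
                    dist_sd_frac = 0.15)) {
  if (n_per_group < 2) stop("synth_config: n_per_group must be >= 2", call. = FALSE)
  stopifnot(all(noise_sd > 0), exercise_sdlog > 0)
  structure(list(n_per_group = n_per_group,
                 exercise_meanlog = exercise_meanlog,
                 exercise_sdlog = exercise_sdlog,
                 loadings = loadings, group_offset = group_offset,
                 baseline = baseline, noise_sd = noise_sd,
                 cop = cop, gait = gait, triangle = triangle),
            class = "synth_config")
}

#' Simulate a center-of-pressure trace (Ornstein-Uhlenbeck)
#'
#' Two independent OU processes (one per axis) with exact discretization:
#' `x[k+1] = x[k] exp(-theta dt) + sigma sqrt((1 - exp(-2 theta dt)) /
#' (2 theta)) eps`. The stationary marginal sd per axis is
#' `sigma / sqrt(2 theta)`, so the long-run 95% prediction ellipse area is
#' `pi * qchisq(0.95, 2) * sigma^2 / (2 theta)`.
#'
#' @param theta mean-reversion rate (1/s), > 0.
#' @param sigma diffusion scale (cm / sqrt(s)), > 0.
#' @param duration_s trial length in seconds (default 30).
#' @param fs sampling rate in Hz (default 180).
#' @param seed optional integer seed.
#' @return A [cop_trace()] with `duration_s * fs` samples.
#' @export
gen_cop <- function(theta, sigma, duration_s = 30, fs = 180, seed = NULL) {
  if (theta <= 0 || sigma < 0) stop("gen_cop: need theta > 0, sigma >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  dt <- 1 / fs
  a <- exp(-theta * dt)
  s_step <- sigma * sqrt((1 - a^2) / (2 * theta))
  s_stat <- sigma / sqrt(2 * theta)
  xy <- matrix(0, n, 2)
  xy[1, ] <- stats::rnorm(2, 0, s_stat)   # start at stationarity
  eps <- matrix(stats::rnorm(2 * (n - 1), 0, s_step), n - 1, 2)
  for (k in 2:n) xy[k, ] <- a * xy[k - 1, ] + eps[k - 1, ]
  cop_trace(t = (seq_len(n) - 1) * dt, x = xy[, 1], y = xy[, 2], fs = fs)
}

# Default 3-channel stride template (100 samples): a dominant sagittal
# swing peak just after the stride boundary (5% into the stride, wrapped
# so concatenation is near-continuous), a mid-stance dip, and smaller
# frontal/transverse components. Keeping the segmentation peak at the
# stride boundary means peak-to-peak intervals track the stride times.
default_stride_template <- function(samples = 100) {
  u <- seq(0, 1, length.out = samples)
  sag <- 4.5 * (exp(-((u - 0.05) / 0.08)^2) + exp(-((u - 1.05) / 0.08)^2)) -
    1.2 * exp(-((u - 0.55) / 0.12)^2) + 0.5 * sin(2 * pi * u)
  fro <- 0.8 * sin(2 * pi * u) + 0.3 * sin(4 * pi * u)
  tra <- 0.6 * sin(2 * pi * u + pi / 4) + 0.2 * cos(6 * pi * u)
  cbind(sag, fro, tra)
}

#' Simulate a foot gyroscope walking trace
#'
#' Draws iid Gaussian stride times (truncated at 0.3 s), time-warps a
#' 3-channel stride template to each stride, concatenates, and adds white
#' amplitude noise. Bout annotations are synthesized by splitting the
#' trace into `n_bouts` equal index ranges. Ground-truth stride-start
#' sample indices and stride times are returned.
#'
#' @param stride_template matrix samples x 3 (default
#'   `default_stride_template()`).
#' @param n_strides number of strides (>= 2).
#' @param stride_time_mean,stride_time_sd stride-duration distribution (s).
#' @param noise_sd additive white-noise sd (rad/s).
#' @param fs sampling rate (Hz, default 100).
#' @param n_bouts bout annotations to synthesize (default 1).
#' @param seed optional integer seed.
#' @return List with `trace` (a [gyro_trace()]) and `truth` (list
#'   `event_indices`, `stride_times`).
#' @export
gen_gait <- function(stride_template = default_stride_template(),
                     n_strides = 70, stride_time_mean = 1.1,
                     stride_time_sd = 0.03, noise_sd = 0.05, fs = 100,
                     n_bouts = 1, seed = NULL) {
  if (n_strides < 2) stop("gen_gait: need n_strides >= 2", call. = FALSE)
  if (stride_time_mean <= 0.3) stop("gen_gait: stride_time_mean too small", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  durations <- stats::rnorm(n_strides, stride_time_mean, stride_time_sd)
  durations <- pmax(durations, 0.3)
  ns <- pmax(2L, round(durations * fs))
  u_t <- seq(0, 1, length.out = nrow(stride_template))
  segs <- vector("list", n_strides)
  for (k in seq_len(n_strides)) {
    grid <- seq(0, 1, length.out = ns[k] + 1L)[seq_len(ns[k])]
    segs[[k]] <- apply(stride_template, 2, function(ch)
      stats::approx(u_t, ch, xout = grid)$y)
  }
  w <- do.call(rbind, segs)
  if (noise_sd > 0) w <- w + matrix(stats::rnorm(length(w), 0, noise_sd),
                                    nrow(w), ncol(w))
  n <- nrow(w)
  events <- cumsum(c(1L, ns[-n_strides]))
  bounds <- unique(round(seq(1L, n + 1L, length.out = n_bouts + 1L)))
  bouts <- cbind(bounds[-length(bounds)], bounds[-1L])
  list(trace = gyro_trace(t = (seq_len(n) - 1) / fs, w = w, fs = fs,
                          bouts = bouts),
       truth = list(event_indices = events, stride_times = ns / fs,
                    drawn_stride_times = durations))
}

#' Simulate triangle-completion trials
#'
#' For each of the four study trials (the two reference triangles, once
#' clockwise and once counterclockwise) the produced turn at C is the
#' correct turn plus a bias and Gaussian noise, and the produced homing
#' length is the correct length times `dist_gain` with multiplicative
#' Gaussian noise; the stopping point P follows from C.
#'
#' @param turn_bias_deg systematic turn error (deg).
#' @param turn_sd_deg turn noise sd (deg).
#' @param dist_gain multiplicative bias on the homing length (> 0).
#' @param dist_sd_frac fractional sd of the homing length.
#' @param n_sets how many 4-trial sets (default 1).
#' @param seed optional integer seed.
#' @return List of [triangle_trial()] objects (4 per set).
#' @export
gen_triangle_trials <- function(turn_bias_deg = 0, turn_sd_deg = 0,
                                dist_gain = 1, dist_sd_frac = 0,
                                n_sets = 1, seed = NULL) {
  if (dist_gain <= 0) stop("gen_triangle_trials: dist_gain must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tris <- reference_triangles()
  out <- list()
  for (set in seq_len(n_sets)) for (id in 1:2) for (dir in c("clockwise", "counterclockwise")) {
    tr <- tris[[id]]
    A <- tr$A; B <- tr$B; C <- tr$C
    if (dir == "counterclockwise") {  # mirror the course
      A <- c(A[1], -A[2]); B <- c(B[1], -B[2]); C <- c(C[1], -C[2])
    }
    inbound <- C - B
    correct_turn <- atan2(inbound[1] * (A - C)[2] - inbound[2] * (A - C)[1],
                          sum(inbound * (A - C))) * 180 / pi
    turn <- correct_turn + turn_bias_deg + stats::rnorm(1, 0, turn_sd_deg)
    len <- sqrt(sum((A - C)^2)) * dist_gain *
      (1 + stats::rnorm(1, 0, dist_sd_frac))
    len <- max(len, 1e-6)
    phi <- atan2(inbound[2], inbound[1]) + turn * pi / 180
    P <- C + len * c(cos(phi), sin(phi))
    out[[length(out) + 1L]] <- triangle_trial(A, B, C, P, direction = dir,
                                              triangle_id = id)
  }
  out
}

#' Implied exercise-outcome correlation of a generator configuration
#'
#' Analytic population Pearson correlation, within one group, between raw
#' exercise minutes and an outcome generated by [gen_cohort()]. The
#' outcome is linear in log2(exercise) plus Gaussian noise while the
#' correlation is taken on the raw (lognormal) minutes, so the attainable
#' magnitude is capped at `sdlog / sqrt(exp(sdlog^2) - 1)` (about 0.91 at
#' the default sdlog = 0.6). Useful for choosing loadings/noise that
#' realize a target correlation.
#'
#' @param config a [synth_config()].
#' @param dv outcome name.
#' @return Population correlation in [-1, 1].
#' @export
implied_exercise_correlation <- function(config, dv) {
  s <- config$exercise_sdlog
  a <- config$loadings[[dv]] * s / log(2)   # sd contribution of the latent term
  noise <- config$noise_sd[[dv]]
  (s / sqrt(exp(s^2) - 1)) * a / sqrt(a^2 + noise^2)
}

#' Generate a complete synthetic cohort
#'
#' Per participant: a latent exercise level is drawn (lognormal, group
#' mean lower in the BVI group), mapped through the dv loadings and group
#' offsets to outcome means, and Gaussian residual noise added. With
#' `level = "dv"` (default) the outcomes are returned directly as a
#' long-format cohort table; with `level = "trace"` raw signals (CoP
#' traces, gait traces, triangle trials) are generated per participant
#' with trace parameters steered by the latent factor, and the outcome
#' values are obtained by running the measurement pipelines — slower, but
#' exercises the whole chain.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (full determinism).
#' @param level `"dv"` or `"trace"`.
#' @return List with `cohort` (long-format table, see [build_cohort()]),
#'   `truth` (data.frame: participant, group, latent exercise, true dv
#'   means), and, for `level = "trace"`, `traces` (per-participant raw
#'   objects).
#' @export
gen_cohort <- function(config = synth_config(), seed = 1,
                       level = c("dv", "trace")) {
  level <- match.arg(level)
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_per_group
  groups <- rep(c("BVI", "sighted"), each = n)
  ids <- sprintf("%s%02d", ifelse(groups == "BVI", "b", "s"),
                 rep(seq_len(n), 2))
  match_id <- c(sprintf("s%02d", seq_len(n)), sprintf("b%02d", seq_len(n)))
  exercise <- stats::rlnorm(2 * n,
                            meanlog = config$exercise_meanlog[groups],
                            sdlog = config$exercise_sdlog)
  dvs <- names(config$loadings)
  # latent scale: log2 of exercise relative to the sighted median, so a
  # loading is "dv units per doubling of weekly exercise"
  z <- log2(exercise) - config$exercise_meanlog[["sighted"]] / log(2)
  true_mean <- sapply(dvs, function(dv)
    config$baseline[[dv]] + config$loadings[[dv]] * z +
      ifelse(groups == "BVI", config$group_offset[[dv]], 0))
  traces <- NULL
  if (level == "dv") {
    values <- true_mean + sapply(dvs, function(dv)
      stats::rnorm(2 * n, 0, config$noise_sd[[dv]]))
    values <- pmax(values, 0)   # outcomes are nonnegative quantities
  } else {
    values <- matrix(NA_real_, 2 * n, length(dvs),
                     dimnames = list(NULL, dvs))
    traces <- vector("list", 2 * n)
    for (i in seq_len(2 * n)) {
      # CoP: stationary variance scaled so the expected PEA matches the
      # participant's true mean sway area
      target_pea <- max(true_mean[i, "pea"], 0.5)
      sig2 <- target_pea / (pi * stats::qchisq(0.95, 2))  # per-axis variance
      theta <- config$cop$theta
      cop <- gen_cop(theta = theta, sigma = sqrt(sig2 * 2 * theta),
                     duration_s = config$cop$duration_s, fs = config$cop$fs)
      values[i, "pea"] <- compute_pea(cop)$area
      # gait: stride-time sd steered by the latent factor
      st_sd <- max(true_mean[i, "stride_time_sd"], 0.003)
      gg <- gen_gait(n_strides = config$gait$n_strides,
                     stride_time_mean = config$gait$stride_time_mean,
                     stride_time_sd = st_sd,
                     noise_sd = config$gait$noise_sd,
                     fs = config$gait$fs, n_bouts = config$gait$n_bouts)
      st <- stride_time_stats(detect_strides(gg$trace))
      values[i, "stride_time_sd"] <- st[["sd"]]
      values[i, "lle"] <- max(true_mean[i, "lle"] +
                                stats::rnorm(1, 0, config$noise_sd[["lle"]]), 0)
      # triangle: bias/noise steered so mean errors track the true means
      trials <- gen_triangle_trials(
        turn_bias_deg = true_mean[i, "angle_error"],
        turn_sd_deg = config$triangle$turn_sd_deg,
        dist_gain = max(1 - true_mean[i, "distance_error"] /
                          mean(c(300, 519.6)), 0.1),
        dist_sd_frac = config$triangle$dist_sd_frac)
      sc <- summarize_trials(lapply(trials, score_trial))
      values[i, "angle_error"] <- sc[["mean_angle_error"]]
      values[i, "distance_error"] <- sc[["mean_distance_error"]]
      values[i, "sls_time"] <- min(max(true_mean[i, "sls_time"] +
        stats::rnorm(1, 0, config$noise_sd[["sls_time"]]), 0), 20)
      traces[[i]] <- list(cop = cop, gait = gg, trials = trials)
    }
  }
  records <- data.frame(id = ids, group = groups, match_id = match_id,
                        condition = "eyes_closed", stringsAsFactors = FALSE)
  records$exercise <- exercise
  records$basic_activity <- stats::rlnorm(2 * n, meanlog = log(300), sdlog = 0.4)
  for (dv in dvs) records[[dv]] <- values[, dv]
  cohort <- build_cohort(records)
  truth <- data.frame(participant_id = ids, group = groups,
                      exercise = exercise, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(true_mean))
  out <- list(cohort = cohort, truth = truth)
  if (!is.null(traces)) out$traces <- traces
  out
}
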