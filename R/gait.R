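#' Apply hallway exclusion rules to a gyroscope trace
#'
#' Walking data from an out-and-back hallway protocol: the first and the
#' last full 25 m bout are discarded, the first and last 2.5 m of every
#' remaining bout are trimmed (distance is mapped linearly onto time
#' within a bout, so 2.5/25 = 10% of each bout's samples go at either
#' end), and samples flagged in the exclusion mask (non-stationary
#' segments, e.g. the participant stopped) are dropped.
#'
#' @param trace a [gyro_trace()] with at least 3 annotated bouts.
#' @param hallway_length bout length in m (default 25).
#' @param edge_trim trimmed distance at each bout end in m (default 2.5).
#' @return A new [gyro_trace()] containing only retained samples, with
#'   bout annotations remapped to the retained index space.
#' @export
apply_exclusions <- function(trace, hallway_length = 25, edge_trim = 2.5) {
  stopifnot(inherits(trace, "gyro_trace"))
  nb <- nrow(trace$bouts)
  if (nb < 3L)
    stop("apply_exclusions: need at least 3 bouts (first and last are discarded)",
         call. = FALSE)
  frac <- edge_trim / hallway_length
  keep_rows <- logical(length(trace$t))
  new_bouts <- list()
  for (b in 2:(nb - 1L)) {
    s <- trace$bouts[b, 1]; e <- trace$bouts[b, 2] - 1L  # inclusive
    len <- e - s + 1L
    trim <- floor(len * frac)
    lo <- s + trim; hi <- e - trim
    if (lo > hi) next
    keep_rows[lo:hi] <- TRUE
    new_bouts[[length(new_bouts) + 1L]] <- c(lo, hi)
  }
  keep_rows <- keep_rows & !trace$exclusion_mask
  if (!any(keep_rows))
    stop("apply_exclusions: no samples retained", call. = FALSE)
  # remap bout boundaries to the retained index space
  cum <- cumsum(keep_rows)
  bouts <- do.call(rbind, lapply(new_bouts, function(be) {
    idx <- be[1]:be[2]
    idx <- idx[keep_rows[idx]]
    if (!length(idx)) return(NULL)
    c(cum[idx[1]], cum[idx[length(idx)]] + 1L)
  }))
  gyro_trace(trace$t[keep_rows], trace$w[keep_rows, , drop = FALSE],
             fs = trace$fs, bouts = bouts,
             exclusion_mask = rep(FALSE, sum(keep_rows)))
}

#' Detect stride-start events from foot angular velocity
#'
#' Picks prominent mid-swing peaks in the sagittal-plane channel with a
#' minimum temporal separation (default 0.4 s) and a height threshold
#' expressed as a fraction of the channel's peak amplitude. Stride times
#' are the intervals between consecutive events.
#'
#' @param trace a [gyro_trace()].
#' @param channel sagittal-plane channel index (default 1).
#' @param min_separation_s minimum peak separation in seconds.
#' @param height_frac height threshold as a fraction of the signal maximum
#'   (default 0.5).
#' @return An object of class `stride_series`: list with `event_indices`,
#'   `stride_times` (s), `source_fs`.
#' @export
detect_strides <- function(trace, channel = 1, min_separation_s = 0.4,
                           height_frac = 0.5) {
  stopifnot(inherits(trace, "gyro_trace"))
  sig <- trace$w[, channel]
  rng <- max(sig) - min(sig)
  if (!is.finite(rng) || rng == 0)
    stop("detect_strides: flat signal, no strides found", call. = FALSE)
  minheight <- min(sig) + height_frac * rng
  mindist <- max(1L, round(min_separation_s * trace$fs))
  pk <- pracma::findpeaks(sig, minpeakheight = minheight,
                          minpeakdistance = mindist)
  if (is.null(pk) || nrow(pk) < 2L)
    stop("detect_strides: fewer than 2 stride events detected", call. = FALSE)
  idx <- sort(pk[, 2])
  structure(list(event_indices = idx,
                 stride_times = diff(idx) / trace$fs,
                 source_fs = trace$fs), class = "stride_series")
}

#' Stride-time mean and variability
#'
#' @param s a `stride_series` from [detect_strides()], or a numeric vector
#'   of stride times in seconds.
#' @return Named vector `c(mean = , sd = )` in seconds; sd uses the n-1
#'   denominator.
#' @export
stride_time_stats <- function(s) {
  times <- if (inherits(s, "stride_series")) s$stride_times else as.numeric(s)
  if (length(times) < 2L)
    stop("stride_time_stats: need at least 2 stride times", call. = FALSE)
  c(mean = mean(times), sd = stats::sd(times))
}

#' Time-normalize strides to a fixed sample grid
#'
#' Each of the first `n_strides` strides is linearly resampled to
#' `samples_per_stride` points per channel and the strides are
#' concatenated, yielding a series of exactly
#' `n_strides * samples_per_stride` samples per channel (6300 with the
#' defaults of 63 strides x 100 samples).
#'
#' @param trace a [gyro_trace()].
#' @param s a `stride_series` with the stride-start events.
#' @param n_strides number of strides used (default 63, the study minimum
#'   across participants and conditions).
#' @param samples_per_stride resampled points per stride (default 100).
#' @return Numeric matrix (`n_strides * samples_per_stride`) x 3.
#' @export
time_normalize_strides <- function(trace, s, n_strides = 63,
                                   samples_per_stride = 100) {
  stopifnot(inherits(trace, "gyro_trace"))
  ev <- s$event_indices
  if (length(ev) < n_strides + 1L)
    stop(sprintf("time_normalize_strides: need %d complete strides, have %d",
                 n_strides, max(0L, length(ev) - 1L)), call. = FALSE)
  out <- matrix(0, n_strides * samples_per_stride, 3L)
  for (k in seq_len(n_strides)) {
    seg <- ev[k]:ev[k + 1L]
    u <- seq(0, 1, length.out = length(seg))
    grid <- seq(0, 1, length.out = samples_per_stride + 1L)[seq_len(samples_per_stride)]
    rows <- ((k - 1L) * samples_per_stride + 1L):(k * samples_per_stride)
    for (c in 1:3)
      out[rows, c] <- stats::approx(u, trace$w[seg, c], xout = grid)$y
  }
  out
}

#' Full local-dynamic-stability gait pipeline
#'
#' Chains the gait stages: hallway exclusions (optional), stride
#' detection, time normalization of 63 strides to 6300 samples, delay
#' embedding of the three angular-velocity channels, and Rosenstein's
#' largest-Lyapunov-exponent estimate. With the fixed embedding (tau = 11,
#' 5 delays per channel) the state dimension is 15; alternatively tau and
#' dimension are selected per trace by the first AMI minimum and the FNN
#' criterion.
#'
#' @param trace a [gyro_trace()].
#' @param tau embedding delay in samples, or `"auto"` for AMI selection.
#' @param d_per_channel delayed copies per channel, or `"auto"` for FNN
#'   selection (applied to the sagittal channel, total dim = 3 x d).
#' @param n_strides,samples_per_stride passed to
#'   [time_normalize_strides()].
#' @param theiler Theiler window in samples; default one stride (100).
#' @param fit_range slope-fit range in resampled steps; default 0-50
#'   (half a stride), the short-term stability convention.
#' @param exclude apply [apply_exclusions()] first (needs bout
#'   annotations; default TRUE).
#' @param channel sagittal channel for stride detection / auto selection.
#' @return An `lle_result` (see [rosenstein_lle()]) with extra fields
#'   `stride_stats` (mean/sd of stride time) and `params_auto` (logical:
#'   were tau/d auto-selected).
#' @export
gait_lds_pipeline <- function(trace, tau = 11, d_per_channel = 5,
                              n_strides = 63, samples_per_stride = 100,
                              theiler = samples_per_stride,
                              fit_range = c(0, 50), exclude = TRUE,
                              channel = 1) {
  if (exclude) trace <- apply_exclusions(trace)
  s <- detect_strides(trace, channel = channel)
  norm <- time_normalize_strides(trace, s, n_strides, samples_per_stride)
  auto <- c(tau = identical(tau, "auto"), d = identical(d_per_channel, "auto"))
  if (auto[["tau"]])
    tau <- ami_first_minimum(norm[, channel], max_lag = samples_per_stride %/% 2)
  if (auto[["d"]])
    d_per_channel <- fnn_dimension(norm[, channel], tau = tau)
  states <- delay_embed(norm, tau = tau, d_per_channel = d_per_channel)
  res <- rosenstein_lle(states, fs_effective = samples_per_stride,
                        theiler = theiler, fit_range = fit_range)
  res$stride_stats <- stride_time_stats(s)
  res$params_auto <- auto
  res
}
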