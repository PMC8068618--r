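test_that("hallway exclusions drop edge bouts, trim 10%, honour the mask", {
  n <- 10000
  bouts <- cbind(seq(1, n, by = 1000), seq(1001, n + 1, by = 1000))
  tr <- gyro_trace(t = (0:(n - 1)) / 100, w = matrix(rnorm(3 * n), ncol = 3),
                   bouts = bouts)
  out <- apply_exclusions(tr)
  expect_identical(length(out$t), 6400L)    # 8 bouts x 800 retained
  expect_identical(nrow(out$bouts), 8L)

  # masked interior run reduces the count exactly
  tr2 <- tr
  tr2$exclusion_mask[2200:2249] <- TRUE     # inside bout 3's retained zone
  out2 <- apply_exclusions(tr2)
  expect_identical(length(out2$t), 6350L)

  few <- gyro_trace(t = (0:99) / 100, w = matrix(rnorm(300), ncol = 3),
                    bouts = cbind(c(1, 51), c(51, 101)))
  expect_error(apply_exclusions(few), "at least 3 bouts")
})

test_that("stride detection recovers generator ground truth", {
  g <- gen_gait(n_strides = 70, stride_time_mean = 1.10, stride_time_sd = 0,
                noise_sd = 0, seed = 31)
  s <- detect_strides(g$trace)
  expect_identical(length(s$event_indices), 70L)
  expect_true(all(abs(s$stride_times - 1.10) <= 1 / g$trace$fs + 1e-12))

  # jittered template train: stride times recovered within one sample each
  g2 <- gen_gait(n_strides = 80, stride_time_sd = 0.03, noise_sd = 0,
                 seed = 32)
  s2 <- detect_strides(g2$trace)
  expect_identical(length(s2$event_indices), 80L)
  truth <- g2$truth$stride_times[1:79]
  expect_true(all(abs(s2$stride_times - truth) <= 1 / g2$trace$fs + 1e-12))

  flat <- gyro_trace(t = (0:999) / 100, w = matrix(0, 1000, 3))
  expect_error(detect_strides(flat), "flat signal|no strides")
})

test_that("stride-time statistics use the sample sd", {
  st <- stride_time_stats(c(1.0, 1.2))
  expect_equal(st[["mean"]], 1.1)
  expect_equal(st[["sd"]], 0.2 / sqrt(2), tolerance = 1e-12)
  expect_equal(stride_time_stats(rep(1.1, 63))[["sd"]], 0)
  expect_error(stride_time_stats(1.0), "at least 2")

  # estimator lands in the sampling band around the true sd
  set.seed(33)
  g <- gen_gait(n_strides = 200, stride_time_sd = 0.03, seed = 33)
  sd_hat <- stride_time_stats(detect_strides(g$trace))[["sd"]]
  expect_gte(sd_hat, 0.024)
  expect_lte(sd_hat, 0.036)
})

test_that("time normalization yields exactly 63 x 100 samples and keeps constants", {
  g <- gen_gait(n_strides = 70, seed = 34)
  s <- detect_strides(g$trace)
  norm <- time_normalize_strides(g$trace, s)
  expect_identical(dim(norm), c(6300L, 3L))

  short <- gen_gait(n_strides = 40, seed = 35)
  expect_error(time_normalize_strides(short$trace, detect_strides(short$trace)),
               "need 63")

  # constant channel stays constant through resampling
  tr <- g$trace
  tr$w[, 3] <- 2.5
  norm2 <- time_normalize_strides(tr, s)
  expect_true(all(abs(norm2[, 3] - 2.5) < 1e-12))
})

test_that("the LDS pipeline records the fixed study embedding", {
  g <- gen_gait(n_strides = 70, stride_time_sd = 0.03, seed = 36)
  r <- gait_lds_pipeline(g$trace, exclude = FALSE)
  expect_identical(r$embedding$tau, 11L)
  expect_identical(r$embedding$d_per_channel, 5L)
  expect_identical(r$embedding$total_dim, 15L)
  expect_identical(r$n_state_vectors, 6256L)
  expect_false(any(r$params_auto))
  expect_error(gait_lds_pipeline(gen_gait(n_strides = 30, seed = 37)$trace,
                                 exclude = FALSE), "need 63")
})

test_that("stride-time sd is invariant under a time shift of the trace", {
  g <- gen_gait(n_strides = 80, stride_time_sd = 0.03, seed = 38)
  tr <- g$trace
  tr2 <- gyro_trace(tr$t + 17.3, tr$w, fs = tr$fs, bouts = tr$bouts)
  expect_equal(stride_time_stats(detect_strides(tr))[["sd"]],
               stride_time_stats(detect_strides(tr2))[["sd"]])
})
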