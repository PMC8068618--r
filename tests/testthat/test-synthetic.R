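test_that("OU sway traces honour the stationary-moment oracle", {
  tr <- gen_cop(theta = 1, sigma = 1.5, duration_s = 30, fs = 180, seed = 1)
  expect_identical(length(tr$t), 5400L)

  # cross-sectional variance over seeds matches sigma^2 / (2 theta)
  set.seed(61)
  last <- t(sapply(1:100, function(s) {
    tr <- gen_cop(1, 1.5, duration_s = 2, fs = 50, seed = 600 + s)
    c(tr$x[100], tr$y[100])
  }))
  expect_lt(abs(var(as.vector(last)) - 1.5^2 / 2) / (1.5^2 / 2), 0.35)

  # within-trace variance over many seeds lands within 10% of the target
  v <- sapply(1:60, function(s) var(gen_cop(1, 1.5, seed = 700 + s)$x))
  expect_lt(abs(mean(v) - 1.5^2 / 2) / (1.5^2 / 2), 0.10)

  tiny <- gen_cop(1, 1e-9, duration_s = 1, fs = 100, seed = 2)
  expect_lt(max(abs(c(tiny$x, tiny$y))), 1e-6)
  expect_error(gen_cop(0, 1), "theta > 0")
})

test_that("gait generation is deterministic and sized as configured", {
  g1 <- gen_gait(n_strides = 70, stride_time_mean = 1.1, seed = 62)
  g2 <- gen_gait(n_strides = 70, stride_time_mean = 1.1, seed = 62)
  expect_identical(g1$trace$w, g2$trace$w)
  expect_equal(length(g1$trace$t), 7700, tolerance = 0.02)

  quiet <- gen_gait(n_strides = 70, stride_time_sd = 0, noise_sd = 0, seed = 63)
  r <- gait_lds_pipeline(quiet$trace, exclude = FALSE)
  expect_lt(abs(r$lle), 0.05)   # limit-cycle limit: no divergence
})

test_that("triangle trial generation forces the configured geometry", {
  perfect <- gen_triangle_trials(seed = 64)
  expect_identical(length(perfect), 4L)
  s <- summarize_trials(lapply(perfect, score_trial))
  expect_lt(s[["mean_angle_error"]], 1e-9)
  expect_lt(s[["mean_distance_error"]], 1e-9)

  under <- gen_triangle_trials(dist_gain = 0.8, seed = 65)
  for (tr in under) {
    sc <- score_trial(tr)
    expect_equal(sc$distance_error, 0.2 * sqrt(sum((tr$A - tr$C)^2)),
                 tolerance = 1e-9)
  }

  # folded-normal oracle for the mean absolute angle error
  set.seed(66)
  many <- gen_triangle_trials(turn_bias_deg = 15, turn_sd_deg = 5,
                              n_sets = 250, seed = 66)
  mae <- mean(sapply(many, function(t) score_trial(t)$angle_error))
  mu <- 15; sd <- 5
  folded <- sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) +
    mu * (1 - 2 * pnorm(-mu / sd))
  expect_gte(mae, folded - 2); expect_lte(mae, folded + 3)
})

test_that("cohorts reproduce bit-identically under a fixed seed", {
  cfg <- synth_config(n_per_group = 6)
  c1 <- gen_cohort(cfg, seed = 67)
  c2 <- gen_cohort(cfg, seed = 67)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$truth, c2$truth)
})

test_that("zero loadings give near-zero exercise correlations", {
  cfg <- synth_config(n_per_group = 200)
  cfg$loadings[] <- 0
  ok <- sapply(1:20, function(s) {
    cs <- gen_cohort(cfg, seed = 800 + s)
    co <- cs$cohort
    # per group, as in the study's correlation design
    all(sapply(c("BVI", "sighted"), function(g) {
      ex <- co$value[co$dv_name == "exercise" & co$group == g]
      all(sapply(setdiff(unique(co$dv_name), c("exercise", "basic_activity")),
                 function(dv)
                   abs(cor(ex, co$value[co$dv_name == dv & co$group == g])) < 0.2))
    }))
  })
  expect_gte(mean(ok), 0.9)
})

test_that("group effect directions mirror the study at n = 200 per group", {
  cfg <- synth_config(n_per_group = 200)
  cs <- gen_cohort(cfg, seed = 68)
  co <- cs$cohort
  gm <- function(dv, g) mean(co$value[co$dv_name == dv & co$group == g])
  expect_gt(gm("pea", "BVI"), gm("pea", "sighted"))
  expect_lt(gm("sls_time", "BVI"), gm("sls_time", "sighted"))
  expect_lt(gm("exercise", "BVI"), gm("exercise", "sighted"))
})

test_that("stronger loadings yield stronger empirical correlations", {
  base <- synth_config(n_per_group = 150)
  rs <- sapply(c(0, -0.006, -0.02), function(lam) {
    cfg <- base
    cfg$loadings[] <- 0
    cfg$loadings[["stride_time_sd"]] <- lam
    mean(sapply(1:10, function(s) {
      cs <- gen_cohort(cfg, seed = 900 + s)
      co <- cs$cohort
      abs(cor(co$value[co$dv_name == "exercise"],
              co$value[co$dv_name == "stride_time_sd"]))
    }))
  })
  expect_true(all(diff(rs) > 0))
})

test_that("trace-level cohorts run the measurement pipelines end to end", {
  cfg <- synth_config(n_per_group = 2)
  cs <- gen_cohort(cfg, seed = 69, level = "trace")
  expect_identical(length(cs$traces), 4L)
  co <- cs$cohort
  expect_true(all(c("pea", "stride_time_sd", "angle_error") %in% co$dv_name))
  expect_true(all(co$value[co$dv_name == "pea"] > 0))
})
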