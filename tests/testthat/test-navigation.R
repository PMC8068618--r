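test_that("3-4-5 trials score exactly", {
  # perfect return: P = A, |A - C| = 500
  s <- score_trial(trial_345(c(0, 0)))
  expect_equal(s$angle_error, 0, tolerance = 1e-9)
  expect_equal(s$distance_error, 0, tolerance = 1e-9)
  expect_equal(s$endpoint_miss, 0, tolerance = 1e-9)

  # correct heading, stopped 100 cm short
  C <- c(300, 400); A <- c(0, 0)
  P_short <- C + 400 * (A - C) / 500
  s2 <- score_trial(trial_345(P_short))
  expect_equal(s2$angle_error, 0, tolerance = 1e-9)
  expect_equal(s2$distance_error, 100, tolerance = 1e-9)
  expect_equal(s2$signed_distance_error, -100, tolerance = 1e-9)

  # correct length, heading off by +10 degrees
  th <- 10 * pi / 180
  v <- (A - C) / 500
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s3 <- score_trial(trial_345(C + 500 * as.numeric(R %*% v)))
  expect_equal(s3$angle_error, 10, tolerance = 1e-9)
  expect_equal(s3$distance_error, 0, tolerance = 1e-9)
})

test_that("scores are invariant under rotation, translation and mirroring", {
  set.seed(41)
  base <- trial_345(c(40, -40))
  s0 <- score_trial(base)
  for (k in 1:5) {
    tr <- transform_trial(base, angle = runif(1, -pi, pi),
                          shift = runif(2, -500, 500))
    s <- score_trial(tr)
    expect_equal(s$angle_error, s0$angle_error, tolerance = 1e-9)
    expect_equal(s$distance_error, s0$distance_error, tolerance = 1e-9)
    expect_equal(s$endpoint_miss, s0$endpoint_miss, tolerance = 1e-9)
  }
  # mirrored course with mirrored stopping point scores identically
  m <- function(p) c(p[1], -p[2])
  mir <- triangle_trial(m(base$A), m(base$B), m(base$C), m(base$P),
                        direction = "counterclockwise")
  sm <- score_trial(mir)
  expect_equal(sm$angle_error, s0$angle_error, tolerance = 1e-9)
  expect_equal(sm$distance_error, s0$distance_error, tolerance = 1e-9)
})

test_that("angle errors are bounded and zero along the extended homing line", {
  set.seed(42)
  for (k in 1:20) {
    P <- runif(2, -600, 600)
    s <- score_trial(trial_345(P))
    expect_gte(s$angle_error, 0); expect_lte(s$angle_error, 180)
    expect_gte(s$distance_error, 0)
    expect_equal(s$angle_error, abs(s$signed_angle_error))
  }
  # P beyond A on the C->A ray: angle error exactly zero
  C <- c(300, 400)
  P_over <- C + 1.4 * (c(0, 0) - C)
  expect_equal(score_trial(trial_345(P_over))$angle_error, 0, tolerance = 1e-9)
  expect_error(score_trial(trial_345(c(300, 400))), "degenerate")
})

test_that("trial summaries average absolute errors", {
  mk <- function(a, d) structure(list(angle_error = a, distance_error = d),
                                 class = "trial_score")
  s <- summarize_trials(list(mk(10, 1), mk(20, 2), mk(30, 3), mk(40, 4)))
  expect_equal(s[["mean_angle_error"]], 25)
  expect_equal(s[["mean_distance_error"]], 2.5)
  expect_equal(summarize_trials(list(mk(0, 0)))[["mean_angle_error"]], 0)
  expect_error(summarize_trials(list()), "at least one")
})

test_that("reference triangles match the design geometry", {
  tri <- reference_triangles()
  side <- function(p, q) sqrt(sum((p - q)^2))
  t1 <- tri$triangle1
  expect_equal(c(side(t1$A, t1$B), side(t1$B, t1$C), side(t1$C, t1$A)),
               c(300, 300, 300), tolerance = 1e-9)
  t2 <- tri$triangle2
  sides <- sort(c(side(t2$A, t2$B), side(t2$B, t2$C), side(t2$C, t2$A)))
  expect_equal(sides, c(150, 150 * sqrt(3), 300), tolerance = 1e-9)
  expect_setequal(t2$angles, c(30, 60, 90))
  # every segment lies within the 150-300 cm design range
  all_sides <- unlist(lapply(tri, function(t)
    c(side(t$A, t$B), side(t$B, t$C), side(t$C, t$A))))
  expect_true(all(all_sides >= 150 - 1e-9 & all_sides <= 300 + 1e-9))
})
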