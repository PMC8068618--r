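test_that("mixed ANOVA matches the hand SS oracle on a 4-participant table", {
  y11 <- c(3, 5); y12 <- c(4, 8)     # group 1, conditions 1 and 2
  y21 <- c(10, 6); y22 <- c(7, 9)    # group 2
  d <- data.frame(
    participant_id = rep(c("a", "b", "c", "d"), 2),
    group = rep(c("BVI", "BVI", "sighted", "sighted"), 2),
    condition = rep(c("c1", "c2"), each = 4),
    dv_name = "y",
    value = c(y11, y21, y12, y22))
  a <- mixed_anova_2x2(d)
  o <- anova_oracle_2x2(y11, y12, y21, y22)
  expect_equal(a$group$F, o$F_group, tolerance = 1e-6)
  expect_equal(a$condition$F, o$F_cond, tolerance = 1e-6)
  expect_equal(a$interaction$F, o$F_int, tolerance = 1e-6)

  # independent route: base-R split-plot aov on the same data
  s <- summary(stats::aov(value ~ group * condition +
                            Error(participant_id / condition), data = d))
  expect_equal(a$group$F, s[[1]][[1]]["group", "F value"], tolerance = 1e-9)
  expect_equal(a$condition$F, s[[2]][[1]]["condition", "F value"],
               tolerance = 1e-9)
  expect_equal(a$interaction$F, s[[2]][[1]]["group:condition", "F value"],
               tolerance = 1e-9)
})

test_that("identical cell means give a null group effect", {
  # both groups carry the same participant profiles: cell means match but
  # the error variance is nonzero
  vals <- c(1.0, 2.5, 3.1, 0.4)           # condition 1, participants 1-4
  vals2 <- c(2.2, 1.7, 4.0, 0.9)          # condition 2
  d <- make_cohort_2x2(n1 = 4, n2 = 4,
                       fun = function(n) c(vals, vals, vals2, vals2))
  a <- mixed_anova_2x2(d)
  expect_lt(a$group$F, 1e-9)
  expect_lt(a$interaction$F, 1e-9)
  expect_gt(a$condition$F, 0)
})

test_that("a pure within effect moves F_condition, not F_group", {
  set.seed(51)
  F_c <- sapply(c(0, 0.5, 1.5), function(delta) {
    d <- make_cohort_2x2(n1 = 10, n2 = 10)
    d$value[d$condition == "c2"] <- d$value[d$condition == "c2"] + delta
    mixed_anova_2x2(d)$condition$F
  })
  expect_true(all(diff(F_c) > 0))

  rej <- mean(replicate(200, {
    d <- make_cohort_2x2(n1 = 10, n2 = 10)
    d$value[d$condition == "c2"] <- d$value[d$condition == "c2"] + 1
    mixed_anova_2x2(d)$group$p < 0.05
  }))
  expect_gte(rej, 0.01); expect_lte(rej, 0.10)
})

test_that("ANOVA validates unbalanced within-levels", {
  d <- make_cohort_2x2(n1 = 3, n2 = 3)
  d <- d[-1, ]   # one participant loses a condition
  expect_error(mixed_anova_2x2(d), "missing a within-level")
})

test_that("Levene test behaves under null, power and degenerate cases", {
  expect_equal(levene_test(list(c(1, 2, 3), c(1, 2, 3)))[["W"]], 0)
  expect_equal(levene_test(list(rep(2, 5), rep(2, 6)))[["p"]], 1)
  set.seed(52)
  r_null <- mean(replicate(500, levene_test(list(rnorm(200), rnorm(200)))["p"] < 0.05))
  expect_gte(r_null, 0.03); expect_lte(r_null, 0.08)
  r_pow <- mean(replicate(200, levene_test(list(rnorm(50), rnorm(50, 0, 2)))["p"] < 0.05))
  expect_gte(r_pow, 0.8)
})

test_that("HC3 correction stays close to the classical F when homoscedastic", {
  set.seed(53)
  d <- make_cohort_2x2(n1 = 100, n2 = 100)
  a0 <- mixed_anova_2x2(d, hc = FALSE)
  a1 <- mixed_anova_2x2(d, hc = TRUE)
  expect_true(a1$heteroscedasticity_corrected)
  for (e in c("group", "condition", "interaction"))
    expect_lt(abs(a1[[e]]$F - a0[[e]]$F) / max(a0[[e]]$F, 1e-12), 0.15)

  # still finite at n = 2 per cell
  d2 <- make_cohort_2x2(n1 = 2, n2 = 2)
  a2 <- mixed_anova_2x2(d2, hc = TRUE)
  expect_true(is.finite(a2$group$F))
})

test_that("hc_correct keeps the corrected group test calibrated under heteroscedasticity", {
  set.seed(54)
  rej <- replicate(500, {
    d <- make_cohort_2x2(n1 = 14, n2 = 14)
    bvi <- d$group == "BVI"
    d$value[bvi] <- d$value[bvi] * 3
    mixed_anova_2x2(d, hc = TRUE)$group$p < 0.05
  })
  expect_gte(mean(rej), 0.02); expect_lte(mean(rej), 0.09)
})

test_that("Cohen's d matches hand arithmetic and flips sign with its arguments", {
  r <- cohens_d_ci(c(0, 1), c(1, 2))
  expect_equal(r$d, -1 / sqrt(0.5), tolerance = 1e-6)  # pooled sd = sqrt(0.5)
  expect_true(r$ci_95[1] <= r$d && r$d <= r$ci_95[2])

  a <- c(1.2, 3.1, 0.4, 2.2); b <- c(2.5, 4.0, 3.3)
  expect_equal(cohens_d_ci(a, b)$d, -cohens_d_ci(b, a)$d, tolerance = 1e-12)

  same <- c(1, 2, 3, 4)
  r0 <- cohens_d_ci(same, same)
  expect_equal(r0$d, 0)
  expect_equal(r0$ci_95[1], -r0$ci_95[2], tolerance = 1e-6)

  set.seed(55)
  r8 <- cohens_d_ci(rnorm(1000, 0.8), rnorm(1000, 0))
  expect_gte(r8$d, 0.7); expect_lte(r8$d, 0.9)
  expect_error(cohens_d_ci(rep(1, 5), rep(1, 5)), "zero pooled sd")
})

test_that("Tukey adjustment collapses for 2 levels and penalizes 3", {
  set.seed(56)
  d2 <- data.frame(value = rnorm(20), level = rep(c("a", "b"), 10))
  ct <- emm_contrasts(d2)
  fit <- lm(value ~ level, data = d2)
  raw_p <- summary(fit)$coefficients[2, 4]
  expect_equal(ct$p.value, raw_p, tolerance = 1e-9)

  d3 <- data.frame(value = rnorm(30), level = rep(c("a", "b", "c"), 10))
  ct3 <- emm_contrasts(d3)
  # brute-force studentized-range comparison per contrast
  for (i in seq_len(nrow(ct3))) {
    raw <- 2 * pt(abs(ct3$t.ratio[i]), ct3$df[i], lower.tail = FALSE)
    tukey <- ptukey(abs(ct3$t.ratio[i]) * sqrt(2), 3, ct3$df[i],
                    lower.tail = FALSE)
    expect_equal(ct3$p.value[i], tukey, tolerance = 1e-6)
    expect_gt(ct3$p.value[i], raw)
  }
  # contrast estimate equals the cell-mean difference in balanced data
  means <- tapply(d3$value, d3$level, mean)
  expect_equal(ct3$estimate[1], unname(means["a"] - means["b"]),
               tolerance = 1e-9)
})

test_that("Pearson correlation matches the deviation-sum oracle with Fisher CI", {
  r <- pearson_ci(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-6)   # 0.9820
  expect_equal(r$df, 1)

  x <- 1:50
  rp <- pearson_ci(x, 2 * x + 1)
  expect_equal(rp$r, 1)
  expect_lt(rp$p, 1e-12)

  # affine invariance and sign flip
  set.seed(57)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  r0 <- pearson_ci(x, y)$r
  expect_equal(pearson_ci(3 * x + 2, 0.5 * y - 7)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_ci(-x, y)$r, -r0, tolerance = 1e-12)
  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("the report runs both families and flags only the planted effect", {
  set.seed(58)
  cfg <- synth_config()
  cfg$loadings[] <- 0
  cfg$group_offset[] <- 0
  cfg$group_offset[["pea"]] <- 12      # only sway differs between groups
  cfg$exercise_meanlog[] <- log(300)
  hits <- replicate(30, {
    cs <- gen_cohort(cfg, seed = sample.int(1e6, 1))
    rep <- reproduce_analysis(cs$cohort)
    c(pea = rep$anovas$pea$group$p < 0.05,
      gait = rep$anovas$stride_time_sd$group$p < 0.05)
  })
  expect_gt(mean(hits["pea", ]), 0.5)        # planted effect is found
  expect_lt(mean(hits["gait", ]), 0.3)       # absent effect stays near level
  expect_identical(length(reproduce_analysis(data.frame())$anovas), 0L)
})

test_that("in balanced designs the split-plot SS decomposition is exact", {
  set.seed(59)
  d <- make_cohort_2x2(n1 = 8, n2 = 8)
  wide <- reshape(d[, c("participant_id", "group", "condition", "value")],
                  idvar = c("participant_id", "group"), timevar = "condition",
                  direction = "wide")
  y <- c(wide$value.c1, wide$value.c2)
  g <- factor(rep(wide$group, 2)); cond <- factor(rep(c("c1", "c2"), each = 16))
  id <- factor(rep(wide$participant_id, 2))
  ss_tot <- sum((y - mean(y))^2)
  fit <- stats::aov(y ~ g * cond + Error(id))
  ss_parts <- sum(unlist(lapply(summary(fit), function(s)
    s[[1]][["Sum Sq"]])))
  expect_equal(ss_parts, ss_tot, tolerance = 1e-6 * ss_tot)
})
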