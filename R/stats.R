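#' Two-by-two mixed factorial ANOVA (Type III)
#'
#' Split-plot analysis with one between-subjects factor (Group, 2 levels)
#' and one within-subjects factor (Condition, 2 levels), participant as
#' the random blocking factor. With two levels per factor the design
#' collapses exactly: per-participant averages over condition carry the
#' Group effect (between stratum), per-participant condition differences
#' carry the Condition and Group x Condition effects (within stratum).
#' Both strata are fitted as linear models with sum-to-zero contrasts, so
#' the F tests are Type III (unweighted-means) tests, which matters when
#' the groups are unbalanced after missing-data removal.
#'
#' When `hc = TRUE` (or when `hc = "auto"` and Levene's test on the
#' stratum residuals rejects at `hc_alpha`), the F statistics are
#' recomputed as Wald tests with a White-Huber (HC3) sandwich covariance.
#'
#' @param table long-format cohort data (see [build_cohort()]) or any
#'   data.frame with columns `participant_id`, `group`, `condition`,
#'   `dv_name`, `value`.
#' @param dv which `dv_name` to analyse (may be omitted when the table
#'   holds a single dv).
#' @param hc `FALSE`, `TRUE`, or `"auto"` (Levene-gated).
#' @param hc_alpha gate level for `"auto"` (default 0.05).
#' @return An object of class `anova_2x2`: list of per-effect rows
#'   (`group`, `condition`, `interaction`) each with `F`, `df_num`,
#'   `df_den`, `p`, `mean_difference`, `cohens_d`, `d_ci_95`; plus
#'   `heteroscedasticity_corrected`, `levene`, `n_per_group`.
#' @export
mixed_anova_2x2 <- function(table, dv = NULL, hc = FALSE, hc_alpha = 0.05) {
  d <- as.data.frame(table)
  if (!is.null(dv)) d <- d[d$dv_name == dv, , drop = FALSE]
  if (!is.null(d$dv_name) && length(unique(d$dv_name)) > 1L)
    stop("mixed_anova_2x2: multiple dv_name values; pass dv=", call. = FALSE)
  conds <- sort(unique(d$condition))
  if (length(conds) != 2L)
    stop("mixed_anova_2x2: need exactly 2 within-levels", call. = FALSE)
  wide <- stats::reshape(
    d[, c("participant_id", "group", "condition", "value")],
    idvar = c("participant_id", "group"), timevar = "condition",
    direction = "wide")
  v1 <- wide[[paste0("value.", conds[1])]]
  v2 <- wide[[paste0("value.", conds[2])]]
  bad <- is.na(v1) | is.na(v2)
  if (any(bad))
    stop("mixed_anova_2x2: participants missing a within-level: ",
         paste(wide$participant_id[bad], collapse = ", "), call. = FALSE)
  g <- factor(wide$group)
  if (nlevels(g) != 2L || any(table(g) < 2L))
    stop("mixed_anova_2x2: need 2 groups with >= 2 participants each",
         call. = FALSE)
  avg <- (v1 + v2) / 2
  dif <- v1 - v2
  op <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(op))
  fit_b <- stats::lm(avg ~ g)  # between stratum
  fit_w <- stats::lm(dif ~ g)  # within stratum

  lev <- levene_test(split(avg, g))
  use_hc <- isTRUE(hc) || (identical(hc, "auto") && lev["p"] < hc_alpha)

  wald_F <- function(fit, coef_idx) {
    V <- if (use_hc) sandwich::vcovHC(fit, type = "HC3") else stats::vcov(fit)
    b <- stats::coef(fit)[coef_idx]
    Fv <- b^2 / V[coef_idx, coef_idx]
    df2 <- stats::df.residual(fit)
    c(F = unname(Fv), df_num = 1, df_den = df2,
      p = unname(stats::pf(Fv, 1, df2, lower.tail = FALSE)))
  }
  eff_group <- wald_F(fit_b, 2L)
  eff_cond <- wald_F(fit_w, 1L)       # intercept of diff model = condition effect
  eff_int <- wald_F(fit_w, 2L)

  g1 <- levels(g)[1]; g2 <- levels(g)[2]
  # descriptives: unweighted mean differences and standardized effects
  md_group <- mean(avg[g == g1]) - mean(avg[g == g2])
  md_cond <- (mean(dif[g == g1]) + mean(dif[g == g2])) / 2
  safe_d <- function(expr) tryCatch(expr, error = function(e)
    list(d = NA_real_, ci_95 = c(NA_real_, NA_real_)))
  d_group <- safe_d(cohens_d_ci(avg[g == g1], avg[g == g2]))
  d_cond <- cohens_d_ci_one(dif)      # standardized by sd of difference scores
  d_int <- safe_d(cohens_d_ci(dif[g == g1], dif[g == g2]))

  mk <- function(w, md, dd) list(F = w[["F"]], df_num = w[["df_num"]],
                                 df_den = w[["df_den"]], p = w[["p"]],
                                 mean_difference = md,
                                 cohens_d = dd$d, d_ci_95 = dd$ci_95)
  structure(list(
    group = mk(eff_group, md_group, d_group),
    condition = mk(eff_cond, md_cond, d_cond),
    interaction = mk(eff_int, mean(dif[g == g1]) - mean(dif[g == g2]), d_int),
    heteroscedasticity_corrected = use_hc,
    levene = lev,
    n_per_group = as.vector(table(g)),
    groups = levels(g), conditions = conds), class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  for (e in c("group", "condition", "interaction")) {
    r <- x[[e]]
    cat(sprintf("%-12s F(%d, %d) = %.3f, p = %.4f, md = %.3f, d = %.2f [%.2f, %.2f]\n",
                e, r$df_num, r$df_den, r$F, r$p, r$mean_difference,
                r$cohens_d, r$d_ci_95[1], r$d_ci_95[2]))
  }
  if (x$heteroscedasticity_corrected)
    cat("(White-Huber HC3 corrected covariance)\n")
  invisible(x)
}

#' Levene's test for homogeneity of variance
#'
#' Classic (mean-centred) Levene test: a one-way ANOVA on absolute
#' deviations from the group centres, via `car::leveneTest`.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2), or a
#'   data.frame with `value` and `group` columns.
#' @param center `"mean"` (classic, default) or `"median"`
#'   (Brown-Forsythe).
#' @return Named vector `c(W = , df1 = , df2 = , p = )`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("levene_test: need >= 2 groups with n >= 2 each", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0)   # all values identical: no heterogeneity by definition
    return(c(W = 0, df1 = length(groups) - 1, df2 = length(y) - length(groups),
             p = 1))
  centerfun <- if (center == "mean") mean else stats::median
  lt <- suppressWarnings(car::leveneTest(y, f, center = centerfun))
  W <- lt[1, "F value"]
  if (!is.finite(W)) W <- 0
  p <- lt[1, "Pr(>F)"]
  c(W = W, df1 = lt[1, "Df"], df2 = lt[2, "Df"],
    p = if (is.finite(p)) p else 1)
}

#' Cohen's d with noncentral-t confidence interval
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' n-1 pooled standard deviation; the 95% CI is obtained by inverting the
#' noncentral t distribution of the observed t statistic.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param conf confidence level (default 0.95).
#' @return List with `d`, `ci_95` (length-2), `t`, `df`.
#' @export
cohens_d_ci <- function(a, b, conf = 0.95) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("cohens_d_ci: need n >= 2 per sample", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("cohens_d_ci: zero pooled sd", call. = FALSE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  mult <- sqrt(1 / na + 1 / nb)
  tt <- d / mult
  df <- na + nb - 2
  ci <- ncp_interval(tt, df, conf) * mult
  list(d = d, ci_95 = ci, t = tt, df = df)
}

# One-sample variant for within-subject (difference-score) effects:
# d = mean(x) / sd(x), CI by noncentral-t inversion of t = d * sqrt(n).
cohens_d_ci_one <- function(x, conf = 0.95) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 2L || s <= 0) return(list(d = NA_real_, ci_95 = c(NA_real_, NA_real_)))
  d <- mean(x) / s
  tt <- d * sqrt(n)
  ci <- ncp_interval(tt, n - 1, conf) / sqrt(n)
  list(d = d, ci_95 = ci, t = tt, df = n - 1)
}

# CI for a noncentrality parameter given an observed t: the standard
# pivot inversion (find ncp s.t. the observed t is at the 97.5th / 2.5th
# percentile of t(df, ncp)).
ncp_interval <- function(tt, df, conf = 0.95) {
  alpha <- (1 - conf) / 2
  lim <- abs(tt) + 10 + 10 * abs(tt)
  f_lo <- function(ncp) suppressWarnings(stats::pt(tt, df, ncp)) - (1 - alpha)
  f_hi <- function(ncp) suppressWarnings(stats::pt(tt, df, ncp)) - alpha
  lo <- tryCatch(stats::uniroot(f_lo, c(-lim, lim), tol = 1e-8)$root,
                 error = function(e) NA_real_)
  hi <- tryCatch(stats::uniroot(f_hi, c(-lim, lim), tol = 1e-8)$root,
                 error = function(e) NA_real_)
  c(lo, hi)
}

#' White-Huber corrected Wald F tests for a fitted linear model
#'
#' Replaces the model-based coefficient covariance with a
#' heteroscedasticity-consistent sandwich estimate (HC3 by default, the
#' small-sample recommendation) and recomputes per-coefficient Wald F
#' statistics against the residual degrees of freedom.
#'
#' @param fit an `lm` fit (cell-means or contrast-coded model).
#' @param type sandwich flavour passed to `sandwich::vcovHC`.
#' @return List with `vcov` (corrected covariance) and `tests`, a
#'   data.frame of per-coefficient `F`, `df_num`, `df_den`, `p`.
#' @export
hc_correct <- function(fit, type = "HC3") {
  V <- sandwich::vcovHC(fit, type = type)
  b <- stats::coef(fit)
  df2 <- stats::df.residual(fit)
  Fv <- b^2 / diag(V)
  list(vcov = V,
       tests = data.frame(coef = names(b), F = unname(Fv), df_num = 1,
                          df_den = df2,
                          p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
                          row.names = NULL))
}

#' Pairwise marginal-mean contrasts with Tukey adjustment
#'
#' Estimated marginal means of a single factor and all pairwise
#' differences, with studentized-range (Tukey) adjusted p values, via
#' `emmeans`. For a 2-level factor the Tukey adjustment collapses to the
#' unadjusted test.
#'
#' @param data data.frame with columns `value` and `level` (factor).
#' @return data.frame of contrasts: `contrast`, `estimate`, `SE`, `df`,
#'   `t.ratio`, `p.value` (Tukey-adjusted), plus attribute `"emmeans"`.
#' @export
emm_contrasts <- function(data) {
  data$level <- factor(data$level)
  fit <- stats::lm(value ~ level, data = data)
  em <- emmeans::emmeans(fit, "level")
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  attr(ct, "emmeans") <- as.data.frame(em)
  ct
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Two-sided Pearson correlation; p from the t distribution with n - 2
#' degrees of freedom, 95% CI by the Fisher z transform (as produced by
#' `stats::cor.test`).
#'
#' @param x,y numeric vectors, n >= 3, nonzero variance.
#' @param conf confidence level (default 0.95).
#' @return An object of class `correlation_result`: list with `r`, `df`,
#'   `ci_95`, `p`, `n`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("pearson_ci: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_ci: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson",
                        conf.level = conf)
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 ci_95 = as.numeric(ct$conf.int), p = ct$p.value,
                 n = length(x)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, 95%% CI [%.3f, %.3f], p = %.4f\n",
              x$df, x$r, x$ci_95[1], x$ci_95[2], x$p))
  invisible(x)
}
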