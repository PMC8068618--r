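#' Run the full between/within analysis over a cohort table
#'
#' Mirrors the study's Results structure on any long-format cohort table:
#' for every outcome with two within-levels a 2x2 mixed ANOVA
#' (Levene-gated White-Huber correction) comparing the groups; for
#' single-condition outcomes a between-group one-way comparison (the same
#' machinery with the within stratum absent); optionally a second,
#' within-one-group family (e.g. the sighted group's eyes open vs. eyes
#' closed); and per-group two-sided Pearson correlations of the activity
#' measures against every outcome.
#'
#' @param cohort long-format data.frame (see [build_cohort()]).
#' @param activity_dvs names of the activity covariates correlated against
#'   the outcomes (default `c("exercise", "basic_activity")`); outcomes
#'   are every other dv.
#' @param hc `"auto"` (default), TRUE or FALSE; passed to the ANOVAs.
#' @return An object of class `cohort_report`: list with `anovas` (per
#'   dv), `correlations` (per group x activity x outcome, a data.frame),
#'   `warnings`.
#' @export
reproduce_analysis <- function(cohort,
                               activity_dvs = c("exercise", "basic_activity"),
                               hc = "auto") {
  cohort <- as.data.frame(cohort)
  warns <- character()
  if (nrow(cohort) == 0L)
    return(structure(list(anovas = list(),
                          correlations = data.frame(),
                          warnings = "empty cohort"), class = "cohort_report"))
  dvs <- unique(cohort$dv_name)
  outcome_dvs <- setdiff(dvs, activity_dvs)

  anovas <- list()
  for (dv in dvs) {
    d <- cohort[cohort$dv_name == dv, , drop = FALSE]
    nlev <- length(unique(d$condition))
    res <- tryCatch({
      if (nlev == 2L) mixed_anova_2x2(d, hc = hc)
      else one_way_group(d, hc = hc)
    }, error = function(e) {
      warns <<- c(warns, sprintf("%s: %s", dv, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) anovas[[dv]] <- res
  }

  # per-group correlations: activity measures x outcomes (participant means
  # over conditions)
  pm <- stats::aggregate(value ~ participant_id + group + dv_name,
                         data = cohort, FUN = mean)
  cors <- list()
  for (grp in unique(pm$group)) for (act in intersect(activity_dvs, dvs)) {
    a <- pm[pm$group == grp & pm$dv_name == act, c("participant_id", "value")]
    for (dv in outcome_dvs) {
      o <- pm[pm$group == grp & pm$dv_name == dv, c("participant_id", "value")]
      m <- merge(a, o, by = "participant_id")
      if (nrow(m) < 3L) next
      ct <- tryCatch(pearson_ci(m$value.x, m$value.y), error = function(e) NULL)
      if (is.null(ct)) next
      cors[[length(cors) + 1L]] <- data.frame(
        group = grp, activity = act, outcome = dv, n = ct$n, r = ct$r,
        df = ct$df, ci_lo = ct$ci_95[1], ci_hi = ct$ci_95[2], p = ct$p,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(cors)) do.call(rbind, cors) else data.frame()
  structure(list(anovas = anovas, correlations = correlations,
                 warnings = warns), class = "cohort_report")
}

# Between-group comparison for a single-condition outcome: Wald F from a
# one-way lm with sum contrasts (equals the two-sample t test squared),
# with the same Levene-gated HC3 option as the mixed ANOVA.
one_way_group <- function(d, hc = "auto", hc_alpha = 0.05) {
  agg <- stats::aggregate(value ~ participant_id + group, data = d, FUN = mean)
  g <- factor(agg$group)
  if (nlevels(g) != 2L || any(table(g) < 2L))
    stop("one_way_group: need 2 groups with n >= 2", call. = FALSE)
  y <- agg$value
  lev <- levene_test(split(y, g))
  use_hc <- isTRUE(hc) || (identical(hc, "auto") && lev["p"] < hc_alpha)
  op <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(op))
  fit <- stats::lm(y ~ g)
  V <- if (use_hc) sandwich::vcovHC(fit, type = "HC3") else stats::vcov(fit)
  b <- stats::coef(fit)[2L]
  Fv <- unname(b^2 / V[2L, 2L])
  df2 <- stats::df.residual(fit)
  dd <- cohens_d_ci(y[g == levels(g)[1]], y[g == levels(g)[2]])
  structure(list(
    group = list(F = Fv, df_num = 1, df_den = df2,
                 p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
                 mean_difference = mean(y[g == levels(g)[1]]) -
                   mean(y[g == levels(g)[2]]),
                 cohens_d = dd$d, d_ci_95 = dd$ci_95),
    heteroscedasticity_corrected = use_hc,
    levene = lev, n_per_group = as.vector(table(g)),
    groups = levels(g)), class = "anova_2x2")
}

#' Collect every p value produced by a cohort report
#'
#' Convenience accessor for calibration studies: all ANOVA effect p values
#' plus all correlation p values.
#'
#' @param report a `cohort_report` from [reproduce_analysis()].
#' @return Numeric vector of p values.
#' @export
report_p_values <- function(report) {
  ps <- unlist(lapply(report$anovas, function(a)
    vapply(intersect(c("group", "condition", "interaction"), names(a)),
           function(e) a[[e]]$p, numeric(1))))
  c(ps, report$correlations$p)
}
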