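# Shared fixtures, built in code at test time.

# Long-format cohort with one dv and both within-levels, group sizes n1/n2.
make_cohort_2x2 <- function(n1 = 14, n2 = 14, fun = stats::rnorm, dv = "y") {
  n <- n1 + n2
  ids <- sprintf("p%02d", seq_len(n))
  grp <- rep(c("BVI", "sighted"), c(n1, n2))
  data.frame(participant_id = rep(ids, 2),
             group = rep(grp, 2),
             condition = rep(c("c1", "c2"), each = n),
             dv_name = dv,
             value = fun(2 * n),
             stringsAsFactors = FALSE)
}

# A clean 3-4-5 triangle trial: A=(0,0), B=(300,0), C=(300,400).
trial_345 <- function(P, direction = "clockwise") {
  triangle_trial(c(0, 0), c(300, 0), c(300, 400), P, direction = direction)
}

# Hand split-plot SS oracle for a balanced 2x2 mixed design: classical
# sums-of-squares arithmetic, independent of the package's regression route.
anova_oracle_2x2 <- function(y11, y12, y21, y22) {
  # yij: group i, condition j, vectors over participants (balanced)
  n <- length(y11)
  avg1 <- (y11 + y12) / 2; avg2 <- (y21 + y22) / 2
  dif1 <- y11 - y12; dif2 <- y21 - y22
  grand <- mean(c(avg1, avg2))
  ss_group <- 2 * n * ((mean(avg1) - grand)^2 + (mean(avg2) - grand)^2)
  ss_subj <- 2 * (sum((avg1 - mean(avg1))^2) + sum((avg2 - mean(avg2))^2))
  md <- mean(c(dif1, dif2))
  ss_cond <- n * md^2
  ss_int <- n / 2 * ((mean(dif1) - md)^2 + (mean(dif2) - md)^2)
  ss_err <- (sum((dif1 - mean(dif1))^2) + sum((dif2 - mean(dif2))^2)) / 2
  list(F_group = (ss_group / 1) / (ss_subj / (2 * n - 2)),
       F_cond = (ss_cond / 1) / (ss_err / (2 * n - 2)),
       F_int = (ss_int / 1) / (ss_err / (2 * n - 2)))
}

# Rotate/translate all points of a trial (direction preserved).
transform_trial <- function(trial, angle = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  tf <- function(p) as.numeric(R %*% p + shift)
  triangle_trial(tf(trial$A), tf(trial$B), tf(trial$C), tf(trial$P),
                 direction = trial$direction, triangle_id = trial$triangle_id)
}
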