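#' Read a center-of-pressure trace from CSV
#'
#' Expects a header with columns `t_s`, `cop_x_cm`, `cop_y_cm`.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz; defaults to 180.
#' @return A [cop_trace()].
#' @export
read_cop_csv <- function(path, fs = 180) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "cop_x_cm", "cop_y_cm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_cop_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cop_trace(d$t_s, d$cop_x_cm, d$cop_y_cm, fs = fs)
}

#' Write a center-of-pressure trace to CSV
#' @param trace a [cop_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cop_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cop_trace"))
  utils::write.csv(
    data.frame(t_s = trace$t, cop_x_cm = trace$x, cop_y_cm = trace$y),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a 3-axis gyroscope trace from CSV
#'
#' Expects columns `t_s`, `wx_rads`, `wy_rads`, `wz_rads`; optional
#' `excluded` (0/1) column populates the exclusion mask.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz; defaults to 100.
#' @param bouts optional bout matrix passed to [gyro_trace()].
#' @return A [gyro_trace()].
#' @export
read_gyro_csv <- function(path, fs = 100, bouts = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "wx_rads", "wy_rads", "wz_rads")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_gyro_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mask <- if ("excluded" %in% names(d)) as.logical(d$excluded) else NULL
  gyro_trace(d$t_s, cbind(d$wx_rads, d$wy_rads, d$wz_rads), fs = fs,
             bouts = bouts, exclusion_mask = mask)
}

#' Write a gyroscope trace to CSV
#' @param trace a [gyro_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(trace, path) {
  stopifnot(inherits(trace, "gyro_trace"))
  utils::write.csv(
    data.frame(t_s = trace$t, wx_rads = trace$w[, 1], wy_rads = trace$w[, 2],
               wz_rads = trace$w[, 3], excluded = as.integer(trace$exclusion_mask)),
    path, row.names = FALSE)
  invisible(path)
}

#' Read triangle-completion trials from CSV
#'
#' Columns: `trial_id, ax, ay, bx, by, cx, cy, px, py, direction`.
#'
#' @param path CSV file path.
#' @return List of [triangle_trial()] objects.
#' @export
read_triangle_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "ax", "ay", "bx", "by", "cx", "cy", "px", "py", "direction")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_triangle_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(d)), function(i)
    triangle_trial(c(d$ax[i], d$ay[i]), c(d$bx[i], d$by[i]),
                   c(d$cx[i], d$cy[i]), c(d$px[i], d$py[i]),
                   direction = d$direction[i], triangle_id = d$trial_id[i]))
}

#' Aggregate single-leg stance times
#'
#' Each of the two 20 s trials is scored by one or more raters; the rater
#' times are averaged within trial, then trials are averaged.
#'
#' @param times numeric matrix, trials in rows, raters in columns; seconds.
#' @return Mean stance time in seconds.
#' @export
aggregate_single_leg <- function(times) {
  times <- as.matrix(times)
  if (nrow(times) != 2L || ncol(times) < 1L)
    stop("aggregate_single_leg: expected a 2-trial x >=1-rater matrix", call. = FALSE)
  if (anyNA(times) || any(times < 0) || any(times > 20))
    stop("aggregate_single_leg: times must lie in [0, 20] s (20 s trial cap)",
         call. = FALSE)
  mean(rowMeans(times))
}

#' Sum weekly activity minutes per category
#'
#' Activity diary entries fall into two categories: `basic` everyday
#' activity (walking to school, stairs, ...) and structured physical
#' `exercise`. Minutes are summed per category.
#'
#' @param entries data.frame with columns `category` (`"basic"` or
#'   `"exercise"`) and `minutes` (>= 0), or an empty data.frame / NULL.
#' @return Named numeric vector `c(basic = , exercise = )` in minutes/week.
#' @export
score_activity <- function(entries) {
  out <- c(basic = 0, exercise = 0)
  if (is.null(entries) || NROW(entries) == 0L) return(out)
  if (!all(c("category", "minutes") %in% names(entries)))
    stop("score_activity: need columns category, minutes", call. = FALSE)
  bad <- setdiff(unique(entries$category), c("basic", "exercise"))
  if (length(bad))
    stop("score_activity: unknown category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(entries$minutes < 0))
    stop("score_activity: minutes must be >= 0", call. = FALSE)
  s <- tapply(entries$minutes, factor(entries$category, c("basic", "exercise")),
              sum, default = 0)
  out[] <- c(s[["basic"]], s[["exercise"]])
  out
}

#' Build the long-format cohort table
#'
#' Converts per-participant outcome records into the long format consumed
#' by the statistics layer: one row per (participant, condition, outcome).
#' If a participant is missing an outcome in some condition, the rows for
#' that outcome are dropped for the participant AND for their age/gender
#' matched partner (`match_id`), so group comparisons stay matched.
#'
#' @param records data.frame with columns `id`, `group` (`"BVI"` or
#'   `"sighted"`), `match_id`, `condition`, plus one column per outcome
#'   (NA = missing).
#' @param dvs character vector of outcome column names; defaults to every
#'   column not among the bookkeeping ones.
#' @return data.frame with columns `participant_id`, `group`, `condition`,
#'   `dv_name`, `value`; attribute `"removed"` lists matched-pair removals.
#' @export
build_cohort <- function(records, dvs = NULL) {
  empty <- data.frame(participant_id = character(), group = character(),
                      condition = character(), dv_name = character(),
                      value = numeric(), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) return(empty)
  book <- c("id", "group", "match_id", "condition")
  if (!all(c("id", "group", "condition") %in% names(records)))
    stop("build_cohort: need columns id, group, condition", call. = FALSE)
  if (is.null(records$match_id)) records$match_id <- NA
  if (!all(records$group %in% c("BVI", "sighted")))
    stop("build_cohort: group must be 'BVI' or 'sighted'", call. = FALSE)
  if (is.null(dvs)) dvs <- setdiff(names(records), book)
  key <- interaction(records$id, records$condition, drop = TRUE)
  if (anyDuplicated(key))
    stop("build_cohort: duplicate (id, condition) rows", call. = FALSE)

  removed <- character()
  rows <- list()
  for (dv in dvs) {
    v <- records[[dv]]
    miss_ids <- unique(records$id[is.na(v)])
    # pull in matched partners of participants with missing data
    partners <- unique(c(
      records$match_id[records$id %in% miss_ids],
      records$id[records$match_id %in% miss_ids]))
    drop_ids <- unique(c(miss_ids, partners[!is.na(partners)]))
    extra <- setdiff(drop_ids, miss_ids)
    if (length(extra))
      removed <- c(removed, sprintf("%s: removed matched partner(s) %s",
                                    dv, paste(extra, collapse = ", ")))
    keep <- !(records$id %in% drop_ids)
    if (!any(keep)) next
    rows[[dv]] <- data.frame(
      participant_id = as.character(records$id[keep]),
      group = records$group[keep],
      condition = as.character(records$condition[keep]),
      dv_name = dv,
      value = v[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
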