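#' Rescale 4-week recall hours to the weekly WPAI metric
#'
#' The WPAI-GH items are scored over 7 days; when administered with a 4-week
#' recall (to smooth over compressed FIFO rosters), reported hours are
#' divided by 4 to return to the weekly metric.
#'
#' @param hours_4w Hours reported over the 4-week recall window (>= 0).
#' @param recall_weeks Length of the recall window in weeks. Default 4.
#' @return Hours per week.
#' @export
#' @examples
#' rescale_recall(16.07)  # 4.0175
rescale_recall <- function(hours_4w, recall_weeks = 4) {
  check_nonneg(hours_4w, "`hours_4w`")
  if (!is.numeric(recall_weeks) || length(recall_weeks) != 1 ||
      recall_weeks <= 0) {
    abort("`recall_weeks` must be a single positive number")
  }
  hours_4w / recall_weeks
}

#' WPAI absenteeism percentage
#'
#' Percentage of scheduled work time missed due to health problems:
#' `100 * missed / (missed + worked)`. Workers reporting zero hours both
#' missed and worked have no defined loss and return `NA` (exclude and count
#' them upstream; see [score_wpai()]).
#'
#' @param hours_missed_wk Work hours missed due to health problems per week.
#' @param hours_worked_wk Actual work hours per week.
#' @return Percentage in \[0, 100\], `NA` where both inputs are zero.
#' @export
#' @examples
#' wpai_absenteeism(14, 28)  # 33.33
wpai_absenteeism <- function(hours_missed_wk, hours_worked_wk) {
  check_nonneg(hours_missed_wk, "`hours_missed_wk`")
  check_nonneg(hours_worked_wk, "`hours_worked_wk`")
  total <- hours_missed_wk + hours_worked_wk
  out <- 100 * hours_missed_wk / total
  out[!is.na(total) & total == 0] <- NA_real_
  out
}

#' WPAI presenteeism percentage
#'
#' Percentage work impairment while at work, from the 0-10 impairment
#' rating: `rating x 10`.
#'
#' @param rating_0_10 Integer impairment rating, 0 (no impairment) to 10
#'   (completely impaired).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' wpai_presenteeism(2)  # 20
wpai_presenteeism <- function(rating_0_10) {
  check_range(rating_0_10, 0, 10, "`rating_0_10`")
  nonint <- !is.na(rating_0_10) & rating_0_10 != round(rating_0_10)
  if (any(nonint)) abort("`rating_0_10` must be whole numbers 0-10")
  rating_0_10 * 10
}

#' WPAI total productivity loss percentage
#'
#' Combines absenteeism and presenteeism so that impairment only applies to
#' the time actually at work: with `a`, `p` as fractions,
#' `total = a + (1 - a) * p`, reported as a percentage. The result is always
#' between `max(a, p)` and `min(a + p, 1)`.
#'
#' @param absenteeism_pct,presenteeism_pct Percentages in \[0, 100\].
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' wpai_total_loss(33.33, 20)  # 46.66
wpai_total_loss <- function(absenteeism_pct, presenteeism_pct) {
  check_range(absenteeism_pct, 0, 100, "`absenteeism_pct`")
  check_range(presenteeism_pct, 0, 100, "`presenteeism_pct`")
  a <- absenteeism_pct / 100
  p <- presenteeism_pct / 100
  100 * (a + (1 - a) * p)
}

#' Score WPAI-GH productivity loss for a cohort
#'
#' Computes per-worker absenteeism, presenteeism and total productivity loss
#' percentages from the raw 4-week-recall WPAI items. Workers with zero
#' hours both missed and worked (not at work during the window) have no
#' defined loss; they are excluded and counted in attribute `"n_undefined"`.
#'
#' @param data Data frame with columns `worker_id`, `wpai_hours_missed_4w`,
#'   `wpai_hours_worked_4w`, `wpai_impairment_0_10`.
#' @param recall_weeks Recall window length in weeks (default 4); hours are
#'   divided by this to return to the weekly WPAI metric.
#' @return A tibble with `worker_id`, `hours_missed_wk`, `hours_worked_wk`,
#'   `absenteeism_pct`, `presenteeism_pct`, `total_loss_pct`; one row per
#'   worker with a defined loss. Attribute `"n_undefined"` counts excluded
#'   workers.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_workers = 50, seed = 1))
#' score_wpai(cohort)
score_wpai <- function(data, recall_weeks = 4) {
  needed <- c("worker_id", "wpai_hours_missed_4w", "wpai_hours_worked_4w",
              "wpai_impairment_0_10")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    worker_id = data$worker_id,
    hours_missed_wk = rescale_recall(data$wpai_hours_missed_4w, recall_weeks),
    hours_worked_wk = rescale_recall(data$wpai_hours_worked_4w, recall_weeks)
  )
  undefined <- !is.na(out$hours_missed_wk) & !is.na(out$hours_worked_wk) &
    out$hours_missed_wk + out$hours_worked_wk == 0
  out$absenteeism_pct <- wpai_absenteeism(out$hours_missed_wk,
                                          out$hours_worked_wk)
  out$presenteeism_pct <- wpai_presenteeism(data$wpai_impairment_0_10)
  out$total_loss_pct <- wpai_total_loss(out$absenteeism_pct,
                                        out$presenteeism_pct)
  out <- out[!undefined, , drop = FALSE]
  attr(out, "n_undefined") <- sum(undefined)
  out
}

#' Cohort-level productivity loss summary
#'
#' @param losses Output of [score_wpai()].
#' @return A one-row tibble: `n`, `any_absenteeism_pct`,
#'   `any_presenteeism_pct`, and mean/sd of each loss measure.
#' @export
wpai_summary <- function(losses) {
  if (nrow(losses) == 0) abort("`losses` is empty")
  tibble(
    n = nrow(losses),
    any_absenteeism_pct = 100 * mean(losses$absenteeism_pct > 0, na.rm = TRUE),
    any_presenteeism_pct = 100 * mean(losses$presenteeism_pct > 0, na.rm = TRUE),
    absenteeism_mean = mean(losses$absenteeism_pct, na.rm = TRUE),
    absenteeism_sd = sd(losses$absenteeism_pct, na.rm = TRUE),
    presenteeism_mean = mean(losses$presenteeism_pct, na.rm = TRUE),
    presenteeism_sd = sd(losses$presenteeism_pct, na.rm = TRUE),
    total_loss_mean = mean(losses$total_loss_pct, na.rm = TRUE),
    total_loss_sd = sd(losses$total_loss_pct, na.rm = TRUE)
  )
}
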