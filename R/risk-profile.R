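#' Multiple-health-risk tier from a risk count
#'
#' Bins the number of co-occurring high-risk conditions into the standard
#' tiers: low (0-2 conditions), medium (3-4), high (5 or more).
#'
#' @param risk_count Integer count of high-risk flags, 0-8.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
#' @examples
#' risk_tier(0:8)
risk_tier <- function(risk_count) {
  check_range(risk_count, 0, 8, "`risk_count`")
  cut(risk_count, breaks = c(-Inf, 2, 4, Inf),
      labels = c("low", "medium", "high"))
}

#' Score all eight risk classifiers for a worker table
#'
#' Applies the eight instrument classifiers to a worker-level table and
#' appends one logical column per condition, the risk count, the
#' multiple-risk tier and an `incomplete` indicator. Workers missing any
#' instrument response get `NA` flags and `incomplete = TRUE`; downstream
#' analyses use complete cases only, with the exclusion count recorded.
#' A missing item that cannot change a disjunctive classification (e.g.
#' missing fruit serves when vegetable serves are already below their
#' minimum) still yields a definite flag.
#'
#' @param data Data frame with one row per worker containing the columns
#'   `gender`, `k10_score`, `pcs_score`, `sleep_hours`, `sleep_quality`,
#'   `auditc_score`, `smoking_status`, `met_minutes`, `height_m`,
#'   `weight_kg`, `fruit_serves`, `veg_serves` (as produced by
#'   [generate_cohort()] or read from a survey CSV).
#' @param rules A [risk_rules()] object.
#' @return The input as a tibble with added columns: the eight condition
#'   flags (see [risk_conditions()]), `bmi_value`, `risk_count`,
#'   `risk_tier` and `incomplete`. The number of incomplete rows is stored
#'   in attribute `"n_incomplete"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_workers = 20, seed = 1))
#' score_risks(cohort)
score_risks <- function(data, rules = risk_rules()) {
  needed <- c("gender", "k10_score", "pcs_score", "sleep_hours",
              "sleep_quality", "auditc_score", "smoking_status",
              "met_minutes", "height_m", "weight_kg", "fruit_serves",
              "veg_serves")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data)
  out <- dplyr::mutate(
    out,
    bmi_value = bmi(.data$weight_kg, .data$height_m),
    poor_sleep = classify_sleep(.data$sleep_hours, .data$sleep_quality, rules),
    risky_alcohol = classify_alcohol(.data$auditc_score, .data$gender, rules),
    smoking = classify_smoking(.data$smoking_status),
    poor_diet = classify_diet(.data$fruit_serves, .data$veg_serves, rules),
    weight_problem = classify_weight(.data$bmi_value, rules),
    insufficient_pa = classify_physical_activity(.data$met_minutes, rules),
    poor_physical_health = classify_physical_health(.data$pcs_score, rules),
    psychological_distress =
      classify_psychological_distress(.data$k10_score, rules)
  )
  flags <- as.matrix(out[risk_conditions()])
  count <- as.integer(rowSums(flags))
  incomplete <- apply(flags, 1L, anyNA)
  out$risk_count <- ifelse(incomplete, NA_integer_, count)
  out$risk_tier <- risk_tier(ifelse(incomplete, NA_integer_, count))
  out$incomplete <- incomplete
  attr(out, "n_incomplete") <- sum(incomplete)
  out
}

#' Per-condition prevalence of high risk
#'
#' @param profiles Output of [score_risks()] (incomplete rows are dropped
#'   before tabulating).
#' @return A tibble with `condition`, `label`, `n_high`, `n` and
#'   `prevalence_pct` (100 x flagged / total).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_workers = 216, seed = 1))
#' prevalence_table(score_risks(cohort))
prevalence_table <- function(profiles) {
  keep <- dplyr::filter(profiles, !.data$incomplete)
  if (nrow(keep) == 0) abort("no complete risk profiles to tabulate")
  purrr::map_dfr(risk_conditions(), function(cond) {
    tibble(condition = cond,
           label = unname(condition_labels()[cond]),
           n_high = sum(keep[[cond]]),
           n = nrow(keep),
           prevalence_pct = 100 * sum(keep[[cond]]) / nrow(keep))
  })
}

#' Distribution of the number of co-occurring health conditions
#'
#' @inheritParams prevalence_table
#' @return A tibble with `risk_count` (0-8), `n` and `pct`.
#' @export
risk_count_table <- function(profiles) {
  keep <- dplyr::filter(profiles, !.data$incomplete)
  if (nrow(keep) == 0) abort("no complete risk profiles to tabulate")
  counts <- table(factor(keep$risk_count, levels = 0:8))
  tibble(risk_count = 0:8,
         n = as.integer(counts),
         pct = 100 * as.integer(counts) / nrow(keep))
}
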