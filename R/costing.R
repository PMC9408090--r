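#' Annual salary model for human-capital costing
#'
#' Values lost productive time at the gross wage. The default annual salary
#' of AUD 134,323.20 is the May-2021 average weekly earnings for the
#' Australian mining industry multiplied by 48 working weeks (52 weeks minus
#' 4 weeks of annual leave).
#'
#' @param weekly_earnings Average weekly earnings in AUD. If supplied, the
#'   annual salary is `weekly_earnings * working_weeks`.
#' @param working_weeks Working weeks per year. Default 48.
#' @param annual_salary Annual salary in AUD; used directly when
#'   `weekly_earnings` is `NULL`. Default 134323.20.
#' @return A list with class `"salary_model"` and elements
#'   `weekly_earnings`, `working_weeks`, `annual_salary`.
#' @export
#' @examples
#' salary_model()
#' salary_model(weekly_earnings = 2798.40)
salary_model <- function(weekly_earnings = NULL, working_weeks = 48,
                         annual_salary = 134323.20) {
  if (!is.null(weekly_earnings)) {
    if (!is.numeric(weekly_earnings) || weekly_earnings <= 0) {
      abort("`weekly_earnings` must be positive")
    }
    annual_salary <- weekly_earnings * working_weeks
  }
  if (!is.numeric(annual_salary) || annual_salary <= 0 ||
      !is.numeric(working_weeks) || working_weeks <= 0) {
    abort("salary components must be positive")
  }
  structure(list(weekly_earnings = weekly_earnings,
                 working_weeks = working_weeks,
                 annual_salary = annual_salary),
            class = "salary_model")
}

#' Excess productivity loss
#'
#' Difference in mean productivity loss between the high-risk and low-risk
#' groups for a condition; may be negative if the high-risk group lost less.
#'
#' @param mean_high,mean_low Mean loss percentages in \[0, 100\].
#' @return Excess loss in percentage points.
#' @export
#' @examples
#' excess_loss(15.11, 4.40)  # 10.71
excess_loss <- function(mean_high, mean_low) {
  check_range(mean_high, 0, 100, "`mean_high`")
  check_range(mean_low, 0, 100, "`mean_low`")
  mean_high - mean_low
}

#' Annual excess cost per worker
#'
#' Values the excess loss at the annual wage: `excess / 100 * annual_salary`.
#'
#' @param excess Excess loss in percentage points.
#' @param salary A [salary_model()].
#' @return AUD per worker per year.
#' @export
#' @examples
#' cost_per_worker(10.71)  # 14386.01
cost_per_worker <- function(excess, salary = salary_model()) {
  stopifnot(inherits(salary, "salary_model"))
  excess / 100 * salary$annual_salary
}

#' Annual cost per 1000 workers for a health condition
#'
#' Scales the covariate-adjusted excess loss by how common the condition is:
#' `prevalence/100 * adjusted_excess/100 * annual_salary * n_workers`.
#' A negative adjusted excess means the condition showed no excess loss for
#' that measure; its cost is recorded as not applicable (`NA`).
#'
#' @param prevalence Prevalence of the high-risk condition, in percent.
#' @param adjusted_excess Adjusted excess loss (regression coefficient), in
#'   percentage points.
#' @param salary A [salary_model()].
#' @param n_workers Workforce size to scale to. Default 1000.
#' @return AUD per `n_workers` workers per year; `NA` where
#'   `adjusted_excess < 0`.
#' @export
#' @examples
#' cost_per_1000(33.3, 6.56)  # 2,934,263.44
cost_per_1000 <- function(prevalence, adjusted_excess,
                          salary = salary_model(), n_workers = 1000) {
  stopifnot(inherits(salary, "salary_model"))
  check_range(prevalence, 0, 100, "`prevalence`")
  out <- prevalence / 100 * adjusted_excess / 100 *
    salary$annual_salary * n_workers
  out[!is.na(adjusted_excess) & adjusted_excess < 0] <- NA_real_
  out
}

#' Aggregate per-1000 costs across health conditions
#'
#' Totals and means of the per-1000-worker annual cost for each loss
#' measure. Only conditions with a positive adjusted excess contribute; a
#' condition with a negative coefficient (no excess loss) is excluded from
#' both the total and the mean's denominator for that measure.
#'
#' @param rows A tibble with one row per condition x measure, columns
#'   `condition`, `measure`, `adjusted_excess` and `cost_per_1000` (as built
#'   by [adjusted_cost_table()]).
#' @return A tibble with one row per measure: `n_contributing`,
#'   `total_cost`, `mean_cost`.
#' @export
#' @examples
#' aggregate_costs(printed_adjusted_costs())
aggregate_costs <- function(rows) {
  needed <- c("condition", "measure", "adjusted_excess", "cost_per_1000")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("`rows` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(rows[c("condition", "measure")]) > 0) {
    abort("duplicate condition/measure rows in `rows`")
  }
  rows |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      n_contributing = sum(.data$adjusted_excess > 0, na.rm = TRUE),
      total_cost = sum(.data$cost_per_1000[.data$adjusted_excess > 0],
                       na.rm = TRUE),
      mean_cost = .data$total_cost / .data$n_contributing,
      .groups = "drop"
    )
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

loss_measures <- function() c("absenteeism", "presenteeism", "total")

loss_column <- function(measure) {
  c(absenteeism = "absenteeism_pct", presenteeism = "presenteeism_pct",
    total = "total_loss_pct")[[measure]]
}

#' Unadjusted excess loss and per-worker cost by condition
#'
#' For each of the eight conditions and each loss measure, computes the mean
#' loss in the high- and low-risk groups, their difference (the unadjusted
#' excess loss), the annual excess cost per worker, and a Mann-Whitney test
#' of the group difference.
#'
#' @param profiles Output of [score_risks()].
#' @param losses Output of [score_wpai()] for the same workers.
#' @param salary A [salary_model()].
#' @return A tibble with one row per condition x measure: `mean_high`,
#'   `mean_low`, `excess`, `cost_per_worker`, `z`, `p_value`, `stars`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_workers = 216, seed = 1))
#' excess_cost_table(score_risks(cohort), score_wpai(cohort))
excess_cost_table <- function(profiles, losses, salary = salary_model()) {
  data <- dplyr::inner_join(
    dplyr::filter(profiles, !.data$incomplete), losses, by = "worker_id")
  if (nrow(data) == 0) abort("no complete workers with defined losses")
  grid <- tidyr::expand_grid(condition = risk_conditions(),
                             measure = loss_measures())
  purrr::pmap_dfr(grid, function(condition, measure) {
    y <- data[[loss_column(measure)]]
    flag <- data[[condition]]
    high <- y[flag]
    low <- y[!flag]
    mw <- if (length(high) > 0 && length(low) > 0) {
      mann_whitney(high, low)
    } else {
      tibble(z = NA_real_, p_value = NA_real_)
    }
    exc <- mean(high) - mean(low)
    tibble(condition = condition,
           label = unname(condition_labels()[condition]),
           measure = measure,
           mean_high = mean(high),
           mean_low = mean(low),
           excess = exc,
           cost_per_worker = cost_per_worker(exc, salary),
           z = mw$z, p_value = mw$p_value, stars = p_stars(mw$p_value))
  })
}

#' Covariate-adjusted excess loss and per-1000 cost by condition
#'
#' Fits the adjusted excess-loss regression (see [fit_adjusted_excess()])
#' for each loss measure, takes the eight condition coefficients as the
#' adjusted excess losses, and converts them to annual costs per 1000
#' workers using each condition's prevalence in the cohort.
#'
#' @inheritParams excess_cost_table
#' @param n_workers Workforce size to scale costs to. Default 1000.
#' @return A tibble with one row per condition x measure: `prevalence`,
#'   `adjusted_excess`, `se`, `p_value`, `stars`, `cost_per_1000` (`NA`
#'   where the coefficient is negative). The three fitted models are
#'   attached as attribute `"fits"`.
#' @export
adjusted_cost_table <- function(profiles, losses, salary = salary_model(),
                                n_workers = 1000) {
  data <- dplyr::inner_join(
    dplyr::filter(profiles, !.data$incomplete), losses, by = "worker_id")
  if (nrow(data) == 0) abort("no complete workers with defined losses")
  prev <- prevalence_table(dplyr::semi_join(profiles, losses,
                                            by = "worker_id"))
  fits <- purrr::map(setNames(loss_measures(), loss_measures()),
                     function(m) fit_adjusted_excess(data, m))
  out <- purrr::map_dfr(loss_measures(), function(m) {
    coefs <- adjusted_excess(fits[[m]])
    dplyr::mutate(coefs, measure = m, .after = "condition")
  })
  out <- dplyr::left_join(out, prev[c("condition", "prevalence_pct")],
                          by = "condition")
  out |>
    dplyr::mutate(
      label = unname(condition_labels()[.data$condition]),
      prevalence = .data$prevalence_pct,
      cost_per_1000 = cost_per_1000(.data$prevalence, .data$adjusted_excess,
                                    salary, n_workers),
      stars = p_stars(.data$p_value)
    ) |>
    dplyr::select("condition", "label", "measure", "prevalence",
                  "adjusted_excess", "se", "p_value", "stars",
                  "cost_per_1000") |>
    structure(fits = fits)
}
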