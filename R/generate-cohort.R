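# lognormal truncated to [lo, hi], parameterised by the untruncated mean/sd
rtrunc_lnorm <- function(n, mean, sd, lo, hi) {
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  sdlog <- sqrt(sdlog2)
  p_lo <- plnorm(lo, meanlog, sdlog)
  p_hi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, p_lo, pmax(p_lo, p_hi)), meanlog, sdlog)
}

sample_demographics <- function(n) {
  age <- pmin(pmax(round(rnorm(n, 39.9, 11.6)), 18), 70)
  gender <- sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.662, 0.338))
  fifo_role <- sample(fifo_role_levels(), n, replace = TRUE,
                      prob = c(0.250, 0.125, 0.181, 0.208, 0.162,
                               0.046, 0.028))
  shift_pattern <- sample(c("rotation", "regular"), n, replace = TRUE,
                          prob = c(0.574, 0.426))
  shift_hours <- ifelse(runif(n) < 0.139,
                        sample(c(10, 11), n, replace = TRUE),
                        sample(c(12, 12, 12, 13), n, replace = TRUE))
  on_band <- sample(1:3, n, replace = TRUE, prob = c(0.199, 0.722, 0.079))
  days_on <- ifelse(on_band == 1, sample(5:7, n, replace = TRUE),
             ifelse(on_band == 2, sample(8:14, n, replace = TRUE),
                    sample(15:21, n, replace = TRUE)))
  days_off <- ifelse(runif(n) < 0.866, sample(5:7, n, replace = TRUE),
                     sample(8:14, n, replace = TRUE))
  yr_band <- sample(1:3, n, replace = TRUE, prob = c(0.403, 0.213, 0.384))
  fifo_years <- round(ifelse(yr_band == 1, runif(n, 0.5, 5),
                      ifelse(yr_band == 2, runif(n, 5, 10),
                             runif(n, 10, 25))), 1)
  tibble(age = age, gender = gender, fifo_role = fifo_role,
         shift_pattern = shift_pattern, shift_hours = shift_hours,
         days_on = days_on, days_off = days_off, fifo_years = fifo_years)
}

# Raw instrument responses drawn "backwards" from the intended flag so that
# score_risks() with default rules reproduces the flag exactly. Draws keep a
# small margin away from every threshold to avoid floating-point boundary
# ambiguity.
sample_instruments <- function(flags, gender) {
  n <- nrow(flags)
  k10_score <- ifelse(flags[, "psychological_distress"],
                      sample(22:50, n, replace = TRUE),
                      sample(10:21, n, replace = TRUE))
  pcs_score <- ifelse(flags[, "poor_physical_health"],
                      runif(n, 20, 49.5), runif(n, 50.5, 68))
  sleep_short <- runif(n) < 0.7  # flagged mostly via short duration
  sleep_hours <- round(ifelse(flags[, "poor_sleep"],
                              ifelse(sleep_short, runif(n, 4, 6.9),
                                     runif(n, 7.1, 9)),
                              runif(n, 7.1, 9)), 1)
  good_q <- c("very good", "good", "fair")
  bad_q <- c("fairly bad", "very bad")
  sleep_quality <- ifelse(flags[, "poor_sleep"] & !(sleep_hours < 7),
                          sample(bad_q, n, replace = TRUE),
                   ifelse(flags[, "poor_sleep"],
                          sample(sleep_quality_levels(), n, replace = TRUE,
                                 prob = c(0.1, 0.2, 0.3, 0.3, 0.1)),
                          sample(good_q, n, replace = TRUE)))
  male <- gender == "male"
  auditc_score <- ifelse(flags[, "risky_alcohol"],
                         ifelse(male, sample(4:12, n, replace = TRUE),
                                sample(3:12, n, replace = TRUE)),
                         ifelse(male, sample(0:3, n, replace = TRUE),
                                sample(0:2, n, replace = TRUE)))
  smoking_status <- ifelse(flags[, "smoking"], "current",
                           sample(c("never", "previous"), n, replace = TRUE,
                                  prob = c(0.6, 0.4)))
  met_minutes <- round(ifelse(flags[, "insufficient_pa"],
                              runif(n, 0, 595), runif(n, 605, 4000)))
  under <- runif(n) < 0.07  # small underweight share among weight problems
  bmi_target <- ifelse(flags[, "weight_problem"],
                       ifelse(under, runif(n, 16, 18.4), runif(n, 25.1, 39)),
                       runif(n, 18.6, 24.9))
  height_m <- round(ifelse(male, rnorm(n, 1.76, 0.07),
                           rnorm(n, 1.63, 0.06)), 2)
  weight_kg <- round(bmi_target * height_m^2, 1)
  diet_mode <- sample(1:3, n, replace = TRUE)  # fruit-low / veg-low / both
  fruit_serves <- ifelse(flags[, "poor_diet"],
                         ifelse(diet_mode == 2, runif(n, 2.1, 4),
                                runif(n, 0, 1.9)),
                         runif(n, 2.1, 4))
  veg_serves <- ifelse(flags[, "poor_diet"],
                       ifelse(diet_mode == 1, runif(n, 5.1, 8),
                              runif(n, 0, 4.9)),
                       runif(n, 5.1, 8))
  tibble(k10_score = k10_score, pcs_score = round(pcs_score, 1),
         sleep_hours = sleep_hours, sleep_quality = sleep_quality,
         auditc_score = auditc_score, smoking_status = smoking_status,
         met_minutes = met_minutes, height_m = height_m,
         weight_kg = weight_kg, fruit_serves = round(fruit_serves, 1),
         veg_serves = round(veg_serves, 1))
}

#' Generate a synthetic FIFO worker cohort
#'
#' Draws a worker-level survey table with the statistical structure the
#' productivity-loss analysis assumes: correlated high-risk condition flags
#' from a latent-Gaussian copula, raw instrument responses generated
#' backwards from each flag (so the risk classifiers are exercised end to
#' end), demographics sampled from workforce margins, and zero-inflated
#' WPAI losses from a hurdle model (logistic-in-flags chance of any loss;
#' truncated-lognormal positive missed hours; latent-normal impairment
#' rating rounded to 0-10).
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per worker and the survey columns
#'   (`worker_id`, demographics, instrument responses and the raw 4-week
#'   WPAI items). The flags the generator intended are attached as
#'   attribute `"intended_flags"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_workers = 100, seed = 7))
#' dplyr::glimpse(cohort)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a cohort_config()")
  }
  if (!is.null(config$seed)) {
    withr::local_seed(as.integer(config$seed))
  }
  n <- config$n_workers
  conds <- risk_conditions()

  # correlated flags: equicorrelated Gaussian copula via a shared factor
  rho <- config$risk_correlation
  w <- rnorm(n)
  z <- sqrt(rho) * w +
    sqrt(1 - rho) * matrix(rnorm(n * 8), n, 8)
  flags <- sweep(z, 2, qnorm(config$risk_prevalence), "<=")
  colnames(flags) <- conds

  demo <- sample_demographics(n)
  instruments <- sample_instruments(flags, demo$gender)

  hc <- if (is.null(config$hours_contract)) {
    demo$shift_hours * demo$days_on * 28 / (demo$days_on + demo$days_off)
  } else {
    rep(config$hours_contract, n)
  }

  eff <- config$effect_sizes
  lp_abs <- config$hurdle_intercepts[["absenteeism"]] +
    drop(flags %*% eff$logit_absenteeism)
  lp_pres <- config$hurdle_intercepts[["presenteeism"]] +
    drop(flags %*% eff$logit_presenteeism)
  any_abs <- runif(n) < plogis(lp_abs)
  any_pres <- runif(n) < plogis(lp_pres)

  missed <- numeric(n)
  if (any(any_abs)) {
    base <- rtrunc_lnorm(sum(any_abs), config$missed_hours_mean,
                         config$missed_hours_sd, 1, hc[any_abs])
    shift <- drop(flags[any_abs, , drop = FALSE] %*% eff$pos_absenteeism)
    missed[any_abs] <- pmin(base + shift, hc[any_abs] - 1)
  }
  worked <- hc - missed

  rating <- integer(n)
  if (any(any_pres)) {
    latent <- config$base_rating +
      drop(flags[any_pres, , drop = FALSE] %*% eff$pos_presenteeism) +
      rnorm(sum(any_pres), 0, config$noise_sd)
    rating[any_pres] <- pmin(10L, pmax(1L, as.integer(round(latent))))
  }

  cohort <- dplyr::bind_cols(
    tibble(worker_id = sprintf("W%05d", seq_len(n))),
    demo, instruments,
    tibble(wpai_hours_missed_4w = round(missed, 2),
           wpai_hours_worked_4w = round(worked, 2),
           wpai_impairment_0_10 = rating))
  attr(cohort, "intended_flags") <-
    dplyr::bind_cols(tibble(worker_id = cohort$worker_id),
                     as_tibble(as.data.frame(flags)))
  cohort
}

#' Summarise a synthetic cohort against its configured margins
#'
#' Classifies the cohort with [score_risks()] and scores losses with
#' [score_wpai()], then reports per-condition prevalence, the proportions
#' with any absenteeism / presenteeism, and the mean and sd of each loss
#' measure, in one long tibble. Useful for checking generator calibration.
#'
#' @param cohort Output of [generate_cohort()] (or any worker table with
#'   the same columns).
#' @param rules A [risk_rules()] object.
#' @return A tibble with columns `metric` and `value`.
#' @export
margins_report <- function(cohort, rules = risk_rules()) {
  if (nrow(cohort) == 0) abort("`cohort` is empty")
  profiles <- score_risks(cohort, rules)
  prev <- prevalence_table(profiles)
  losses <- score_wpai(cohort)
  s <- wpai_summary(losses)
  dplyr::bind_rows(
    tibble(metric = paste0("prevalence_pct_", prev$condition),
           value = prev$prevalence_pct),
    tidyr::pivot_longer(s, dplyr::everything(), names_to = "metric",
                        values_to = "value"))
}

worker_columns <- function() {
  c("worker_id", "age", "gender", "fifo_role", "shift_pattern",
    "shift_hours", "days_on", "days_off", "fifo_years", "k10_score",
    "pcs_score", "sleep_hours", "sleep_quality", "auditc_score",
    "smoking_status", "met_minutes", "height_m", "weight_kg",
    "fruit_serves", "veg_serves", "wpai_hours_missed_4w",
    "wpai_hours_worked_4w", "wpai_impairment_0_10")
}

#' Read and write worker cohort CSV files
#'
#' RFC 4180 CSV, UTF-8, header row, one row per worker with exactly the
#' survey columns. `write_cohort_config()` stores the generator settings
#' (including the seed) as JSON next to the data for reproducibility.
#'
#' @param cohort A worker table, e.g. from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns a validated tibble; the writers return
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[worker_columns()], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      worker_id = readr::col_character(),
      gender = readr::col_character(),
      fifo_role = readr::col_character(),
      shift_pattern = readr::col_character(),
      sleep_quality = readr::col_character(),
      smoking_status = readr::col_character(),
      k10_score = readr::col_integer(),
      auditc_score = readr::col_integer(),
      days_on = readr::col_integer(),
      days_off = readr::col_integer(),
      wpai_impairment_0_10 = readr::col_integer(),
      .default = readr::col_double()))
  missing_cols <- setdiff(worker_columns(), names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out[worker_columns()]
}

#' @rdname write_cohort
#' @param config A [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  out$effect_sizes <- as.data.frame(out$effect_sizes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
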