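#' FIFO role categories
#'
#' The seven job-role categories used for the workforce, management being
#' the reference level in regressions.
#'
#' @return Character vector of the seven levels.
#' @export
fifo_role_levels <- function() {
  c("management", "professional", "maintenance", "production",
    "machinery", "catering", "other")
}

adjustment_covariates <- function() {
  c("age", "gender", "fifo_role", "shift_pattern", "shift_hours",
    "days_on", "days_off", "fifo_years")
}

prepare_model_data <- function(data) {
  needed <- c(adjustment_covariates(), risk_conditions(), "risk_tier")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("model data is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data$gender <- factor(data$gender, levels = c("male", "female"))
  data$fifo_role <- factor(data$fifo_role, levels = fifo_role_levels())
  data$shift_pattern <- factor(data$shift_pattern,
                               levels = c("rotation", "regular"))
  data$risk_tier <- factor(data$risk_tier,
                           levels = c("low", "medium", "high"))
  data
}

model_formula <- function(outcome_col) {
  as.formula(paste(
    outcome_col, "~",
    paste(c(adjustment_covariates(), risk_conditions(), "risk_tier"),
          collapse = " + ")))
}

check_full_rank <- function(fit) {
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al) > 0) {
    abort(paste0("design matrix is rank deficient; collinear terms: ",
                 paste(rownames(al), collapse = ", ")))
  }
  invisible(fit)
}

#' Covariate-adjusted excess-loss regression
#'
#' Ordinary least squares on the percentage loss scale:
#' `loss ~ age + gender + FIFO role + shift pattern + shift hours +
#' consecutive days at work + consecutive days at home + years in FIFO +
#' the eight condition flags + multiple-risk tier`. The eight condition
#' coefficients are the covariate-adjusted excess losses (in percentage
#' points) that feed the per-1000-worker costing.
#'
#' @param data Complete-case worker table containing the covariates, the
#'   condition flags and the loss columns (scored risks joined to scored
#'   losses, as assembled by [adjusted_cost_table()] or [run_pipeline()]).
#' @param outcome One of `"absenteeism"`, `"presenteeism"`, `"total"`.
#' @return An object of class `"adjusted_excess_fit"`: a list with the
#'   underlying `lm` fit, `outcome` and `n`. Methods: [tidy()], [glance()],
#'   [adjusted_excess()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_workers = 300, seed = 1))
#' data <- dplyr::inner_join(score_risks(cohort), score_wpai(cohort),
#'                           by = "worker_id")
#' fit <- fit_adjusted_excess(data, "total")
#' adjusted_excess(fit)
fit_adjusted_excess <- function(data, outcome = loss_measures()) {
  outcome <- match.arg(outcome)
  data <- prepare_model_data(data)
  outcome_col <- loss_column(outcome)
  if (!outcome_col %in% names(data)) {
    abort(paste0("model data is missing the outcome column ", outcome_col))
  }
  data <- data[complete.cases(data[c(adjustment_covariates(),
                                     risk_conditions(), "risk_tier",
                                     outcome_col)]), ]
  n_terms <- length(adjustment_covariates()) + length(risk_conditions()) + 1
  if (nrow(data) <= n_terms + 10) {
    abort("too few complete cases to fit the adjusted model")
  }
  fit <- lm(model_formula(outcome_col), data = data)
  check_full_rank(fit)
  structure(list(fit = fit, outcome = outcome, n = nrow(data)),
            class = "adjusted_excess_fit")
}

#' Extract adjusted excess losses from a fitted model
#'
#' @param x An `"adjusted_excess_fit"` from [fit_adjusted_excess()].
#' @return A tibble with one row per condition: `condition`,
#'   `adjusted_excess` (coefficient, percentage points), `se`, `p_value`.
#' @export
adjusted_excess <- function(x) {
  stopifnot(inherits(x, "adjusted_excess_fit"))
  sm <- summary(x$fit)$coefficients
  terms <- paste0(risk_conditions(), "TRUE")
  found <- terms %in% rownames(sm)
  if (!all(found)) {
    abort(paste0("condition coefficients missing from fit: ",
                 paste(risk_conditions()[!found], collapse = ", ")))
  }
  tibble(condition = risk_conditions(),
         adjusted_excess = sm[terms, "Estimate"],
         se = sm[terms, "Std. Error"],
         p_value = sm[terms, "Pr(>|t|)"])
}

#' @exportS3Method generics::tidy
tidy.adjusted_excess_fit <- function(x, conf.level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  zq <- stats::qt(1 - (1 - conf.level) / 2, df = x$fit$df.residual)
  tibble(term = rownames(sm),
         estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"],
         statistic = sm[, "t value"],
         p.value = sm[, "Pr(>|t|)"],
         conf.low = sm[, "Estimate"] - zq * sm[, "Std. Error"],
         conf.high = sm[, "Estimate"] + zq * sm[, "Std. Error"])
}

#' @exportS3Method generics::glance
glance.adjusted_excess_fit <- function(x, ...) {
  sm <- summary(x$fit)
  f <- sm$fstatistic
  tibble(r.squared = sm$r.squared,
         adj.r.squared = sm$adj.r.squared,
         statistic = unname(f[1]),
         df = unname(f[2]),
         df.residual = unname(f[3]),
         p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
         nobs = x$n,
         outcome = x$outcome)
}

#' @export
print.adjusted_excess_fit <- function(x, ...) {
  cat("Adjusted excess-loss model (", x$outcome, "), n = ", x$n, "\n",
      sep = "")
  print(adjusted_excess(x))
  invisible(x)
}

#' Two-part (hurdle) model of productivity loss predictors
#'
#' Part 1 is a multiple logistic regression for reporting any loss
#' (loss > 0) on the full sample; part 2 is an OLS regression of the loss
#' magnitude on the subsample with positive loss. Both parts use the same
#' covariates as [fit_adjusted_excess()]. Odds ratios are
#' `exp(coefficient)` with Wald confidence intervals. Variance inflation
#' factors are computed on the part-1 design matrix.
#'
#' @inheritParams fit_adjusted_excess
#' @param part2_transform Transform applied to the positive losses in part
#'   2: `"identity"` (default, percentage scale) or `"log"`.
#' @return An object of class `"two_part_fit"`: list with `part1` (glm),
#'   `part2` (lm), `outcome`, `n`, `n_positive`, `vif`,
#'   `part2_transform`, `separation` (logical flag). Methods: [tidy()],
#'   [glance()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_workers = 500, seed = 1))
#' data <- dplyr::inner_join(score_risks(cohort), score_wpai(cohort),
#'                           by = "worker_id")
#' fit <- fit_two_part(data, "presenteeism")
#' tidy(fit)
#' glance(fit)
fit_two_part <- function(data, outcome = loss_measures(),
                         part2_transform = c("identity", "log")) {
  outcome <- match.arg(outcome)
  part2_transform <- match.arg(part2_transform)
  data <- prepare_model_data(data)
  outcome_col <- loss_column(outcome)
  data <- data[complete.cases(data[c(adjustment_covariates(),
                                     risk_conditions(), "risk_tier",
                                     outcome_col)]), ]
  y <- data[[outcome_col]]
  if (all(y == 0)) abort("outcome is all zero: part 1 is not estimable")
  if (all(y > 0)) abort("outcome is all positive: part 1 is not estimable")
  data$.any_loss <- as.integer(y > 0)
  f1 <- as.formula(paste(
    ".any_loss ~",
    paste(c(adjustment_covariates(), risk_conditions(), "risk_tier"),
          collapse = " + ")))
  part1 <- glm(f1, data = data, family = binomial())
  separation <- any(abs(coef(part1)[-1]) > 15, na.rm = TRUE) ||
    any(part1$fitted.values < 1e-10 | part1$fitted.values > 1 - 1e-10)
  if (separation) {
    warn("possible separation in the logistic part (extreme coefficients or fitted probabilities)")
  }
  pos <- data[y > 0, ]
  pos$.y2 <- switch(part2_transform,
                    identity = pos[[outcome_col]],
                    log = log(pos[[outcome_col]]))
  part2 <- lm(as.formula(paste(
    ".y2 ~",
    paste(c(adjustment_covariates(), risk_conditions(), "risk_tier"),
          collapse = " + "))), data = pos)
  mm <- model.matrix(part1)[, -1, drop = FALSE]
  keep <- apply(mm, 2, sd) > 0
  vifs <- vif(mm[, keep, drop = FALSE])
  structure(list(part1 = part1, part2 = part2, outcome = outcome,
                 n = nrow(data), n_positive = nrow(pos), vif = vifs,
                 part2_transform = part2_transform,
                 separation = separation),
            class = "two_part_fit")
}

#' @exportS3Method generics::tidy
tidy.two_part_fit <- function(x, exponentiate = TRUE, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  s1 <- summary(x$part1)$coefficients
  t1 <- tibble(part = "part1_logistic",
               term = rownames(s1),
               estimate = s1[, "Estimate"],
               std.error = s1[, "Std. Error"],
               statistic = s1[, "z value"],
               p.value = s1[, "Pr(>|z|)"],
               conf.low = s1[, "Estimate"] - z * s1[, "Std. Error"],
               conf.high = s1[, "Estimate"] + z * s1[, "Std. Error"])
  if (exponentiate) {
    t1 <- dplyr::mutate(t1,
                        estimate = exp(.data$estimate),
                        conf.low = exp(.data$conf.low),
                        conf.high = exp(.data$conf.high))
  }
  s2 <- summary(x$part2)$coefficients
  tq <- stats::qt(1 - (1 - conf.level) / 2, df = x$part2$df.residual)
  t2 <- tibble(part = "part2_ols",
               term = rownames(s2),
               estimate = s2[, "Estimate"],
               std.error = s2[, "Std. Error"],
               statistic = s2[, "t value"],
               p.value = s2[, "Pr(>|t|)"],
               conf.low = s2[, "Estimate"] - tq * s2[, "Std. Error"],
               conf.high = s2[, "Estimate"] + tq * s2[, "Std. Error"])
  dplyr::bind_rows(t1, t2)
}

#' @exportS3Method generics::glance
glance.two_part_fit <- function(x, ...) {
  ll <- as.numeric(logLik(x$part1))
  null_dev <- x$part1$null.deviance
  pseudo_r2 <- 1 - x$part1$deviance / null_dev
  sm2 <- summary(x$part2)
  f <- sm2$fstatistic
  tibble(outcome = x$outcome,
         n = x$n,
         n_positive = x$n_positive,
         log_lik_part1 = ll,
         pseudo_r2_part1 = pseudo_r2,
         f_statistic_part2 = unname(f[1]),
         f_p_value_part2 = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
         adj_r_squared_part2 = sm2$adj.r.squared,
         max_vif = max(x$vif),
         separation = x$separation)
}

#' @export
print.two_part_fit <- function(x, ...) {
  cat("Two-part model (", x$outcome, "): n = ", x$n, ", positive = ",
      x$n_positive, "\n", sep = "")
  print(glance(x))
  invisible(x)
}
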