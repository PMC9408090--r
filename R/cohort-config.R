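#' Default high-risk prevalences for the synthetic cohort
#'
#' Marginal probabilities of each of the eight conditions in the emulated
#' FIFO mining workforce: poor sleep 64.4%, risky alcohol 34.3%, smoking
#' 26.4%, poor diet 96.3%, weight problem 74.5%, insufficient physical
#' activity 26.9%, poor physical health 8.8%, psychological distress 33.3%.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_risk_prevalence <- function() {
  c(poor_sleep = 0.644, risky_alcohol = 0.343, smoking = 0.264,
    poor_diet = 0.963, weight_problem = 0.745, insufficient_pa = 0.269,
    poor_physical_health = 0.088, psychological_distress = 0.333)
}

#' Default condition effect sizes for the synthetic cohort
#'
#' Per-condition effects on productivity loss, used by [generate_cohort()]:
#' a log-odds increment on each hurdle (the chance of reporting any
#' absenteeism / any presenteeism) and an additive increment on the positive
#' part (extra missed hours per 4 weeks; extra points on the latent 0-10
#' impairment rating). The defaults give the largest effects to poor
#' physical health, psychological distress and insufficient physical
#' activity, mirroring the ordering seen in FIFO workforce surveys.
#'
#' @param zero If `TRUE`, return an all-zero effect table (the null
#'   generator, useful for type-I-error and coverage simulations).
#' @return A tibble with columns `condition`, `logit_absenteeism`,
#'   `logit_presenteeism`, `pos_absenteeism`, `pos_presenteeism`.
#' @export
default_effect_sizes <- function(zero = FALSE) {
  out <- tibble(
    condition = risk_conditions(),
    logit_absenteeism  = c(0.30, 0.10, 0.10, 0.15, 0.10, 1.08, 2.11, 0.70),
    logit_presenteeism = c(0.50, 0.10, 0.50, 0.20, 0.20, 0.20, 1.64, 1.42),
    pos_absenteeism    = c(1.0, 0.5, 0.5, 1.0, 0.5, 3.0, 8.0, 5.0),
    pos_presenteeism   = c(0.50, 0.10, 0.50, 0.20, 0.20, 0.30, 1.50, 1.00)
  )
  if (zero) {
    out[-1] <- lapply(out[-1], function(x) rep(0, length(x)))
  }
  out
}

# Marginal P(any loss) under the latent-Gaussian copula for the flags:
# integrate over the shared factor w; flags are conditionally independent
# given w, so enumerate flag combinations for conditions with nonzero effect.
marginal_any_loss <- function(alpha, beta, prevalence, rho) {
  active <- which(beta != 0 & prevalence > 0 & prevalence < 1)
  base <- sum(beta[!is.na(prevalence) & prevalence == 1])  # always-on flags
  if (length(active) == 0) return(plogis(alpha + base))
  w <- seq(-6, 6, length.out = 121)
  wt <- stats::dnorm(w)
  wt <- wt / sum(wt)
  thr <- qnorm(prevalence[active])
  pw <- vapply(seq_along(active), function(j) {
    pnorm((thr[j] - sqrt(rho) * w) / sqrt(1 - rho))
  }, numeric(length(w)))                       # n_w x n_active
  combos <- as.matrix(expand.grid(rep(list(0:1), length(active))))
  lp <- plogis(alpha + base + drop(combos %*% beta[active]))  # 2^a
  total <- 0
  for (i in seq_along(w)) {
    p <- pw[i, ]
    combo_prob <- exp(combos %*% log(p) + (1 - combos) %*% log(1 - p))
    total <- total + wt[i] * sum(combo_prob * lp)
  }
  total
}

calibrate_hurdle_intercept <- function(target, beta, prevalence, rho) {
  uniroot(function(a) marginal_any_loss(a, beta, prevalence, rho) - target,
          interval = c(-15, 15), tol = 1e-10)$root
}

#' Configuration for the synthetic FIFO cohort generator
#'
#' Defines the statistical structure [generate_cohort()] draws from: the
#' marginal prevalence of each high-risk condition, a latent-Gaussian
#' equicorrelation between conditions, hurdle (zero-inflation) intercepts
#' for any-absenteeism and any-presenteeism, per-condition effect sizes, and
#' the positive-loss distributions. Defaults emulate the margins of a
#' surveyed FIFO mining workforce: the default condition prevalences, 20.4% of
#' workers reporting any absenteeism and 53.7% any presenteeism, and
#' positive missed hours averaging about 16 h (sd 20) per 4 weeks.
#'
#' When `hurdle_intercepts` is `NULL` (the default) the intercepts are
#' calibrated analytically -- by integrating the hurdle probability over the
#' latent risk-flag copula -- so the marginal any-loss probabilities equal
#' `any_loss_target` under the configured prevalences and effect sizes.
#'
#' @param n_workers Number of workers to generate (>= 1). Default 216.
#' @param seed Integer seed; identical `(config, seed)` pairs reproduce
#'   identical cohorts. `NULL` uses the current RNG state.
#' @param risk_prevalence Named probability vector over
#'   [risk_conditions()]. Default [default_risk_prevalence()].
#' @param risk_correlation Pairwise latent correlation between condition
#'   flags, in \[0, 1). Default 0.2.
#' @param effect_sizes Tibble as returned by [default_effect_sizes()].
#' @param hurdle_intercepts Named vector `c(absenteeism =, presenteeism =)`
#'   of log-odds intercepts, or `NULL` to calibrate to `any_loss_target`.
#' @param any_loss_target Marginal probabilities of any absenteeism /
#'   presenteeism used for calibration. Default `c(0.204, 0.537)`.
#' @param hours_contract Scheduled work hours per 4 weeks. `NULL` (default)
#'   derives it per worker from the roster: shift hours x days on x 28 /
#'   (days on + days off), i.e. about 192 h for a 12-h, 8-on/6-off roster.
#' @param missed_hours_mean,missed_hours_sd Mean and sd of the positive
#'   missed-hours distribution (lognormal truncated to \[1,
#'   hours_contract\]) per 4 weeks. Defaults 16 and 20.
#' @param base_rating Latent mean of the positive 0-10 impairment rating
#'   before condition effects. Default 1.8.
#' @param noise_sd Sd of the latent impairment noise. Default 1.5.
#' @return A list with class `"cohort_config"`, with calibrated
#'   `hurdle_intercepts` filled in.
#' @export
#' @examples
#' cfg <- cohort_config(n_workers = 216, seed = 42)
#' cfg$hurdle_intercepts
cohort_config <- function(n_workers = 216,
                          seed = NULL,
                          risk_prevalence = default_risk_prevalence(),
                          risk_correlation = 0.2,
                          effect_sizes = default_effect_sizes(),
                          hurdle_intercepts = NULL,
                          any_loss_target = c(absenteeism = 0.204,
                                              presenteeism = 0.537),
                          hours_contract = NULL,
                          missed_hours_mean = 16,
                          missed_hours_sd = 20,
                          base_rating = 1.8,
                          noise_sd = 1.5) {
  if (!is.numeric(n_workers) || length(n_workers) != 1 || n_workers < 1 ||
      n_workers != round(n_workers)) {
    abort("`n_workers` must be a positive whole number")
  }
  conds <- risk_conditions()
  if (!all(conds %in% names(risk_prevalence))) {
    abort("`risk_prevalence` must name all eight conditions")
  }
  risk_prevalence <- risk_prevalence[conds]
  if (any(risk_prevalence < 0 | risk_prevalence > 1)) {
    abort("`risk_prevalence` values must be probabilities in [0, 1]")
  }
  if (risk_correlation < 0 || risk_correlation >= 1) {
    abort("`risk_correlation` must be in [0, 1)")
  }
  effect_sizes <- as_tibble(effect_sizes)
  eff_cols <- c("logit_absenteeism", "logit_presenteeism",
                "pos_absenteeism", "pos_presenteeism")
  if (!all(c("condition", eff_cols) %in% names(effect_sizes)) ||
      !setequal(effect_sizes$condition, conds)) {
    abort("`effect_sizes` must have one row per condition with columns condition, logit_absenteeism, logit_presenteeism, pos_absenteeism, pos_presenteeism")
  }
  effect_sizes <- effect_sizes[match(conds, effect_sizes$condition), ]
  if (any(effect_sizes$pos_absenteeism < 0) ||
      any(effect_sizes$pos_presenteeism < 0)) {
    abort("positive-part effect sizes must be non-negative")
  }
  if (!is.null(hours_contract) &&
      (!is.numeric(hours_contract) || hours_contract <= 0)) {
    abort("`hours_contract` must be positive")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive")
  if (any(any_loss_target <= 0 | any_loss_target >= 1)) {
    abort("`any_loss_target` must be strictly inside (0, 1)")
  }
  if (is.null(hurdle_intercepts)) {
    hurdle_intercepts <- c(
      absenteeism = calibrate_hurdle_intercept(
        any_loss_target[["absenteeism"]],
        setNames(effect_sizes$logit_absenteeism, conds),
        risk_prevalence, risk_correlation),
      presenteeism = calibrate_hurdle_intercept(
        any_loss_target[["presenteeism"]],
        setNames(effect_sizes$logit_presenteeism, conds),
        risk_prevalence, risk_correlation))
  } else if (!all(c("absenteeism", "presenteeism") %in%
                  names(hurdle_intercepts))) {
    abort("`hurdle_intercepts` must name absenteeism and presenteeism")
  }
  structure(list(n_workers = as.integer(n_workers),
                 seed = seed,
                 risk_prevalence = risk_prevalence,
                 risk_correlation = risk_correlation,
                 effect_sizes = effect_sizes,
                 hurdle_intercepts = hurdle_intercepts,
                 any_loss_target = any_loss_target,
                 hours_contract = hours_contract,
                 missed_hours_mean = missed_hours_mean,
                 missed_hours_sd = missed_hours_sd,
                 base_rating = base_rating,
                 noise_sd = noise_sd),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration: n =", x$n_workers,
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  cat("  hurdle intercepts:",
      sprintf("absenteeism %.3f, presenteeism %.3f",
              x$hurdle_intercepts[["absenteeism"]],
              x$hurdle_intercepts[["presenteeism"]]), "\n")
  cat("  latent risk correlation:", x$risk_correlation, "\n")
  invisible(x)
}
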