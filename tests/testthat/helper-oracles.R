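# Independent oracles, deliberately written from the definitions rather than
# reusing any package internals.

# WPAI formulas in integer (rational) arithmetic: for whole hours m, w and an
# integer rating r, both percentages are ratios of integers.
oracle_absenteeism <- function(m, w) (100 * m) / (m + w)
oracle_total_loss <- function(m, w, r) (100 * m + 10 * w * r) / (m + w)

# Exhaustive-permutation Mann-Whitney: statistic = rank sum of group 1 over
# all C(n, n1) assignments; two-sided p = share of assignments at least as
# extreme as observed.
oracle_mw_permutation <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  expected <- n1 * (length(pooled) + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  stats <- apply(idx, 2, function(i) sum(r[i]))
  mean(abs(stats - expected) >= abs(obs - expected) - 1e-9)
}

# Hand-ranked tie-corrected Kruskal-Wallis H.
oracle_kw_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(groups)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Dunn pairwise z for two named groups, from the mean-rank definition.
oracle_dunn_z <- function(values, groups, g1, g2) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  sigma2 <- (n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1)))
  m1 <- mean(r[groups == g1])
  m2 <- mean(r[groups == g2])
  (m1 - m2) / sqrt(sigma2 * (1 / sum(groups == g1) + 1 / sum(groups == g2)))
}

# Worker rows whose raw instrument responses realise a given flag
# combination exactly (used to exercise score_risks end to end).
records_for_flags <- function(flags) {
  n <- nrow(flags)
  tibble::tibble(
    worker_id = sprintf("F%03d", seq_len(n)),
    gender = "male",
    k10_score = ifelse(flags[, "psychological_distress"], 22L, 10L),
    pcs_score = ifelse(flags[, "poor_physical_health"], 40, 60),
    sleep_hours = ifelse(flags[, "poor_sleep"], 6, 8),
    sleep_quality = "good",
    auditc_score = ifelse(flags[, "risky_alcohol"], 4L, 0L),
    smoking_status = ifelse(flags[, "smoking"], "current", "never"),
    met_minutes = ifelse(flags[, "insufficient_pa"], 300, 1200),
    height_m = 1.8,
    weight_kg = ifelse(flags[, "weight_problem"], 27, 22) * 1.8^2,
    fruit_serves = ifelse(flags[, "poor_diet"], 0, 3),
    veg_serves = ifelse(flags[, "poor_diet"], 0, 6)
  )
}

# A generator configuration with one known active effect and a latent
# impairment scale kept far from the 0/10 clamps, for clean parameter
# recovery: part-1 true log-odds = 0.8 and part-2 true increment = 10
# percentage points for poor physical health, all else null.
recovery_config <- function(n_workers, seed) {
  eff <- default_effect_sizes(zero = TRUE)
  eff$logit_presenteeism[eff$condition == "poor_physical_health"] <- 0.8
  eff$pos_presenteeism[eff$condition == "poor_physical_health"] <- 1.0
  cohort_config(
    n_workers = n_workers, seed = seed, effect_sizes = eff,
    hurdle_intercepts = c(absenteeism = qlogis(0.204),
                          presenteeism = qlogis(0.45)),
    base_rating = 5, noise_sd = 1
  )
}
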