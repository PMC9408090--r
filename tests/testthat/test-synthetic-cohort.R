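test_that("identical (config, seed) pairs reproduce identical cohorts", {
  cfg <- cohort_config(n_workers = 150, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_workers = 150, seed = 100))
  expect_false(identical(a, c))
})

test_that("configuration validation rejects invalid settings", {
  expect_error(cohort_config(n_workers = 0), "positive")
  prev <- default_risk_prevalence()
  prev["smoking"] <- 1.2
  expect_error(cohort_config(risk_prevalence = prev), "probabilities")
  expect_error(cohort_config(risk_correlation = 1), "1")
  expect_error(cohort_config(noise_sd = 0), "positive")
  expect_error(cohort_config(hours_contract = -5), "positive")
})

test_that("classified prevalences converge to the configured targets", {
  cohort <- generate_cohort(cohort_config(n_workers = 20000, seed = 3))
  prev <- prevalence_table(score_risks(cohort))
  target <- 100 * default_risk_prevalence()[prev$condition]
  expect_true(all(abs(prev$prevalence_pct - target) < 1))
})

test_that("a degenerate prevalence of 1 gives 100% classified prevalence", {
  prev <- default_risk_prevalence()
  prev["smoking"] <- 1
  cohort <- generate_cohort(cohort_config(n_workers = 200, seed = 8,
                                          risk_prevalence = prev))
  tab <- prevalence_table(score_risks(cohort))
  expect_equal(tab$prevalence_pct[tab$condition == "smoking"], 100)
})

test_that("zero-loss fractions match the hurdle intercepts when effects are null", {
  cfg <- cohort_config(
    n_workers = 30000, seed = 17,
    effect_sizes = default_effect_sizes(zero = TRUE),
    hurdle_intercepts = c(absenteeism = qlogis(0.204),
                          presenteeism = qlogis(0.537)))
  cohort <- generate_cohort(cfg)
  zero_abs <- mean(cohort$wpai_hours_missed_4w == 0)
  zero_pres <- mean(cohort$wpai_impairment_0_10 == 0)
  expect_equal(zero_abs, 1 - 0.204, tolerance = 0.01 / 0.796)
  expect_equal(zero_pres, 1 - 0.537, tolerance = 0.012 / 0.463)
})

test_that("null effect sizes leave loss unassociated with the risk count", {
  cfg <- cohort_config(n_workers = 10000, seed = 23,
                       effect_sizes = default_effect_sizes(zero = TRUE))
  cohort <- generate_cohort(cfg)
  profiles <- score_risks(cohort)
  losses <- score_wpai(cohort)
  d <- dplyr::inner_join(profiles, losses, by = "worker_id")
  expect_lt(abs(stats::cor(d$risk_count, d$total_loss_pct)), 0.05)
})

test_that("increasing a positive-part effect strictly increases flagged workers' loss", {
  means <- vapply(c(0.5, 1.5, 3), function(effect) {
    eff <- default_effect_sizes(zero = TRUE)
    eff$pos_presenteeism[eff$condition == "poor_sleep"] <- effect
    cfg <- cohort_config(n_workers = 8000, seed = 31, effect_sizes = eff,
                         hurdle_intercepts = c(absenteeism = qlogis(0.204),
                                               presenteeism = qlogis(0.537)),
                         base_rating = 4, noise_sd = 1)
    cohort <- generate_cohort(cfg)
    flag <- attr(cohort, "intended_flags")$poor_sleep
    losses <- score_wpai(cohort)
    y <- losses$presenteeism_pct[match(cohort$worker_id, losses$worker_id)]
    mean(y[flag])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("positive missed hours stay within [1, contract] and track the target moments", {
  cohort <- generate_cohort(cohort_config(
    n_workers = 30000, seed = 41,
    effect_sizes = default_effect_sizes(zero = TRUE)))
  missed <- cohort$wpai_hours_missed_4w
  pos <- missed[missed > 0]
  hc <- cohort$wpai_hours_missed_4w + cohort$wpai_hours_worked_4w
  expect_true(all(pos >= 1))
  expect_true(all(missed <= hc))
  # truncation pulls the lognormal mean slightly below its nominal 16
  expect_equal(mean(pos), 16, tolerance = 0.15)
  expect_equal(sd(pos), 20, tolerance = 0.35)
})

test_that("margins report covers prevalences and loss moments", {
  m <- margins_report(generate_cohort(cohort_config(n_workers = 500,
                                                    seed = 2)))
  expect_true(all(paste0("prevalence_pct_", risk_conditions()) %in%
                    m$metric))
  expect_true(all(c("any_absenteeism_pct", "any_presenteeism_pct",
                    "total_loss_mean") %in% m$metric))
  expect_error(margins_report(generate_cohort(
    cohort_config(n_workers = 1, seed = 1))[0, ]), "empty")
})

test_that("cohort CSV round-trips through write and read", {
  cohort <- generate_cohort(cohort_config(n_workers = 40, seed = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  attr(cohort, "intended_flags") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(cohort[names(back)]),
               tolerance = 1e-9)
  cfg_path <- withr::local_tempfile(fileext = ".json")
  write_cohort_config(cohort_config(n_workers = 40, seed = 13), cfg_path)
  stored <- jsonlite::read_json(cfg_path)
  expect_equal(stored$seed, 13)
  expect_equal(stored$n_workers, 40)
})
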