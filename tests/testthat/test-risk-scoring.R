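test_that("each classifier flips exactly at its screening threshold", {
  expect_equal(classify_psychological_distress(c(10, 21, 22, 50)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(classify_physical_health(c(0, 49.9, 50, 100)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(
    classify_sleep(c(6.5, 8, 7, 6.99),
                   c("very good", "fairly bad", "good", "good")),
    c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(
    classify_alcohol(c(4, 3, 3, 2, 12), c("male", "male", "female",
                                          "female", "male")),
    c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(classify_smoking(c("current", "previous", "never")),
               c(TRUE, FALSE, FALSE))
  expect_equal(classify_physical_activity(c(599, 600, 0)),
               c(TRUE, FALSE, TRUE))
  expect_equal(classify_weight(c(25, 18.5, 18.49, 24.99, 30)),
               c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(classify_diet(c(2, 3, 0, 1.9), c(5, 4, 0, 5)),
               c(FALSE, TRUE, TRUE, TRUE))
})

test_that("out-of-range instrument values are rejected", {
  expect_error(classify_psychological_distress(9), "10")
  expect_error(classify_psychological_distress(51), "10")
  expect_error(classify_physical_health(101), "0")
  expect_error(classify_sleep(-1, "good"), "non-negative")
  expect_error(classify_sleep(8, "terrible"), "one of")
  expect_error(classify_alcohol(13, "male"), "12")
  expect_error(classify_smoking("sometimes"), "one of")
  expect_error(bmi(0, 1.8), "positive")
  expect_error(classify_diet(-1, 5), "non-negative")
  expect_error(ipaq_met_minutes("moderate", 8, 30), "7")
  expect_error(ipaq_met_minutes("sprinting", 3, 30), "one of")
})

test_that("IPAQ MET-minutes are the sum of weighted activity products", {
  expect_equal(ipaq_met_minutes(character(), numeric(), numeric()), 0)
  expect_equal(ipaq_met_minutes("moderate", 5, 30), 600)
  expect_equal(ipaq_met_minutes(c("walking", "vigorous"), c(7, 2),
                                c(10, 20)), 551)
})

test_that("BMI arithmetic places the example worker just inside the healthy band", {
  b <- bmi(80, 1.79)
  expect_equal(b, 80 / 1.79^2)
  expect_lt(b, 25)
  expect_false(classify_weight(b))
})

test_that("risk count and tier are consistent over all 256 flag combinations", {
  flags <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 8)))
  colnames(flags) <- risk_conditions()
  profiles <- score_risks(records_for_flags(flags))
  for (cond in risk_conditions()) {
    expect_equal(profiles[[cond]], unname(flags[, cond]))
  }
  counts <- rowSums(flags)
  expect_equal(profiles$risk_count, as.integer(counts))
  expect_equal(as.character(profiles$risk_tier),
               ifelse(counts <= 2, "low",
                      ifelse(counts <= 4, "medium", "high")))
  # tier mapping is total and non-overlapping over 0..8
  expect_equal(as.character(risk_tier(0:8)),
               c(rep("low", 3), rep("medium", 2), rep("high", 4)))
})

test_that("incomplete records get NA flags and are excluded from prevalence", {
  cohort <- generate_cohort(cohort_config(n_workers = 30, seed = 5))
  cohort$k10_score[3] <- NA
  cohort$pcs_score[7] <- NA
  profiles <- score_risks(cohort)
  expect_equal(attr(profiles, "n_incomplete"), 2)
  expect_true(all(profiles$incomplete[c(3, 7)]))
  expect_true(is.na(profiles$risk_count[3]))
  prev <- prevalence_table(profiles)
  expect_true(all(prev$n == 28))
})

test_that("prevalence percentages reproduce frequency/total arithmetic", {
  flags <- matrix(FALSE, 216, 8, dimnames = list(NULL, risk_conditions()))
  flags[seq_len(139), "poor_sleep"] <- TRUE
  flags[seq_len(19), "poor_physical_health"] <- TRUE
  prev <- prevalence_table(score_risks(records_for_flags(flags)))
  expect_equal(prev$prevalence_pct[prev$condition == "poor_sleep"],
               100 * 139 / 216)
  expect_equal(round(prev$prevalence_pct[prev$condition == "poor_sleep"], 1),
               64.4)
  expect_equal(
    round(prev$prevalence_pct[prev$condition == "poor_physical_health"], 1),
    8.8)
  all_false <- prevalence_table(
    score_risks(records_for_flags(
      matrix(FALSE, 5, 8, dimnames = list(NULL, risk_conditions())))))
  expect_true(all(all_false$prevalence_pct == 0))
})

test_that("classifier output reproduces generator-intended flags for every worker", {
  cohort <- generate_cohort(cohort_config(n_workers = 2000, seed = 11))
  intended <- attr(cohort, "intended_flags")
  profiles <- score_risks(cohort)
  for (cond in risk_conditions()) {
    expect_equal(profiles[[cond]], intended[[cond]])
  }
})
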