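test_that("recall rescaling divides 4-week hours by 4", {
  expect_equal(rescale_recall(0), 0)
  expect_equal(rescale_recall(16.07), 4.0175)
  expect_equal(rescale_recall(96), 24)
  expect_error(rescale_recall(-1), "non-negative")
})

test_that("loss formulas reproduce their worked examples", {
  expect_equal(wpai_absenteeism(0, 42), 0)
  expect_equal(wpai_absenteeism(14, 28), 100 / 3)
  expect_equal(wpai_absenteeism(42, 0), 100)
  expect_true(is.na(wpai_absenteeism(0, 0)))

  expect_equal(wpai_presenteeism(c(0L, 10L, 2L)), c(0, 100, 20))
  expect_error(wpai_presenteeism(11), "10")
  expect_error(wpai_presenteeism(2.5), "whole")

  expect_equal(wpai_total_loss(0, 37), 37)
  expect_equal(wpai_total_loss(100, 60), 100)
  expect_equal(wpai_total_loss(100 / 3, 20), 140 / 3)
})

test_that("loss formulas match the rational-arithmetic oracle", {
  withr::local_seed(404)
  m <- sample(0:96, 2000, replace = TRUE)
  w <- sample(0:96, 2000, replace = TRUE)
  keep <- m + w > 0
  m <- m[keep]; w <- w[keep]
  r <- sample(0:10, length(m), replace = TRUE)
  a <- wpai_absenteeism(m, w)
  expect_equal(a, oracle_absenteeism(m, w), tolerance = 1e-12)
  expect_equal(wpai_total_loss(a, wpai_presenteeism(r)),
               oracle_total_loss(m, w, r), tolerance = 1e-12)
})

test_that("total loss respects its bounds and monotonicity on a grid", {
  grid <- expand.grid(a = seq(0, 100, 5), p = seq(0, 100, 5))
  total <- wpai_total_loss(grid$a, grid$p)
  expect_true(all(total >= pmax(grid$a, grid$p) - 1e-9))
  expect_true(all(total <= pmin(grid$a + grid$p, 100) + 1e-9))
  expect_equal(wpai_total_loss(grid$a, 0), grid$a)
  expect_equal(wpai_total_loss(0, grid$p), grid$p)
  # monotone non-decreasing in each argument
  for (p in c(0, 40, 100)) {
    expect_true(all(diff(wpai_total_loss(seq(0, 100, 5), p)) >= -1e-9))
  }
  for (a in c(0, 40, 100)) {
    expect_true(all(diff(wpai_total_loss(a, seq(0, 100, 5))) >= -1e-9))
  }
})

test_that("absenteeism is invariant to rescaling both hour inputs", {
  m <- c(3, 10, 25)
  w <- c(40, 30, 75)
  for (c_scale in c(0.5, 2, 7.3)) {
    expect_equal(wpai_absenteeism(c_scale * m, c_scale * w),
                 wpai_absenteeism(m, w))
  }
})

test_that("score_wpai reproduces the single-worker worked example", {
  worker <- tibble::tibble(worker_id = "w1", wpai_hours_missed_4w = 14,
                           wpai_hours_worked_4w = 154,
                           wpai_impairment_0_10 = 3L)
  loss <- score_wpai(worker)
  expect_equal(loss$hours_missed_wk, 3.5)
  expect_equal(loss$hours_worked_wk, 38.5)
  expect_equal(loss$absenteeism_pct, 100 / 12)
  expect_equal(loss$presenteeism_pct, 30)
  expect_equal(loss$total_loss_pct, 100 * (1 / 12 + (11 / 12) * 0.3))
  expect_equal(round(loss$total_loss_pct, 2), 35.83)
})

test_that("score_wpai excludes and counts workers with no defined loss", {
  cohort <- tibble::tibble(
    worker_id = c("a", "b", "c"),
    wpai_hours_missed_4w = c(0, 0, 8),
    wpai_hours_worked_4w = c(160, 0, 152),
    wpai_impairment_0_10 = c(0L, 0L, 4L))
  loss <- score_wpai(cohort)
  expect_equal(nrow(loss), 2)
  expect_equal(attr(loss, "n_undefined"), 1)
  expect_false("b" %in% loss$worker_id)
})

test_that("cohort summary reports zero-loss shares on the frequency scale", {
  n <- 216
  cohort <- tibble::tibble(
    worker_id = sprintf("w%03d", seq_len(n)),
    wpai_hours_missed_4w = c(rep(8, 44), rep(0, n - 44)),
    wpai_hours_worked_4w = 160,
    wpai_impairment_0_10 = 0L)
  s <- wpai_summary(score_wpai(cohort))
  expect_equal(s$any_absenteeism_pct, 100 * 44 / 216)
  expect_equal(round(s$any_absenteeism_pct, 1), 20.4)
  expect_equal(s$any_presenteeism_pct, 0)
  expect_equal(s$presenteeism_mean, 0)

  all_zero <- tibble::tibble(worker_id = "z", wpai_hours_missed_4w = 0,
                             wpai_hours_worked_4w = 100,
                             wpai_impairment_0_10 = 0L)
  s0 <- wpai_summary(score_wpai(all_zero))
  expect_equal(s0$absenteeism_mean, 0)
  expect_equal(s0$total_loss_mean, 0)
})
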