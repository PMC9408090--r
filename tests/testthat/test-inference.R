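test_that("Mann-Whitney matches its definition and sign convention", {
  # identical groups: no evidence of a difference
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-6)

  # fully separated with the high group smaller: U = 0, z positive
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_high, 0)
  expect_gt(mw$z, 0)
  # high group stochastically larger reports negative z
  expect_lt(mann_whitney(c(4, 5, 6), c(1, 2, 3))$z, 0)

  # normal-approximation p agrees with the exhaustive permutation p at
  # small n (approximation error only)
  p_perm <- oracle_mw_permutation(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p_perm, 2 / 20)
  expect_lt(abs(mw$p_value - p_perm), 0.06)
})

test_that("Mann-Whitney p equals the tie-corrected normal approximation of wilcox.test", {
  withr::local_seed(71)
  for (i in 1:20) {
    x <- sample(0:5, sample(4:12, 1), replace = TRUE)
    y <- sample(0:5, sample(4:12, 1), replace = TRUE)
    ours <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("rank tests match exhaustive/hand-ranked oracles for all small inputs", {
  withr::local_seed(90)
  abs_z <- c()
  p_perm <- c()
  for (i in 1:40) {
    n <- sample(4:8, 1)
    n1 <- sample(2:(n - 2), 1)
    vals <- sample(0:3, n, replace = TRUE)
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    if (length(unique(c(x, y))) == 1) next
    ours <- mann_whitney(x, y)
    # U statistic from the pair-counting definition
    u_def <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(ours$u_high, u_def)
    abs_z <- c(abs_z, abs(ours$z))
    p_perm <- c(p_perm, oracle_mw_permutation(x, y))

    g <- sample(rep(c("a", "b", "c"), length.out = n))
    if (min(table(g)) == 0) next
    kw <- kruskal_wallis(vals, g)
    expect_equal(kw$h, oracle_kw_h(vals, g), tolerance = 1e-10)
  }
  # the normal approximation cannot equal the exact permutation p at these
  # sizes, but it must order the evidence the same way
  expect_lt(stats::cor(abs_z, p_perm, method = "spearman"), -0.85)
})

test_that("Kruskal-Wallis handles identical and ordered groups", {
  same <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(same$h, 3)
  exact <- kruskal_wallis(c(1, 2, 3, 4, 5, 6),
                          rep(c("a", "b", "c"), each = 2))
  expect_equal(exact$h, oracle_kw_h(c(1, 2, 3, 4, 5, 6),
                                    rep(c("a", "b", "c"), each = 2)))
  expect_equal(exact$df, 2)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2")
})

test_that("Dunn-Bonferroni adjusts pairwise mean-rank tests by the pair count", {
  vals <- c(1, 2, 3, 4, 8, 9, 10, 2, 3)
  grp <- rep(c("low", "medium", "high"), each = 3)
  d <- dunn_bonferroni(vals, grp)
  expect_equal(nrow(d), 3)
  expect_equal(d$p_adjusted, pmin(1, d$p_value * 3))
  expect_true(all(d$p_adjusted >= d$p_value))
  for (i in seq_len(nrow(d))) {
    expect_equal(d$z[i], oracle_dunn_z(vals, grp, d$group1[i], d$group2[i]),
                 tolerance = 1e-10)
  }
  flat <- dunn_bonferroni(rep(c(1, 2), 6), rep(c("a", "b", "c"), 4))
  expect_true(all(flat$p_adjusted == 1))
})

test_that("rank tests detect an injected distress-sized presenteeism gap at survey scale", {
  eff <- default_effect_sizes(zero = TRUE)
  eff$logit_presenteeism[eff$condition == "psychological_distress"] <- 1.4
  eff$pos_presenteeism[eff$condition == "psychological_distress"] <- 1.2
  hits <- 0
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(n_workers = 216, seed = 5000 + s,
                         effect_sizes = eff)
    cohort <- generate_cohort(cfg)
    flag <- attr(cohort, "intended_flags")$psychological_distress
    loss <- score_wpai(cohort)
    y <- loss$presenteeism_pct[match(cohort$worker_id, loss$worker_id)]
    p <- mann_whitney(y[flag], y[!flag])$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("VIF matches the closed form and flags rank deficiency", {
  withr::local_seed(33)
  n <- 5000
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  v <- vif(cbind(a = x1, b = x2))
  r2 <- stats::cor(x1, x2)^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-10)
  expect_equal(unname(v), rep(5.26, 2), tolerance = 0.3)

  ortho <- qr.Q(qr(cbind(1, matrix(rnorm(300), 100, 3))))[, -1]
  expect_equal(unname(vif(ortho)), rep(1, 3), tolerance = 1e-8)

  dup <- cbind(x1, x1, rnorm(n))
  expect_true(any(is.infinite(vif(dup))))
})

test_that("VIF agrees with the car package on a continuous design", {
  skip_if_not_installed("car")
  withr::local_seed(12)
  d <- data.frame(y = rnorm(200), a = rnorm(200), b = rnorm(200))
  d$c <- 0.5 * d$a + rnorm(200)
  fit <- lm(y ~ a + b + c, data = d)
  expect_equal(unname(vif(as.matrix(d[c("a", "b", "c")]))),
               unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("adjusted excess regression recovers known generator effects", {
  # zero hurdle effects keep E[loss | flags] linear in the flags, with
  # known slope P(any) x 10 x latent increment
  eff <- default_effect_sizes(zero = TRUE)
  eff$pos_presenteeism[eff$condition == "poor_physical_health"] <- 1.0
  cfg <- cohort_config(
    n_workers = 20000, seed = 202, effect_sizes = eff,
    hurdle_intercepts = c(absenteeism = qlogis(0.204),
                          presenteeism = qlogis(0.6)),
    base_rating = 5, noise_sd = 1)
  cohort <- generate_cohort(cfg)
  data <- dplyr::inner_join(score_risks(cohort), score_wpai(cohort),
                            by = "worker_id")
  fit <- fit_adjusted_excess(data, "presenteeism")
  est <- adjusted_excess(fit)
  row <- est[est$condition == "poor_physical_health", ]
  expect_lt(abs(row$adjusted_excess - 0.6 * 10 * 1.0), 2 * row$se)
  null_rows <- est[est$condition != "poor_physical_health", ]
  expect_true(all(abs(null_rows$adjusted_excess) <
                    3.5 * null_rows$se))
})

test_that("rank-deficient designs raise an error naming the collinear term", {
  cohort <- generate_cohort(cohort_config(n_workers = 300, seed = 9))
  data <- dplyr::inner_join(score_risks(cohort), score_wpai(cohort),
                            by = "worker_id")
  data$days_off <- data$days_on
  expect_error(fit_adjusted_excess(data, "total"), "days_off")
})

test_that("two-part model fits, reports OR-scale estimates and errors on degenerate outcomes", {
  cohort <- generate_cohort(cohort_config(n_workers = 800, seed = 21))
  data <- dplyr::inner_join(score_risks(cohort), score_wpai(cohort),
                            by = "worker_id")
  fit <- fit_two_part(data, "presenteeism")
  expect_s3_class(fit, "two_part_fit")
  expect_equal(fit$n_positive, sum(data$presenteeism_pct > 0))
  td <- tidy(fit)
  raw <- tidy(fit, exponentiate = FALSE)
  p1 <- td[td$part == "part1_logistic", ]
  p1_raw <- raw[raw$part == "part1_logistic", ]
  expect_equal(p1$estimate, exp(p1_raw$estimate))
  expect_equal(p1$conf.low, exp(p1_raw$conf.low))
  expect_true(all(p1$conf.low <= p1$estimate & p1$estimate <= p1$conf.high))
  g <- glance(fit)
  expect_gte(g$pseudo_r2_part1, 0)
  expect_gte(g$max_vif, 1)

  zero <- dplyr::mutate(data, wpai_impairment_0_10 = 0L,
                        presenteeism_pct = 0, total_loss_pct = 0)
  expect_error(fit_two_part(zero, "presenteeism"), "all zero")
  allpos <- dplyr::mutate(data, presenteeism_pct = presenteeism_pct + 1)
  expect_error(fit_two_part(allpos, "presenteeism"), "all positive")
})

test_that("two-part model recovers a large injected hurdle effect", {
  cfg <- recovery_config(4000, seed = 77)
  cohort <- generate_cohort(cfg)
  data <- dplyr::inner_join(score_risks(cohort), score_wpai(cohort),
                            by = "worker_id")
  fit <- fit_two_part(data, "presenteeism")
  raw <- tidy(fit, exponentiate = FALSE)
  b <- raw[raw$part == "part1_logistic" &
             raw$term == "poor_physical_healthTRUE", ]
  expect_lt(abs(b$estimate - 0.8), 2.5 * b$std.error)
  expect_gt(exp(b$conf.low), 1)  # OR confidently above 1
})
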