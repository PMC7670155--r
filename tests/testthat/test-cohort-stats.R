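test_that("cv_percent: closed form, zero case, scale invariance", {
  expect_equal(cv_percent(c(9.9, 10.1), c(1, 1)),
               100 * sd(c(9.9, 10.1)) / 10, tolerance = 1e-12)
  expect_equal(cv_percent(c(9.9, 10.1), c(1, 1)), 1.4142, tolerance = 1e-3)
  expect_equal(cv_percent(rep(5, 6), rep(1:3, each = 2)), 0)

  set.seed(31)
  v <- rnorm(100, 10); s <- rep(1:50, each = 2)
  expect_equal(cv_percent(v, s), cv_percent(7.3 * v, s), tolerance = 1e-10)

  expect_error(cv_percent(c(-1, 1), c(1, 1)), "zero")
  expect_error(cv_percent(c(1, 2), c(1, 2)), "2 replicates")
})

test_that("cv_percent matches its Monte-Carlo expectation", {
  set.seed(32)
  n <- 500
  v <- rep(10, 2 * n) + rnorm(2 * n, sd = 0.2)
  s <- rep(seq_len(n), each = 2)
  expect_equal(cv_percent(v, s), 2.0, tolerance = 0.2)
})

test_that("icc_percent: perfect agreement, variance ratio, pure noise", {
  set.seed(33)
  x <- rnorm(50, 10, 2)
  expect_equal(icc_percent(c(x, x), rep(1:50, 2), rep(1:2, each = 50)), 100,
               tolerance = 1e-9)

  # between-subject SD 2, error SD 0.5 -> ICC ~ 100 * 4 / 4.25 = 94.1
  n <- 2000
  subj <- rnorm(n, 10, 2)
  v <- c(subj + rnorm(n, sd = 0.5), subj + rnorm(n, sd = 0.5))
  icc <- icc_percent(v, rep(seq_len(n), 2), rep(1:2, each = n))
  expect_equal(icc, 100 * 4 / 4.25, tolerance = 0.8)

  v0 <- rnorm(2 * n, sd = 1)  # no subject signal
  icc0 <- icc_percent(v0, rep(seq_len(n), 2), rep(1:2, each = n))
  expect_lt(abs(icc0), 5)

  # invariance under a common affine transform
  icc2 <- icc_percent(3 * v + 7, rep(seq_len(n), 2), rep(1:2, each = n))
  expect_equal(icc, icc2, tolerance = 1e-9)

  expect_error(icc_percent(rep(1, 8), rep(1:4, 2), rep(1:2, each = 4)),
               "5 subjects")
})

test_that("anova_oneway: hand-computed case, null case, t^2 identity", {
  r <- anova_oneway(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(1:3, each = 3))
  expect_equal(r$F, 3.0, tolerance = 1e-12)
  expect_equal(r$p, 0.125, tolerance = 1e-10)
  expect_equal(c(r$df1, r$df2), c(2, 6))

  r0 <- anova_oneway(rep(c(1, 2), 3), rep(1:3, each = 2))
  expect_equal(r0$F, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)

  set.seed(41)
  x <- rnorm(30); g <- rep(1:2, each = 15)
  r2 <- anova_oneway(x, g)
  tt <- t.test(x[g == 1], x[g == 2], var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
})

test_that("anova_from_summary agrees with raw ANOVA and printed summaries", {
  # identity: summaries of raw data reproduce F exactly
  set.seed(42)
  for (i in 1:20) {
    g <- rep(1:3, times = sample(5:30, 3, replace = TRUE))
    x <- rnorm(length(g), mean = g)
    raw <- anova_oneway(x, g)
    sm <- anova_from_summary(n = tabulate(g),
                             mean = tapply(x, g, mean),
                             sd = tapply(x, g, sd))
    expect_equal(sm$F, raw$F, tolerance = 1e-10)
  }

  # the study's AHI row: 8.6+/-1.7 (113), 8.4+/-0.8 (98), 8.1+/-2.0 (128)
  r <- anova_from_summary(n = c(113, 98, 128), mean = c(8.6, 8.4, 8.1),
                          sd = c(1.7, 0.8, 2.0))
  expect_equal(r$F, 2.8766, tolerance = 1e-4)
  expect_equal(r$p, 0.0577, tolerance = 1e-3)

  expect_equal(anova_from_summary(c(5, 5), c(3, 3), c(1, 1))$F, 0)
  z <- anova_from_summary(c(5, 5), c(1, 2), c(0, 0))
  expect_true(z$zero_within)
  expect_equal(z$p, 0)
})

test_that("percent_difference: paper pairs, antisymmetry relation, errors", {
  expect_equal(round(percent_difference(6.7, 8.5), 1), 26.9)
  expect_equal(round(percent_difference(9.7, 11.0), 1), 13.4)
  expect_equal(percent_difference(4, 4), 0)
  set.seed(43)
  for (i in 1:10) {
    ab <- runif(2, 1, 20)
    pd1 <- percent_difference(ab[1], ab[2])
    pd2 <- percent_difference(ab[2], ab[1])
    expect_equal((1 + pd1 / 100) * (1 + pd2 / 100), 1, tolerance = 1e-12)
  }
  expect_error(percent_difference(0, 5), "zero")
})

test_that("pairwise_tests: null, strong effect, Bonferroni option", {
  set.seed(44)
  x <- rnorm(150)
  g <- rep(c("a", "b", "c"), each = 50)
  r <- pairwise_tests(x, g)
  expect_equal(nrow(r), 3)
  expect_true(all(r$p > 0.01))

  x2 <- c(rnorm(50), rnorm(50, 5), rnorm(50))
  r2 <- pairwise_tests(x2, g)
  expect_lt(r2$p[r2$group1 == "a" & r2$group2 == "b"], 1e-10)

  r3 <- pairwise_tests(x, g, bonferroni = TRUE)
  expect_equal(r3$p, pmin(r$p * 3, 1), tolerance = 1e-12)

  expect_error(pairwise_tests(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
})

test_that("reference_range_95: both methods, convergence, refusal", {
  cc <- rep(4.2, 30)
  expect_equal(unname(reference_range_95(cc, "percentile")), c(4.2, 4.2))
  expect_equal(unname(reference_range_95(cc, "normal")), c(4.2, 4.2))

  set.seed(45)
  z <- rnorm(1e5)
  rp <- reference_range_95(z, "percentile")
  rn <- reference_range_95(z, "normal")
  expect_equal(unname(rp), c(-1.96, 1.96), tolerance = 0.05)
  expect_equal(unname(rn), c(-1.96, 1.96), tolerance = 0.05)

  u <- runif(1e5)
  ru <- reference_range_95(u, "percentile")
  expect_equal(unname(ru), c(0.025, 0.975), tolerance = 0.01)
  run <- reference_range_95(u, "normal")
  expect_gt(abs(run[["low"]] - 0.025), 0.05)  # methods disagree off-Gaussian

  expect_error(reference_range_95(rnorm(10), "percentile"), "n >= 20")
  small <- reference_range_95(rnorm(10), "normal")
  expect_true(attr(small, "small_sample"))
})

test_that("normality_test: calibration, power, degenerate input", {
  set.seed(46)
  rej <- mean(replicate(400, normality_test(rnorm(200))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.04)

  rej_exp <- mean(replicate(150, normality_test(rexp(200))$p < 0.05))
  expect_gt(rej_exp, 0.9)

  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(c(1, 2)), "3 <= n")
})

test_that("reliability_report summarizes a simulated rater table", {
  set.seed(47)
  truth <- data.frame(AHI = rnorm(200, 8.5, 1.5), a = rnorm(200, 14, 2))
  tab <- simulate_raters(truth, rater_noise_model(0.2, 0.1, seed = 6),
                         n_raters = 2, n_replicates = 2)
  rel <- reliability_report(tab)
  expect_equal(rel$parameter, c("AHI", "a"))
  expect_true(all(rel$cv_percent > 0 & rel$cv_percent < 5))
  expect_true(all(rel$icc_percent > 75))
  expect_error(reliability_report(tab[, 1:3]), "missing columns")
})

test_that("build_table3_report has the full shape and consistent contents", {
  co <- simulate_cohort(cohort_spec(seed = 5))
  rep <- build_table3_report(co)
  expect_s3_class(rep, "comparison_report")
  expect_equal(nrow(rep$summaries), 8 * 3)
  expect_equal(nrow(rep$anova), 8)
  expect_equal(nrow(rep$pairwise), 8 * 3)
  expect_equal(nrow(rep$percent_diff), 8 * 3)
  # percent differences consistent with the summary means
  for (i in seq_len(nrow(rep$percent_diff))) {
    row <- rep$percent_diff[i, ]
    s <- rep$summaries
    mref <- s$mean[s$parameter == row$parameter & s$group == row$reference]
    mcmp <- s$mean[s$parameter == row$parameter & s$group == row$comparison]
    expect_equal(row$percent, round(100 * (mcmp - mref) / mref, 1),
                 tolerance = 0.05)
  }
  expect_error(build_table3_report(co, parameters = c("AHI", "nope")),
               "missing parameter columns")
  expect_output(print(rep), "AHI")
})

test_that("threshold_report returns upper reference bounds as cutoffs", {
  co <- simulate_cohort(cohort_spec(seed = 6))
  th <- threshold_report(co, group = "II", method = "normal")
  expect_equal(th$parameter, c("a", "b", "ratio_percent"))
  expect_equal(th$threshold, th$high)
  means <- sapply(c("a", "b", "ratio_percent"),
                  function(p) mean(co[[p]][co$group == "II"]))
  expect_true(all(th$threshold > means))
  # published cutoffs are carried constants, not recomputed targets
  pub <- published_thresholds()
  expect_equal(pub$threshold, c(16.8, 12.9, 33.5))
  expect_error(threshold_report(co, group = "XX"), "group not found")
})
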