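test_that("normality test is calibrated and powered as expected", {
  expect_error(normality_test(c(1, 2)), "3 <= n")
  expect_error(normality_test(rnorm(5001)), "3 <= n")
  expect_error(normality_test(rep(2, 10)), "constant")
  # type-I calibration: ~5% rejections on normal draws
  set.seed(1)
  p_norm <- vapply(1:300, function(i)
    normality_test(rnorm(1000))$p_value, numeric(1))
  rate <- mean(p_norm < 0.05)
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.0475 / 300))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.0475 / 300))
  # power: heavy log-normal samples rejected nearly always
  set.seed(2)
  p_ln <- vapply(1:200, function(i)
    normality_test(rlnorm(50, 0, 1))$p_value, numeric(1))
  expect_gt(mean(p_ln < 0.05), 0.95)
})

test_that("correlation dispatch follows the normality gate", {
  set.seed(3)
  x <- rnorm(60)
  lin <- correlation_auto(x, 2 * x + 1)
  expect_equal(lin$method, "pearson")
  expect_equal(lin$coefficient, 1, tolerance = 1e-12)
  expect_lt(lin$p_value, 1e-10)
  expect_named(lin$gate_report, c("x", "y"))

  mono <- correlation_auto(x, exp(3 * x))  # y fails the gate
  expect_equal(mono$method, "spearman")
  expect_equal(mono$coefficient, 1, tolerance = 1e-12)

  # spearman branch is invariant to strictly increasing transforms
  y <- rnorm(60)^2  # skewed, fails gate
  base <- correlation_auto(x, y)
  expect_equal(base$method, "spearman")
  trans <- correlation_auto(exp(x), y^(1 / 3) + 5)
  expect_equal(trans$coefficient, base$coefficient, tolerance = 1e-12)
  expect_error(correlation_auto(1:3, 1:3), "n >= 4")
})

test_that("pearson estimates show the expected small-sample attenuation", {
  # frozen replicate-mean oracle: E[r] = 0.4907 at n = 30, rho = 0.5
  # (large-replicate simulation)
  set.seed(4)
  r <- replicate(1000, {
    x <- rnorm(30)
    y <- 0.5 * x + sqrt(0.75) * rnorm(30)
    cor(x, y)
  })
  expect_lt(abs(mean(r) - 0.4907), 0.02)
  # and correlation_auto reports the same estimator on gated-normal data
  set.seed(5)
  x <- rnorm(30); y <- 0.5 * x + sqrt(0.75) * rnorm(30)
  expect_equal(correlation_auto(x, y)$coefficient, cor(x, y))
})

test_that("ICC handles perfect, null and degenerate repeatability", {
  x <- c(1, 3, 5, 7, 9, 11)
  perfect <- icc_oneway(x, x, n_boot = 50, seed = 1)
  expect_equal(perfect$estimate, 1)
  expect_false(perfect$degenerate)
  # swapping day labels leaves the estimate unchanged
  set.seed(6)
  d1 <- rnorm(40); d2 <- rnorm(40) + 0.8 * d1
  expect_equal(icc_oneway(d1, d2, n_boot = 10, seed = 2)$estimate,
               icc_oneway(d2, d1, n_boot = 10, seed = 2)$estimate,
               tolerance = 1e-12)
  # independent days: estimate near 0, may be negative, flagged
  set.seed(7)
  nullr <- icc_oneway(rnorm(200), rnorm(200), n_boot = 50, seed = 3)
  expect_lt(abs(nullr$estimate), 0.1)
  expect_error(icc_oneway(1:4, 1:4), ">= 5")
})

test_that("ICC bootstrap is seeded and brackets the estimate", {
  set.seed(8)
  s <- rnorm(80, sd = sqrt(3))
  d1 <- s + rnorm(80); d2 <- s + rnorm(80)
  a <- icc_oneway(d1, d2, n_boot = 400, seed = 11)
  b <- icc_oneway(d1, d2, n_boot = 400, seed = 11)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$estimate)
  expect_gte(a$ci_high, a$estimate)
})

test_that("eta-squared matches the brute-force decomposition when balanced", {
  set.seed(9)
  a <- rep(c("x", "y"), each = 10)
  b <- rep(rep(c("u", "v"), each = 5), 2)
  y <- rnorm(20, mean = 2 * (a == "x") + (b == "u"))
  res <- perm_anova_2x2(y, a, b, n_perm = 100, seed = 1)
  oracle <- oracle_balanced_ss(y, a, b)
  expect_equal(res$terms$eta_squared,
               c(oracle$A, oracle$B, oracle$AB) / oracle$total,
               tolerance = 1e-12)
})

test_that("Type II F statistics agree with car::Anova when unbalanced", {
  skip_if_not_installed("car")
  set.seed(10)
  a <- factor(c(rep("x", 13), rep("y", 9)))
  b <- factor(c(rep(c("u", "v"), c(6, 7)), rep(c("u", "v"), c(4, 5))))
  y <- rnorm(22, mean = (a == "x") * 1.5 - (b == "v"))
  res <- perm_anova_2x2(y, a, b, n_perm = 50, seed = 1)
  ca <- car::Anova(lm(y ~ a * b), type = 2)
  expect_equal(res$terms$F, ca$`F value`[1:3], tolerance = 1e-10)
  # Type II equals the balanced Type I decomposition when balanced
  a2 <- rep(c("x", "y"), each = 8); b2 <- rep(c("u", "v"), 8)
  y2 <- rnorm(16)
  res2 <- perm_anova_2x2(y2, a2, b2, n_perm = 50, seed = 1)
  or2 <- oracle_balanced_ss(y2, a2, b2)
  expect_equal(res2$terms$eta_squared,
               c(or2$A, or2$B, or2$AB) / or2$total, tolerance = 1e-12)
})

test_that("permutation ANOVA handles the no-variance degenerate input", {
  res <- perm_anova_2x2(rep(3, 12), rep(c("x", "y"), each = 6),
                        rep(c("u", "v"), 6), n_perm = 99, seed = 1)
  expect_equal(res$terms$p_value, rep(1, 3))
  expect_equal(res$terms$eta_squared, rep(0, 3))
})

test_that("permutation p-values are smoothed, reproducible and valid", {
  set.seed(11)
  y <- rnorm(24); a <- rep(c("x", "y"), each = 12)
  b <- rep(c("u", "v"), 12)
  r1 <- perm_anova_2x2(y, a, b, n_perm = 500, seed = 99)
  r2 <- perm_anova_2x2(y, a, b, n_perm = 500, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(r1$terms$p_value > 0 & r1$terms$p_value <= 1))
  expect_true(all(r1$terms$eta_squared >= 0))
  expect_lte(sum(r1$terms$eta_squared), 1)
  expect_error(perm_anova_2x2(y, rep("x", 24), b), "two levels")
  expect_error(perm_anova_2x2(y[1:4], c("x", "x", "y", "y"),
                              c("u", "v", "u", "v")), ">= 2")
})

test_that("two-group dispatch, Cohen's d and gating behave as specified", {
  set.seed(12)
  y1 <- rnorm(40); y2 <- rnorm(40)
  same <- two_group_test(y1, y1 + rnorm(40, 0, 1e-8))
  expect_equal(same$cohen_d, 0, tolerance = 1e-6)
  expect_gt(same$p_value, 0.9)

  norm <- two_group_test(y1, y2)
  expect_equal(norm$method, "welch_t")
  skewed <- two_group_test(exp(rnorm(40, 0, 1.5)), exp(rnorm(40, 0, 1.5)))
  expect_equal(skewed$method, "mann_whitney")

  # d calibration: planted 1-SD shift recovered at n = 50/group
  set.seed(13)
  ds <- replicate(200, two_group_test(rnorm(50, 1), rnorm(50))$cohen_d)
  expect_lt(abs(mean(ds) - 1), 0.15)

  # paired branch gates the differences; degenerate input rejected
  p1 <- rnorm(20); p2 <- p1 + 0.5 + rnorm(20, 0, 0.2)
  paired <- two_group_test(p1, p2, paired = TRUE)
  expect_true(paired$method %in% c("paired_t", "wilcoxon_signed_rank"))
  expect_true(is.na(paired$cohen_d))
  expect_error(two_group_test(p1, p1, paired = TRUE), "zero")
  expect_error(two_group_test(1:2, 3:4), ">= 3")
})

test_that("Mann-Whitney exact p matches full enumeration on tiny groups", {
  res <- two_group_test(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                        dispatch = "nonparametric")
  expect_equal(res$method, "mann_whitney")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, enumerate_mw_p(c(1, 2, 3), c(4, 5, 6), "less"))
  expect_equal(res$p_value, 1 / 20)
  # two-sided and a non-extreme arrangement
  res2 <- two_group_test(c(1, 4, 5), c(2, 3, 6),
                         dispatch = "nonparametric")
  expect_equal(res2$p_value,
               enumerate_mw_p(c(1, 4, 5), c(2, 3, 6), "two.sided"))
})

test_that("signed-rank exact p matches sign-flip enumeration for n <= 8", {
  cases <- list(c(1.2, -0.7, 2.1, 3.5, -0.2, 0.9),
                c(0.4, 1.1, 2.2, -3.3, 4.5, -5.1, 6.2),
                c(-1.5, 2.5, 3.5, 4.5, -5.5, 6.5, 7.5, 0.5))
  for (d in cases) {
    y2 <- rnorm(length(d)); y1 <- y2 + d
    res <- two_group_test(y1, y2, paired = TRUE,
                          dispatch = "nonparametric")
    expect_equal(res$method, "wilcoxon_signed_rank")
    expect_equal(res$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("effect sizes are classified by the conventional bands", {
  expect_equal(classify_effect("eta_squared", 0.04)$label, "small")
  expect_equal(classify_effect("eta_squared", 0.082)$label, "medium")
  expect_equal(classify_effect("eta_squared", 0.2)$label, "large")
  expect_equal(classify_effect("cohen_d", 0.83)$label, "large")
  expect_equal(classify_effect("cohen_d", -0.65)$label, "medium")
  expect_equal(classify_effect("cohen_d", 0.3)$label, "small")
  # boundaries follow the printed inequalities exactly
  expect_equal(classify_effect("eta_squared", 0.01)$label, "negligible")
  expect_equal(classify_effect("eta_squared", 0.06)$label, "medium")
  expect_equal(classify_effect("eta_squared", 0.14)$label, "large")
  expect_equal(classify_effect("cohen_d", 0.2)$label, "negligible")
  expect_equal(classify_effect("cohen_d", 0.5)$label, "medium")
  expect_equal(classify_effect("cohen_d", 0.8)$label, "large")
  expect_error(classify_effect("eta_squared", 1.2), "\\[0, 1\\]")
})

test_that("the optional FDR column is appended, raw p-values untouched", {
  rep <- data.frame(p_value = c(0.01, 0.02, 0.5))
  out <- add_bh_column(rep)
  expect_equal(out$p_value, rep$p_value)
  expect_equal(out$p_bh, p.adjust(rep$p_value, "BH"))
})
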