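test_that("moment-based normality screen applies both thresholds", {
  set.seed(1)
  expect_true(normalityCheck(rnorm(500)))
  expect_false(normalityCheck(rexp(500)^3))        # skewness far above 2
  expect_true(normalityCheck(rep(c(-1, 1), 50)))   # symmetric: skewness 0
  expect_error(normalityCheck(rep(3, 10)), "zero variance")
  expect_error(normalityCheck(c(1, 2)), "at least 3")
})

test_that("pooled t / Cohen's d reproduce printed cohort effect sizes", {
  ## follow-up mini-mental row: (26.42 +/- 2.78, n=24) vs (28.10 +/- 1.75, 82)
  r <- independentTAndD(summary1 = c(26.42, 2.78, 24),
                        summary2 = c(28.10, 1.75, 82))
  expect_lt(abs(r$effect_size - 0.83), 0.011)
  ## verbal-learning follow-up row: d = 0.86, CI lower bound ~ 0.38-0.39
  r2 <- independentTAndD(summary1 = c(30.69, 26.00, 24),
                         summary2 = c(52.21, 24.91, 82))
  expect_lt(abs(r2$effect_size - 0.86), 0.011)
  expect_gt(r2$ci95[1], 0.375)
  expect_lt(r2$ci95[1], 0.395)

  set.seed(3)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  raw <- independentTAndD(x, y)
  summ <- independentTAndD(summary1 = c(mean(x), sd(x), 30),
                           summary2 = c(mean(y), sd(y), 40))
  expect_equal(raw$effect_size, summ$effect_size, tolerance = 1e-12)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  ## base-R Welch-free oracle
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(raw$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(raw$p_value, tt$p.value, tolerance = 1e-10)

  same <- independentTAndD(x, x)
  expect_equal(same$effect_size, 0)
  expect_equal(same$p_value, 1)
  expect_error(independentTAndD(rep(1, 5), rep(1, 6)), "pooled variance")
})

test_that("paired t and d follow the pre-minus-post sign convention", {
  set.seed(4)
  pre <- rnorm(50)
  post <- pre + 1 + rnorm(50, 0, 0.1)
  r <- pairedTAndD(pre, post)
  expect_lt(r$effect_size, -5)          # post exceeds pre -> negative d
  expect_lt(r$p_value, 1e-3)
  expect_error(pairedTAndD(pre, pre), "zero variance")
  expect_error(pairedTAndD(pre, post[-1]), "paired")

  ## type-I calibration under a paired null
  pv <- vapply(1:1000, function(s) {
    set.seed(s)
    a <- rnorm(20); b <- a + rnorm(20)     # no systematic pre-post shift
    pairedTAndD(a, b)$p_value
  }, numeric(1))
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(pv) - 0.5), 0.04)
})

test_that("chi-square matches the carrier-table value and scales", {
  apoe <- matrix(c(12, 9, 12, 73), 2)   # carriers 12/24 vs 9/82
  r <- chiSquareTest(apoe)
  orc <- suppressWarnings(chisq.test(apoe, correct = FALSE))
  expect_equal(r$statistic, unname(orc$statistic), tolerance = 1e-10)
  expect_equal(r$statistic, 17.80, tolerance = 0.005)
  expect_lt(r$p_value, 0.001)

  marg <- outer(c(10, 30), c(4, 6)) / 10
  expect_equal(chiSquareTest(marg)$statistic, 0, tolerance = 1e-12)
  expect_equal(chiSquareTest(2 * apoe)$statistic, 2 * r$statistic,
               tolerance = 1e-10)
  expect_error(chiSquareTest(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("ANCOVA group F and partial eta^2 match a normal-equations solve", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 8
    y <- rnorm(n); g <- rep(c("A", "B"), each = 4); cov <- rnorm(n)
    r <- ancovaPartialEta2(y, g, cov)
    ## explicit least squares: X = [1, cov, g]
    X <- cbind(1, cov, as.numeric(factor(g)) - 1)
    b <- solve(t(X) %*% X, t(X) %*% y)
    rssF <- sum((y - X %*% b)^2)
    X0 <- X[, 1:2]
    b0 <- solve(t(X0) %*% X0, t(X0) %*% y)
    rss0 <- sum((y - X0 %*% b0)^2)
    Fo <- (rss0 - rssF) / (rssF / (n - 3))
    expect_equal(r$statistic, Fo, tolerance = 1e-10)
    expect_equal(r$effect_size, (rss0 - rssF) / rss0, tolerance = 1e-10)
  }

  ## covariate orthogonal to both group and response leaves eta^2 unchanged
  y <- c(1, 3, 2, 4, 6, 5, 7, 8)
  g <- rep(c("A", "B"), each = 4)
  cov <- rep(c(-1, 1), 4)
  cov <- cov - mean(cov)
  y0 <- y - mean(y)
  gn <- as.numeric(factor(g)) - 1
  covO <- residuals(lm(cov ~ y0 + gn))
  rWith <- ancovaPartialEta2(y, g, covO)
  tt <- independentTAndD(y[g == "A"], y[g == "B"])
  etaNoCov <- tt$statistic^2 / (tt$statistic^2 + 6)
  expect_equal(rWith$effect_size, etaNoCov, tolerance = 1e-6)

  ## response driven by the covariate alone: the group effect is absorbed
  set.seed(6)
  cv <- rnorm(40)
  rAbs <- ancovaPartialEta2(cv + rnorm(40, 0, 0.1), rep(c("A", "B"), 20), cv)
  expect_lt(rAbs$effect_size, 0.15)
  expect_error(ancovaPartialEta2(cv, rep(c("A", "B"), each = 6),
                                 as.numeric(factor(rep(c("A", "B"),
                                                       each = 6)))),
               "collinear")
})

test_that("partial correlation removes shared confounds, bootstrap seeded", {
  set.seed(7)
  z <- rnorm(200)
  x <- z + rnorm(200, 0, 0.8)
  y <- z + rnorm(200, 0, 0.8)
  pc <- partialCorrelationBootstrap(x, y, z, nBoot = 300, seed = 11)
  expect_gt(cor(x, y), 0.4)             # raw correlation from the confound
  expect_lt(abs(pc$r), 0.12)            # gone after adjustment
  pc2 <- partialCorrelationBootstrap(x, y, z, nBoot = 300, seed = 11)
  expect_identical(pc$ci95, pc2$ci95)

  w <- rnorm(200)
  ident <- partialCorrelationBootstrap(x, x, w, nBoot = 50, seed = 1)
  expect_equal(ident$r, 1, tolerance = 1e-12)

  ## p-value agrees with the t transform
  expect_equal(pc$p_value,
               2 * pt(-abs(pc$r * sqrt(197 / (1 - pc$r^2))), 197),
               tolerance = 1e-12)
  expect_error(partialCorrelationBootstrap(1:4, 1:4, 1:4), "n >= 5")
})

test_that("group comparison report runs both engines over columns", {
  set.seed(8)
  X <- cbind(a = rnorm(30), b = rnorm(30, sd = 2))
  g <- rep(c("A_plus", "A_minus"), 15)
  cov <- rnorm(30)
  rep1 <- groupComparisonReport(X, g, cov)
  expect_identical(nrow(rep1), 2L)
  expect_identical(rep1$effect_type, rep("partial_eta_squared", 2))
  rep2 <- groupComparisonReport(X, g, NULL, fdr = TRUE)
  expect_identical(rep2$effect_type, rep("cohens_d", 2))
  expect_true(all(rep2$p_adj >= rep2$p_value - 1e-12))
})
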