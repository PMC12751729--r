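test_that("proportional thresholding keeps the right edge counts", {
  W <- randomW(19, seed = 1)
  for (p in seq(0.05, 0.35, by = 0.05)) {
    Wt <- proportionalThreshold(W, p)
    expect_identical(sum(Wt[upper.tri(Wt)] > 0), as.integer(round(p * 171)))
    kept <- Wt[upper.tri(Wt)]
    expect_true(all(kept[kept > 0] %in% W[upper.tri(W)]))  # weights preserved
    expect_identical(Wt, t(Wt))
  }
  expect_identical(proportionalThreshold(W, 1), W)
  expect_error(proportionalThreshold(W, 0), "0, 1")
  expect_error(proportionalThreshold(W, 1.2), "0, 1")
  ## deterministic stable tie-breaking: all-equal weights
  Weq <- matrix(1, 5, 5); diag(Weq) <- 0
  t1 <- proportionalThreshold(Weq, 0.5)
  expect_identical(t1, proportionalThreshold(Weq, 0.5))
  expect_identical(sum(t1[upper.tri(t1)] > 0), 5L)   # round(0.5 * 10)
})

test_that("clustering coefficient matches closed forms and the loop oracle", {
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  expect_equal(unname(weightedClusteringCoef(tri)), rep(1, 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 0.8
  expect_equal(unname(weightedClusteringCoef(star)), rep(0, 4))
  expect_error(weightedClusteringCoef(-tri), "negative")
  for (s in 1:25) {
    W <- randomW(8, seed = s, density = runif(1, 0.3, 1))
    expect_equal(unname(weightedClusteringCoef(W)), oracleCC(W),
                 tolerance = 1e-12)
  }
})

test_that("node strength has its closed forms", {
  full <- matrix(1, 19, 19); diag(full) <- 0
  expect_equal(unname(nodeStrength(full)), rep(18, 19))
  expect_equal(unname(nodeStrength(matrix(0, 5, 5))), rep(0, 5))
  W <- randomW(11, seed = 2, density = 0.5)
  expect_equal(sum(nodeStrength(W)), 2 * sum(W[upper.tri(W)]),
               tolerance = 1e-12)
})

test_that("global efficiency matches hand values and igraph Dijkstra", {
  skip_if_not_installed("igraph")
  full <- matrix(1, 19, 19); diag(full) <- 0
  expect_equal(globalEfficiency(full), 1)
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(globalEfficiency(path3), (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  for (s in 1:25) {
    W <- randomW(8, seed = 100 + s, density = runif(1, 0.2, 1))
    expect_equal(globalEfficiency(W), oracleE(W), tolerance = 1e-12)
  }
  ## disconnected graphs: unreachable pairs contribute zero
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(globalEfficiency(W), (2 * 0.5) / (4 * 3), tolerance = 1e-12)
})

test_that("network feature vector aggregates thresholds and counts 205", {
  wb <- lapply(setNames(bandDefinitions()$name, bandDefinitions()$name),
               function(b) randomW(19, seed = match(b, bandDefinitions()$name)))
  for (b in names(wb)) dimnames(wb[[b]]) <- list(montage1020(), montage1020())
  nf <- networkFeatureVector(wb)
  expect_length(nf, 205)
  expect_identical(sum(grepl("_CC_", names(nf))), 100L)
  expect_identical(sum(grepl("_E$", names(nf))), 5L)
  expect_equal(nf[["alpha_CC_Global"]],
               unname(mean(nf[paste0("alpha_CC_", montage1020())])),
               tolerance = 1e-12)

  ## thresholds = {1} reduces to the single-threshold metrics
  one <- networkFeatureVector(wb["alpha"], thresholds = 1)
  expect_equal(unname(one[paste0("alpha_NS_", montage1020())]),
               unname(nodeStrength(wb$alpha)), tolerance = 1e-12)
  expect_equal(one[["alpha_E"]], globalEfficiency(wb$alpha),
               tolerance = 1e-12)

  ## permutation equivariance of nodal metrics
  perm <- sample(19)
  Wp <- wb$alpha[perm, perm]
  expect_equal(unname(weightedClusteringCoef(Wp)),
               unname(weightedClusteringCoef(wb$alpha))[perm],
               tolerance = 1e-12)
  expect_equal(globalEfficiency(Wp), globalEfficiency(wb$alpha),
               tolerance = 1e-12)
})

test_that("efficiency grows with threshold proportion; CC mostly does", {
  ## E is exactly monotone: a larger p keeps a superset of edges with the
  ## same weights, so no distance can grow. CC is not guaranteed monotone
  ## (new weak edges raise binary degrees faster than triangle mass); the
  ## violations are counted and must stay a small minority, not hidden.
  ps <- seq(0.05, 1, by = 0.05)
  ccViol <- 0; ccSteps <- 0
  for (s in 1:20) {
    W <- randomW(19, seed = 200 + s)
    cc <- vapply(ps, function(p)
      mean(weightedClusteringCoef(proportionalThreshold(W, p))), numeric(1))
    ef <- vapply(ps, function(p)
      globalEfficiency(proportionalThreshold(W, p)), numeric(1))
    expect_true(all(diff(ef) > -1e-12))
    ccViol <- ccViol + sum(diff(cc) < -1e-12)
    ccSteps <- ccSteps + length(ps) - 1
  }
  expect_lt(ccViol / ccSteps, 0.25)
})
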