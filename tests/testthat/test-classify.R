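test_that("classification metrics match their closed forms", {
  m <- classificationMetrics(3, 1, 7, 1)
  expect_equal(unname(m), c(10 / 12, 0.75, 0.875, 0.625, 0.75),
               tolerance = 1e-4)
  perfect <- classificationMetrics(5, 0, 9, 0)
  expect_true(all(perfect == 1))
  allNeg <- classificationMetrics(0, 0, 9, 3)
  expect_identical(unname(allNeg[c("mcc", "specificity", "sensitivity")]),
                   c(0, 1, 0))
  expect_error(classificationMetrics(0, 0, 0, 0), "empty")
})

test_that("feature table assembly counts, orders and joins correctly", {
  set.seed(1)
  n <- 6
  spectral <- matrix(rnorm(n * 100), n,
                     dimnames = list(sprintf("S%d", 1:n), paste0("p", 1:100)))
  network <- matrix(rnorm(n * 205), n,
                    dimnames = list(sprintf("S%d", 1:n), paste0("n", 1:205)))
  meta <- data.frame(subject_id = sprintf("S%d", 1:n),
                     group = rep(c("A_plus", "A_minus"), 3),
                     age = rnorm(n, 70), sex = rep(c("male", "female"), 3),
                     education_years = 10:15, apoe4 = rep(c(TRUE, FALSE), 3),
                     severity = runif(n), MMSE = runif(n, 0, 100))
  ft <- buildFeatureTable(spectral, network, meta, "eeg")
  expect_identical(dim(SummarizedExperiment::assay(ft)), c(306L, 6L))
  expect_identical(rownames(SummarizedExperiment::assay(ft)),
                   c(paste0("p", 1:100), paste0("n", 1:205), "age"))
  ftd <- buildFeatureTable(spectral, network, meta, "demographic")
  feats <- rownames(SummarizedExperiment::assay(ftd))
  expect_true(all(c("age", "sex", "education_years", "apoe4", "MMSE")
                  %in% feats))
  expect_false("severity" %in% feats)    # latent variable never leaks
  expect_error(buildFeatureTable(spectral[-1, ], network, meta, "eeg"),
               "do not match")
})

test_that("stratified folds keep class proportions within one member", {
  y <- rep(c(TRUE, FALSE), c(24, 82))
  fold <- scdEEG:::.stratifiedFolds(y, 10, seed = 3)
  perFold <- table(fold, y)
  expect_true(all(perFold[, "TRUE"] %in% 2:3))
  expect_true(all(perFold[, "FALSE"] %in% 8:9))
  expect_warning(scdEEG:::.stratifiedFolds(rep(c(TRUE, FALSE), c(3, 40)),
                                           10, seed = 1),
                 "some folds lack")
})

test_that("fold-wise scaling guards constant columns", {
  tr <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4))
  te <- cbind(a = c(0, 10), b = c(5, 7))
  sc <- scdEEG:::.zscale(tr, te)
  expect_true(all(is.finite(sc$train)) && all(is.finite(sc$test)))
  expect_identical(unname(sc$train[, "b"]), rep(0, 4))
  expect_identical(unname(sc$test[, "b"]), rep(0, 2))
  expect_true(sc$flat[["b"]] && !sc$flat[["a"]])
})

test_that("AdaBoost stumps separate planted structure and predict sanely", {
  set.seed(2)
  n <- 80
  X <- cbind(sig = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
             noise = rnorm(n))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  fit <- fitAdaBoost(X, y)
  expect_s3_class(fit, "adaboostStumps")
  acc <- mean(predict(fit, X, type = "class") == y)
  expect_gte(acc, 0.95)
  ## margins are finite and sign-consistent with classes
  marg <- predict(fit, X)
  expect_true(all(is.finite(marg)))
  expect_gt(mean(marg[y]), mean(marg[!y]))
  expect_error(fitAdaBoost(X, rep(TRUE, n)), "both classes")
})

test_that("forward selection finds planted signal and respects its cap", {
  tab <- plantedFeatureTable(nPos = 20, nNeg = 40, p = 50, seed = 3)
  sel <- sfsSelect(tab, maxFeatures = 6, seed = 2)
  expect_identical(sel[1], "f001")
  expect_lte(length(sel), 6)
  expect_error(sfsSelect(tab, maxFeatures = 0, seed = 1), "at least 1")

  ## a duplicate of the separating feature: exactly one copy selected
  ## before any noise feature
  tab2 <- tab
  a <- SummarizedExperiment::assay(tab2, "features")
  a["f002", ] <- a["f001", ]
  SummarizedExperiment::assays(tab2)$features <- a
  sel2 <- sfsSelect(tab2, maxFeatures = 5, seed = 2)
  expect_identical(sel2[1], "f001")      # ties break by column order
  ## the redundant copy never improves the score, so the best prefix holds
  ## exactly one of the two copies
  expect_identical(sum(c("f001", "f002") %in% sel2), 1L)
})

test_that("cross-validated evaluation is seeded, order-invariant and
           near-perfect on separable data", {
  tab <- plantedFeatureTable(nPos = 24, nNeg = 82, p = 20, seed = 4, gap = 4)
  cv <- cvEvaluate(tab, "f001", seed = 7)
  expect_s4_class(cv, "CVResult")
  expect_gte(cvMetrics(cv)$pooled[cvMetrics(cv)$metric == "accuracy"], 0.97)
  cv2 <- cvEvaluate(tab, "f001", seed = 7)
  expect_identical(cvMetrics(cv), cvMetrics(cv2))

  ## shuffling subject order leaves results unchanged (same seed)
  perm <- sample(ncol(tab))
  cv3 <- cvEvaluate(tab[, perm], "f001", seed = 7)
  expect_identical(cvMetrics(cv), cvMetrics(cv3))

  expect_error(cvEvaluate(tab, "nope", seed = 1), "unknown features")
})

test_that("label permutation keeps noise-level performance honest", {
  tab <- noiseFeatureTable(nPos = 12, nNeg = 28, p = 8, seed = 6)
  mccs <- vapply(1:10, function(s) {
    cv <- suppressWarnings(cvEvaluate(tab, seed = s))
    cvMetrics(cv)$pooled[cvMetrics(cv)$metric == "mcc"]
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.25)

  ## permutation p-value formula: observed above all B = 4 shuffles
  sep <- plantedFeatureTable(nPos = 10, nNeg = 10, p = 3, seed = 8, gap = 6)
  cv <- cvEvaluate(sep, "f001", nFolds = 5, seed = 2)
  cvp <- permutationPvalue(sep, cv, B = 4, seed = 3, nFolds = 5)
  expect_identical(unname(permPvalues(cvp)[["accuracy"]]), 1 / 5)

  ## under the null the permutation p is a valid (conservative) p-value:
  ## P(p <= alpha) <= alpha up to Monte-Carlo error; ties on the discrete
  ## accuracy grid push it above uniform, never below
  nullTab <- noiseFeatureTable(nPos = 10, nNeg = 10, p = 4, seed = 9)
  ps <- vapply(1:30, function(s) {
    cv0 <- suppressWarnings(cvEvaluate(nullTab, nFolds = 5, seed = s,
                                       useSmote = FALSE))
    out <- suppressWarnings(
      permutationPvalue(nullTab, cv0, B = 19, seed = s, nFolds = 5,
                        useSmote = FALSE))
    permPvalues(out)[["accuracy"]]
  }, numeric(1))
  expect_gte(min(ps), 1 / 20)            # attainable floor
  expect_lte(mean(ps <= 0.1), 0.2)
  expect_lte(mean(ps <= 0.25), 0.35)
  expect_gt(mean(ps), 0.25)
})

test_that("EEG-mode beats demographic mode when signal is EEG-only", {
  set.seed(10)
  n <- 36
  ids <- sprintf("S%02d", 1:n)
  group <- rep(c("A_plus", "A_minus"), c(12, 24))
  spectral <- matrix(rnorm(n * 10), n, dimnames = list(ids, paste0("sp", 1:10)))
  spectral[, 1] <- spectral[, 1] + ifelse(group == "A_plus", 3, 0)
  network <- matrix(rnorm(n * 5), n, dimnames = list(ids, paste0("nw", 1:5)))
  meta <- data.frame(subject_id = ids, group = group, age = rnorm(n, 70, 5),
                     sex = sample(c("male", "female"), n, TRUE),
                     education_years = sample(8:18, n, TRUE),
                     apoe4 = runif(n) < 0.2, severity = 0,
                     MMSE = runif(n, 20, 80))
  ftE <- buildFeatureTable(spectral, network, meta, "eeg")
  ftD <- buildFeatureTable(spectral, network, meta, "demographic")
  mccOf <- function(ft) {
    sel <- sfsSelect(ft, maxFeatures = 3, seed = 4)
    cv <- suppressWarnings(cvEvaluate(ft, sel, seed = 4))
    cvMetrics(cv)$pooled[cvMetrics(cv)$metric == "mcc"]
  }
  expect_gt(mccOf(ftE), mccOf(ftD))
})

test_that("exact stump SHAP satisfies the Shapley axioms", {
  set.seed(11)
  X <- cbind(a = c(rnorm(20, 0), rnorm(20, 3)), b = rnorm(40),
             const = rep(2, 40))
  y <- rep(c(FALSE, TRUE), each = 20)
  fit <- fitAdaBoost(X, y)
  sh <- shapSummary(fit, X)
  marg <- predict(fit, X)
  ## efficiency: base + sum phi = margin, per sample
  expect_lt(max(abs(sh@baseValue + rowSums(sh@values) - marg)), 1e-6)
  ## dummy axiom: constant feature gets zero attribution
  expect_identical(unname(sh@values[, "const"]), rep(0, 40))
  ## positive attributions push toward the positive class
  expect_gt(cor(sh@values[, "a"], marg), 0.9)

  ## single stump on one feature: attribution equals margin - base exactly
  X1 <- matrix(c(rnorm(10, 0), rnorm(10, 5)), dimnames = list(NULL, "only"))
  fit1 <- fitAdaBoost(X1, rep(c(FALSE, TRUE), each = 10), rounds = 1)
  sh1 <- shapSummary(fit1, X1)
  expect_equal(unname(sh1@values[, 1]),
               unname(predict(fit1, X1) - sh1@baseValue), tolerance = 1e-12)
  expect_error(shapSummary(fit, X[, 1:2]), "mismatch")
})
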