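test_that("subject recordings are a pure function of (spec, meta, seed)", {
  spec <- cohortSpec(nPos = 2, nNeg = 2, fs = 128, duration = 12, seed = 4)
  meta <- data.frame(subject_id = "a", group = "A_plus", severity = 0.8)
  r1 <- generateSubjectRecording(spec, meta, 99)
  r2 <- generateSubjectRecording(spec, meta, 99)
  expect_identical(eegData(r1), eegData(r2))
  r3 <- generateSubjectRecording(spec, meta, 100)
  expect_false(identical(eegData(r1), eegData(r3)))
  expect_identical(dim(eegData(r1)), dim(eegData(r3)))
  expect_identical(channelLabels(r1), montage1020())
})

test_that("cohort metadata matches the configured group structure", {
  spec <- cohortSpec(seed = 2)              # default 24 + 82
  coh <- generateCohort(spec, recordings = FALSE)
  expect_identical(sum(coh$meta$group == "A_plus"), 24L)
  expect_identical(sum(coh$meta$group == "A_minus"), 82L)
  expect_true(all(coh$meta$age > 0))
  expect_true(all(vapply(c("MMSE", "BNT", "SVLT", "DSC"), function(s)
    all(coh$meta[[s]] >= 0 & coh$meta[[s]] <= 100), logical(1))))
  ## APOE4 carrier proportions within binomial 95% bounds of 0.50 / 0.11
  kPos <- sum(coh$meta$apoe4[coh$meta$group == "A_plus"])
  kNeg <- sum(coh$meta$apoe4[coh$meta$group == "A_minus"])
  expect_gte(kPos, qbinom(0.025, 24, 0.50))
  expect_lte(kPos, qbinom(0.975, 24, 0.50))
  expect_gte(kNeg, qbinom(0.025, 82, 0.11))
  expect_lte(kNeg, qbinom(0.975, 82, 0.11))
  expect_error(cohortSpec(nPos = 1, nNeg = 82), "at least 2")
})

test_that("two master seeds give different cohorts with identical structure", {
  s1 <- generateCohort(cohortSpec(nPos = 3, nNeg = 3, fs = 128,
                                  duration = 6, seed = 1,
                                  artifactRate = 0))
  s2 <- generateCohort(cohortSpec(nPos = 3, nNeg = 3, fs = 128,
                                  duration = 6, seed = 2,
                                  artifactRate = 0))
  expect_identical(s1$meta$group, s2$meta$group)
  expect_identical(dim(eegData(s1$recordings[[1]])),
                   dim(eegData(s2$recordings[[1]])))
  expect_false(identical(eegData(s1$recordings[[1]]),
                         eegData(s2$recordings[[1]])))
})

test_that("artifact injection is Poisson-rated, logged and flaggable", {
  spec <- cohortSpec(nPos = 2, nNeg = 2, fs = 128, duration = 180, seed = 3)
  meta <- data.frame(subject_id = "a", group = "A_minus", severity = 0)
  rec <- generateSubjectRecording(spec, meta, 7)

  r0 <- injectArtifacts(rec, 0, 500, seed = 1)
  expect_identical(eegData(r0), eegData(rec))
  expect_identical(nrow(r0@metadata$artifactEvents), 0L)

  expect_error(injectArtifacts(rec, 6, -5, seed = 1), "positive")

  counts <- vapply(1:30, function(s)
    nrow(injectArtifacts(rec, 6, 500, seed = s)@metadata$artifactEvents),
    numeric(1))
  ## Poisson(18): mean of 30 draws within +/- 4 sd of the mean
  expect_gt(mean(counts), 18 - 4 * sqrt(18 / 30))
  expect_lt(mean(counts), 18 + 4 * sqrt(18 / 30))

  ## every logged event epoch is flagged at a 150 uV threshold
  ri <- injectArtifacts(rec, 6, 500, seed = 2)
  es <- rejectAndSelectEpochs(segmentEpochs(bandpassFilter(ri)),
                              ampThreshUV = 150, nSelect = 40, seed = 1)
  hitEpochs <- unique(floor(ri@metadata$artifactEvents$time / 2) + 1)
  expect_length(intersect(selectedIndices(es), hitEpochs), 0)
})

test_that("cognitive scores decrease with severity by construction", {
  spec <- cohortSpec(nPos = 2, nNeg = 2, seed = 1)
  meta <- data.frame(subject_id = sprintf("s%d", 1:100),
                     severity = runif(100, 0, 2))
  ## degenerate case: no slope, no noise -> identical scores
  s0 <- cohortSpec(nPos = 2, nNeg = 2, seed = 1, scoreSlope = 0,
                   scoreNoiseSd = 0)
  m0 <- generateCovariatesAndScores(meta, s0, 1)
  expect_identical(length(unique(m0$MMSE)), 1L)
  m1 <- generateCovariatesAndScores(meta, spec, 1)
  expect_lt(cor(m1$severity, m1$SVLT), 0)
})

test_that("1/f background has log-log PSD slope near -1 over 2-40 Hz", {
  spec <- cohortSpec(nPos = 2, nNeg = 2, fs = 250, duration = 120, seed = 1,
                     effect = "null", artifactRate = 0, coupling = list(),
                     whiteRms = 0, jitterSd = 0,
                     bandRms = c(delta = 0, theta = 0, alpha = 0, beta = 0,
                                 gamma = 0))
  meta <- data.frame(subject_id = "bg", group = "A_minus", severity = 0)
  rec <- generateSubjectRecording(spec, meta, 11)
  psd <- welchPsd(segmentEpochs(rec))
  keep <- psd$freq >= 2 & psd$freq <= 40
  slope <- coef(lm(log(colMeans(psd$psd)[keep]) ~ log(psd$freq[keep])))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("wPLI rises monotonically with coupling strength, lagged only", {
  bandAlpha <- bandDefinitions()[3, ]
  pair <- c("O1", "O2")
  wpliAt <- function(strength, lagMs) {
    ## quarter-period lag of the 10 Hz band centre; noise-free sources so
    ## the strength ordering is sharp
    spec <- cohortSpec(nPos = 2, nNeg = 2, fs = 250, duration = 124,
                       seed = 1, effect = "null", artifactRate = 0,
                       whiteRms = 0, jitterSd = 0,
                       coupling = list(list(channels = pair, band = "alpha",
                                            lagMs = lagMs,
                                            strength = c(A_plus = strength,
                                                         A_minus = strength))))
    meta <- data.frame(subject_id = "c", group = "A_minus", severity = 0)
    rec <- generateSubjectRecording(spec, meta, 21)
    es <- rejectAndSelectEpochs(segmentEpochs(rec), Inf, 60, seed = 1)
    W <- connMatrix(wpliMatrix(es, bandAlpha))
    W["O1", "O2"]
  }
  w <- vapply(c(0, 0.4, 0.8), wpliAt, numeric(1), lagMs = 25)
  expect_lt(w[1], 0.25)                  # finite-sample independence level
  expect_true(all(diff(w) > 0))          # monotone in strength
  expect_gt(w[3], 0.8)
  ## zero lag: shared source is instantaneous -> stays near the null level,
  ## far below the equally strong lagged coupling
  z <- wpliAt(0.8, 0)
  expect_lt(z, 0.25)
  expect_lt(z, w[3] - 0.5)
})
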