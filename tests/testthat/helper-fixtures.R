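## Shared fixtures: all built in code at test time.

## Recording with the full montage whose channels all carry `signalFun(t)`
## (a function of time in seconds) plus optional per-channel noise.
montageRecording <- function(signalFun, fs = 250, duration = 20,
                             noiseSd = 0, seed = 1, id = "fix") {
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  base <- signalFun(t)
  set.seed(seed)
  dat <- matrix(rep(base, each = 19), 19, n) +
    matrix(rnorm(19 * n, 0, noiseSd), 19, n)
  rownames(dat) <- montage1020()
  new("EEGRecording", subjectID = id, data = dat, fs = fs,
      channels = montage1020(), metadata = list())
}

## EpochSet with independent white-noise channels.
noiseEpochs <- function(nEpochs = 60, nCh = 19, fs = 250, epochLength = 2,
                        seed = 1, sd = 1) {
  set.seed(seed)
  spe <- round(fs * epochLength)
  arr <- array(rnorm(nEpochs * nCh * spe, 0, sd), c(nEpochs, nCh, spe))
  new("EpochSet", subjectID = "noise", epochs = arr, fs = fs,
      epochLength = epochLength,
      channels = montage1020()[seq_len(nCh)],
      selectedIndices = seq_len(nEpochs))
}

## EpochSet from explicit per-channel continuous signals (channels x samples),
## segmented into epochs.
epochsFromSignal <- function(dat, fs = 250, epochLength = 2, id = "sig") {
  labs <- montage1020()[seq_len(nrow(dat))]
  rec <- new("EEGRecording", subjectID = id, data = dat, fs = fs,
             channels = labs, metadata = list())
  segmentEpochs(rec, epochLength)
}

## Two-channel lagged-copy epochs: channel 2 is channel 1 delayed by
## `lagSamples`, with independent noise of sd `noiseSd` on both.
laggedPairEpochs <- function(freqHz = 10, lagSamples = 6, nEpochs = 60,
                             fs = 250, epochLength = 2, noiseSd = 0.05,
                             seed = 1) {
  set.seed(seed)
  n <- round(fs * epochLength) * nEpochs + lagSamples
  ## narrowband source: sinusoid with slowly drifting phase + noise
  src <- sin(2 * pi * freqHz * (seq_len(n) - 1) / fs +
               cumsum(rnorm(n, 0, 0.05)))
  x <- src[(lagSamples + 1):n]
  y <- src[1:(n - lagSamples)]
  m <- length(x)
  dat <- rbind(x + rnorm(m, 0, noiseSd), y + rnorm(m, 0, noiseSd))
  epochsFromSignal(dat, fs, epochLength)
}

## Random symmetric nonnegative weight matrix with zero diagonal.
randomW <- function(n, seed, density = 1) {
  set.seed(seed)
  W <- matrix(runif(n * n), n)
  W[upper.tri(W)] <- W[upper.tri(W)] * (runif(sum(upper.tri(W))) < density)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

## Brute-force oracles for the graph metrics (deliberately different code
## paths from the implementations: explicit loops / igraph).
oracleCC <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  out <- numeric(n)
  if (mx == 0) return(out)
  Wh <- (W / mx)^(1 / 3)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (l in nb)
      if (j != l) s <- s + Wh[i, j] * Wh[j, l] * Wh[l, i]
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracleNS <- function(W) {
  vapply(seq_len(nrow(W)), function(i) sum(W[i, -i]), numeric(1))
}

oracleE <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(
    W, mode = "undirected", weighted = TRUE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

## Feature SummarizedExperiment with pure-noise features.
noiseFeatureTable <- function(nPos = 24, nNeg = 82, p = 305, seed = 1) {
  set.seed(seed)
  n <- nPos + nNeg
  X <- matrix(rnorm(n * p), n,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  meta <- data.frame(subject_id = rownames(X),
                     group = rep(c("A_plus", "A_minus"), c(nPos, nNeg)),
                     age = rnorm(n, 70, 6))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    colData = S4Vectors::DataFrame(meta, row.names = meta$subject_id))
}

## Feature table with one perfectly separating column among noise columns.
plantedFeatureTable <- function(nPos = 24, nNeg = 82, p = 50, seed = 1,
                                gap = 3) {
  tab <- noiseFeatureTable(nPos, nNeg, p, seed)
  a <- SummarizedExperiment::assay(tab, "features")
  a["f001", ] <- rnorm(ncol(a), 0, 0.3) +
    ifelse(SummarizedExperiment::colData(tab)$group == "A_plus", gap, 0)
  SummarizedExperiment::assays(tab)$features <- a
  tab
}

## Cached expensive fixtures, computed at most once per test run.
.fixtureCache <- new.env(parent = emptyenv())
cachedFixture <- function(name, expr) {
  if (!exists(name, .fixtureCache)) assign(name, force(expr), .fixtureCache)
  get(name, .fixtureCache)
}
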