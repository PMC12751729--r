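#' Borderline-SMOTE oversampling (borderline-1 variant)
#'
#' Identifies minority-class "danger" points — those whose `k` nearest
#' neighbours (over both classes) contain at least `k/2` but fewer than `k`
#' majority points — and synthesises new minority samples as convex
#' combinations between danger points and their nearest minority-class
#' neighbours, until the minority count matches the majority count.
#' Minority points surrounded exclusively by majority neighbours are treated
#' as noise and never used for synthesis. Deterministic given `seed`.
#'
#' @param X numeric matrix (samples x features).
#' @param y binary labels (logical, or any two-level vector); the rarer
#'   level is oversampled.
#' @param kNeighbors neighbourhood size (default 5).
#' @param seed integer seed.
#' @return List with augmented `X` and `y` (synthetic rows appended). If the
#'   classes are already balanced, or no danger points exist (with a
#'   warning), the input is returned unchanged.
#' @export
borderlineSmote <- function(X, y, kNeighbors = 5, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  lev <- unique(y)
  if (length(lev) != 2) stop("y must have exactly two classes")
  counts <- c(sum(y == lev[1]), sum(y == lev[2]))
  if (counts[1] == counts[2]) return(list(X = X, y = y))
  minLev <- lev[which.min(counts)]
  majLev <- lev[which.max(counts)]
  minIdx <- which(y == minLev)
  nSynth <- max(counts) - min(counts)
  if (length(minIdx) < kNeighbors + 1)
    stop(sprintf(
      "minority class has %d members; Borderline-SMOTE with k = %d needs at least %d",
      length(minIdx), kNeighbors, kNeighbors + 1))
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  ## danger screen: majority count among each minority point's k-NN
  nMajNN <- vapply(minIdx, function(i) {
    nn <- order(D[i, ])[seq_len(kNeighbors)]
    sum(y[nn] == majLev)
  }, numeric(1))
  danger <- minIdx[nMajNN >= kNeighbors / 2 & nMajNN < kNeighbors]
  if (!length(danger)) {
    warning("no borderline minority points; no synthetic samples generated")
    return(list(X = X, y = y))
  }
  withSeed(seed, {
    src <- danger[sample.int(length(danger), nSynth, replace = TRUE)]
    synth <- matrix(NA_real_, nSynth, ncol(X))
    for (s in seq_len(nSynth)) {
      i <- src[s]
      others <- setdiff(minIdx, i)
      nnMin <- others[order(D[i, others])[seq_len(min(kNeighbors,
                                                      length(others)))]]
      nb <- nnMin[sample.int(length(nnMin), 1)]
      u <- runif(1)
      synth[s, ] <- X[i, ] + u * (X[nb, ] - X[i, ])
    }
    colnames(synth) <- colnames(X)
    list(X = rbind(X, synth), y = c(y, rep(minLev, nSynth)))
  })
}
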