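#' Proportional thresholding of a connectivity matrix
#'
#' Retains the `round(p * n(n-1)/2)` largest off-diagonal weights (ties
#' broken deterministically by first occurrence in row-major upper-triangle
#' order) and zeroes the rest, preserving the retained weights and symmetry.
#' Proportional (rather than absolute) thresholding keeps network density
#' comparable across subjects and mitigates spurious weak connections.
#'
#' @param W symmetric numeric matrix (or [ConnectivityMatrix-class]).
#' @param p proportion of edges to keep, in (0, 1].
#' @return Thresholded matrix of the same class as the input.
#' @export
#' @examples
#' W <- matrix(runif(19 * 19), 19); W <- (W + t(W)) / 2; diag(W) <- 0
#' sum(proportionalThreshold(W, 0.05)[upper.tri(W)] > 0)  # 9 edges
proportionalThreshold <- function(W, p) {
  if (is(W, "ConnectivityMatrix")) {
    out <- W
    out@W <- proportionalThreshold(W@W, p)
    return(out)
  }
  if (!(p > 0 && p <= 1)) stop("p must lie in (0, 1]")
  n <- nrow(W)
  nEdges <- n * (n - 1) / 2
  keep <- round(p * nEdges)
  ## upper-triangle entries in row-major order (row index varies slowest)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- W[idx]
  ord <- order(vals, decreasing = TRUE, method = "radix")  # stable ties
  drop <- ord[-seq_len(keep)]
  out <- W
  if (length(drop)) {
    out[idx[drop, , drop = FALSE]] <- 0
    out[idx[drop, c(2, 1), drop = FALSE]] <- 0
  }
  out
}

#' Weighted clustering coefficient (geometric-mean triangle intensity)
#'
#' Onnela-style weighted clustering: weights are normalised by the matrix
#' maximum, and
#' `C_i = sum_{j,k} (w_ij w_jk w_ki)^{1/3} / (k_i (k_i - 1))` with `k_i` the
#' binary degree; `C_i = 0` when `k_i < 2`. Values lie in `[0, 1]`.
#'
#' @param W symmetric nonnegative matrix with zero diagonal (or
#'   [ConnectivityMatrix-class]).
#' @return Named per-node numeric vector.
#' @export
weightedClusteringCoef <- function(W) {
  if (is(W, "ConnectivityMatrix")) W <- W@W
  if (any(W < 0)) stop("negative weights are not allowed")
  mx <- max(W)
  if (mx == 0) return(setNames(rep(0, nrow(W)), rownames(W)))
  Wn <- (W / mx)^(1 / 3)
  triples <- diag(Wn %*% Wn %*% Wn)
  k <- rowSums(W > 0)
  cc <- ifelse(k >= 2, triples / (k * (k - 1)), 0)
  setNames(cc, rownames(W))
}

#' Node strength
#'
#' Sum of each node's edge weights, `s_i = sum_j w_ij`.
#'
#' @param W symmetric matrix with zero diagonal (or
#'   [ConnectivityMatrix-class]).
#' @return Named per-node numeric vector.
#' @export
nodeStrength <- function(W) {
  if (is(W, "ConnectivityMatrix")) W <- W@W
  setNames(rowSums(W), rownames(W))
}

## All-pairs weighted shortest-path lengths with edge length 1/w, by
## vectorised Floyd-Warshall (n = 19 makes this trivial).
.shortestPaths <- function(W) {
  n <- nrow(W)
  d <- ifelse(W > 0, 1 / W, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

#' Global efficiency
#'
#' Mean inverse weighted shortest-path length over ordered node pairs, with
#' edge lengths `1/w` and `1/d = 0` for disconnected pairs. For edge weights
#' in `[0, 1]` the result lies in `[0, 1]`; 1 corresponds to an all-to-all
#' unit-weight network.
#'
#' @param W symmetric nonnegative matrix (or [ConnectivityMatrix-class]).
#' @return Scalar efficiency.
#' @export
globalEfficiency <- function(W) {
  if (is(W, "ConnectivityMatrix")) W <- W@W
  if (any(W < 0)) stop("negative weights are not allowed")
  n <- nrow(W)
  if (n < 2) return(0)
  d <- .shortestPaths(W)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Threshold-averaged network features for all bands
#'
#' For each band's connectivity matrix and each proportional threshold
#' (default 5% to 35% in 5% steps), computes weighted clustering
#' coefficients, node strengths and global efficiency on the thresholded
#' weighted matrix, then averages each metric across thresholds. `Global`
#' clustering and strength entries are the nodal means. With the 19-channel
#' montage and five bands this yields 205 network features per subject
#' (per band: 19+1 CC, 19+1 NS, 1 E).
#'
#' @param wByBand named list of [ConnectivityMatrix-class] (one per band),
#'   as from [wpliAllBands()].
#' @param thresholds proportions to average over (default
#'   `seq(0.05, 0.35, by = 0.05)`).
#' @return Named numeric vector `<band>_CC_<loc>`, `<band>_NS_<loc>`,
#'   `<band>_E`.
#' @export
networkFeatureVector <- function(wByBand,
                                 thresholds = seq(0.05, 0.35, by = 0.05)) {
  out <- numeric(0)
  for (band in names(wByBand)) {
    W <- wByBand[[band]]
    if (is(W, "ConnectivityMatrix")) W <- W@W
    labs <- rownames(W) %||% as.character(seq_len(nrow(W)))
    cc <- ns <- matrix(0, length(thresholds), nrow(W))
    ef <- numeric(length(thresholds))
    for (ti in seq_along(thresholds)) {
      Wt <- proportionalThreshold(W, thresholds[ti])
      cc[ti, ] <- weightedClusteringCoef(Wt)
      ns[ti, ] <- nodeStrength(Wt)
      ef[ti] <- globalEfficiency(Wt)
    }
    ccm <- colMeans(cc); nsm <- colMeans(ns)
    v <- c(setNames(c(ccm, mean(ccm)),
                    paste0(band, "_CC_", c(labs, "Global"))),
           setNames(c(nsm, mean(nsm)),
                    paste0(band, "_NS_", c(labs, "Global"))),
           setNames(mean(ef), paste0(band, "_E")))
    out <- c(out, v)
  }
  out
}

#' All 305 EEG features for one preprocessed subject
#'
#' Concatenates the 100 relative-power features ([spectralFeatures()]) and
#' the 205 threshold-averaged network features ([networkFeatureVector()]
#' over [wpliAllBands()]).
#'
#' @param es an [EpochSet-class] of selected clean epochs.
#' @param thresholds proportional thresholds (default 0.05-0.35 step 0.05).
#' @return Named numeric vector of length 305.
#' @export
subjectEEGFeatures <- function(es, thresholds = seq(0.05, 0.35, by = 0.05)) {
  c(spectralFeatures(es),
    networkFeatureVector(wpliAllBands(es), thresholds))
}
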