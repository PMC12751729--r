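#' Moment-based normality screen
#'
#' Declares a sample acceptably normal when |sample skewness| < 2 and
#' |sample excess kurtosis| < 7, the conventional screening thresholds for
#' moderate cohort sizes.
#'
#' @param x numeric sample (n >= 3, non-constant).
#' @return `TRUE`/`FALSE`.
#' @export
normalityCheck <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  skew <- mean((x - m)^3) / m2^1.5
  exKurt <- mean((x - m)^4) / m2^2 - 3
  abs(skew) < 2 && abs(exKurt) < 7
}

.groupResult <- function(statistic, p, effect, type, ci = NULL, n1 = NA,
                         n2 = NA) {
  list(statistic = statistic, p_value = p, effect_size = effect,
       effect_type = type, ci95 = ci, n1 = n1, n2 = n2)
}

#' Independent two-sample t test with pooled-SD Cohen's d
#'
#' Two-sided pooled-variance t test plus Cohen's d computed with the pooled
#' SD. The sign convention is `d = (mean(x2) - mean(x1)) / s_pooled`:
#' positive when the second group (conventionally A-) exceeds the first
#' (A+). The 95% CI uses the large-sample d standard error
#' `sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2)))`. Raw samples or group
#' summaries `(mean, sd, n)` are accepted; both routes give identical d.
#'
#' @param x1,x2 numeric samples, or `NULL` when summaries are supplied.
#' @param summary1,summary2 optional `c(mean, sd, n)` per group.
#' @return List with `statistic` (t), `p_value`, `effect_size` (d),
#'   `effect_type`, `ci95`, `n1`, `n2`.
#' @export
#' @examples
#' independentTAndD(summary1 = c(26.42, 2.78, 24),
#'                  summary2 = c(28.10, 1.75, 82))$effect_size  # 0.83
independentTAndD <- function(x1 = NULL, x2 = NULL, summary1 = NULL,
                             summary2 = NULL) {
  if (!is.null(x1)) {
    summary1 <- c(mean(x1), sd(x1), length(x1))
    summary2 <- c(mean(x2), sd(x2), length(x2))
  }
  m1 <- summary1[1]; s1 <- summary1[2]; n1 <- summary1[3]
  m2 <- summary2[1]; s2 <- summary2[2]; n2 <- summary2[3]
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tstat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  d <- (m2 - m1) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  .groupResult(tstat, p, d, "cohens_d", ci = c(d - 1.96 * se, d + 1.96 * se),
               n1 = n1, n2 = n2)
}

#' Paired t test with the paired Cohen's d
#'
#' Two-sided paired t on `diff = pre - post`;
#' `d = mean(diff) / sd(diff)`, negative when follow-up exceeds baseline.
#'
#' @param xPre,xPost equal-length numeric samples.
#' @return Same structure as [independentTAndD()].
#' @export
pairedTAndD <- function(xPre, xPost) {
  if (length(xPre) != length(xPost)) stop("samples must be paired")
  n <- length(xPre)
  if (n < 2) stop("need n >= 2 pairs")
  diff <- xPre - xPost
  sdd <- sd(diff)
  if (sdd == 0) stop("zero variance of paired differences")
  d <- mean(diff) / sdd
  tstat <- d * sqrt(n)
  p <- 2 * pt(-abs(tstat), df = n - 1)
  .groupResult(tstat, p, d, "cohens_d", n1 = n, n2 = n)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of counts.
#' @return Same structure as [independentTAndD()] with `effect_type`
#'   `"none"`.
#' @export
#' @examples
#' chiSquareTest(matrix(c(12, 9, 12, 73), 2))  # APOE4-carrier style table
chiSquareTest <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal total")
  expd <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expd)^2 / expd)
  .groupResult(stat, pchisq(stat, df = 1, lower.tail = FALSE), NA_real_,
               "none", n1 = sum(counts[, 1]), n2 = sum(counts[, 2]))
}

#' ANCOVA group effect with partial eta squared
#'
#' Linear model `y ~ covariate + group`; the group effect is tested by the
#' extra-sum-of-squares F comparing the covariate-only model with the full
#' model, and `partial eta^2 = SS_group / (SS_group + SS_residual)`. Any
#' numeric covariate is accepted (age in the primary analyses, global
#' amyloid SUVR in sensitivity analyses).
#'
#' @param y numeric response.
#' @param group two-level factor or character vector.
#' @param covariate numeric covariate.
#' @return Same structure as [independentTAndD()] with `effect_type`
#'   `"partial_eta_squared"`.
#' @export
ancovaPartialEta2 <- function(y, group, covariate) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (length(y) < 4) stop("need n >= 4")
  g <- as.numeric(group) - 1
  r <- suppressWarnings(cor(g, covariate))
  if (is.finite(r) && abs(r) > 0.999)
    stop("covariate is collinear with the group indicator")
  full <- lm(y ~ covariate + group)
  red <- lm(y ~ covariate)
  ssRes <- sum(residuals(full)^2)
  ssGroup <- sum(residuals(red)^2) - ssRes
  dfRes <- full$df.residual
  fstat <- (ssGroup / 1) / (ssRes / dfRes)
  p <- pf(fstat, 1, dfRes, lower.tail = FALSE)
  eta <- ssGroup / (ssGroup + ssRes)
  .groupResult(fstat, p, eta, "partial_eta_squared",
               n1 = sum(group == levels(group)[1]),
               n2 = sum(group == levels(group)[2]))
}

#' Age-adjusted partial correlation with bootstrap CI
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on the
#' covariate (with intercept); the p-value uses
#' `t = r sqrt((n-3)/(1-r^2))` on `n - 3` degrees of freedom. The 95%
#' percentile CI comes from `nBoot` subject-level resamples (seeded, hence
#' deterministic).
#'
#' @param x,y numeric samples.
#' @param covariate numeric covariate to partial out.
#' @param nBoot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @return List with `r`, `p_value`, `ci95`, `n`, `n_boot`.
#' @export
partialCorrelationBootstrap <- function(x, y, covariate, nBoot = 5000,
                                        seed = 1L) {
  keep <- complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; covariate <- covariate[keep]
  n <- length(x)
  if (n < 5) stop("need n >= 5 complete cases")
  r <- .partialR(x, y, covariate)
  if (!is.finite(r)) stop("constant residuals: partial correlation undefined")
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 3)
  boot <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nBoot, n)
    .partialRRows(x, y, covariate, idx)
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  list(r = r, p_value = p, ci95 = ci, n = n, n_boot = nBoot)
}

## Partial correlation via the residual route (equivalent closed form used
## for the vectorised bootstrap).
.partialR <- function(x, y, z) {
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

## Row-wise partial correlations for a matrix of resample indices, using the
## moment identity r_xy.z = (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2)).
.partialRRows <- function(x, y, z, idx) {
  n <- ncol(idx)
  X <- matrix(x[idx], nrow(idx)); Y <- matrix(y[idx], nrow(idx))
  Z <- matrix(z[idx], nrow(idx))
  rowCor <- function(A, B) {
    a <- A - rowMeans(A); b <- B - rowMeans(B)
    rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  }
  rxy <- rowCor(X, Y); rxz <- rowCor(X, Z); ryz <- rowCor(Y, Z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Group-comparison report for a feature table
#'
#' Applies [ancovaPartialEta2()] (or [independentTAndD()] when no covariate
#' is given) to every feature column, returning a tidy report in the style
#' of cohort-paper EEG tables: group means +/- SD, statistic, effect size
#' and p-value per feature. An optional Benjamini-Hochberg adjusted column
#' can be added; it is off by default, mirroring the single-comparison
#' convention of the exploratory analyses this package models.
#'
#' @param X subjects x features numeric matrix (named columns).
#' @param group two-level grouping vector (first level = A+ convention).
#' @param covariate optional numeric covariate (e.g. age).
#' @param fdr logical; append a BH-adjusted p column.
#' @return data.frame, one row per feature.
#' @export
groupComparisonReport <- function(X, group, covariate = NULL, fdr = FALSE) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2)
  g1 <- group == levels(group)[1]
  rows <- lapply(colnames(X), function(f) {
    y <- X[, f]
    res <- if (is.null(covariate))
      independentTAndD(y[g1], y[!g1])
    else ancovaPartialEta2(y, group, covariate)
    data.frame(feature = f,
               mean1 = mean(y[g1]), sd1 = sd(y[g1]),
               mean2 = mean(y[!g1]), sd2 = sd(y[!g1]),
               statistic = res$statistic, effect_size = res$effect_size,
               effect_type = res$effect_type, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (fdr) out$p_adj <- p.adjust(out$p_value, "BH")
  out
}
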