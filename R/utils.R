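#' @useDynLib scdEEG, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats sd var rnorm runif rbinom rpois lm anova pt pchisq pf
#'   residuals qnorm quantile cor fft mvfft complete.cases setNames
#'   p.adjust dist
#' @importFrom utils write.table read.table head
NULL

## Counter-based child seed scheme: reproducible regardless of the order in
## which subjects are generated. Kept below 2^31 - 1.
childSeed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((as.double(seed) %% 2147483647 * 48271 + 104729 * index) %%
               2147483629) + 1L
}

## Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

clip01 <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
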