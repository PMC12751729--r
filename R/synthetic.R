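#' Specification of a synthetic two-group SCD EEG cohort
#'
#' Builds the parameter object consumed by [generateCohort()] and
#' [generateSubjectRecording()]. Defaults emulate the statistical structure of
#' an amyloid-stratified subjective-cognitive-decline cohort: 24
#' amyloid-positive (A+) and 82 amyloid-negative (A-) subjects, at least
#' 3 minutes of eyes-closed 19-channel EEG per subject, elevated delta/theta
#' and reduced alpha power in A+, weaker posterior alpha-band phase coupling
#' in A+, an age offset between groups, APOE4 carrier rates of 50% vs 11%,
#' and cognitive percentile scores negatively tied to the latent severity
#' that also drives each subject's EEG profile.
#'
#' @param nPos,nNeg group sizes (A+ and A-).
#' @param fs sampling rate in Hz. The study range 1-55 Hz requires
#'   `fs > 110`; 250 Hz is the default.
#' @param duration recording length in seconds (>= 180 by default).
#' @param effect preset for the planted effect strength: `"paper"`
#'   (group differences calibrated to ANCOVA partial eta squared around
#'   0.04-0.10 on the affected features), `"strong"` (nearly separable
#'   groups, for validating classifiers on planted signal) or `"null"`
#'   (no group differences anywhere, for calibration tests).
#' @param seed integer master seed; per-subject seeds are derived from it by
#'   a stable counter scheme so cohorts are reproducible regardless of
#'   generation order.
#' @param ... named overrides for any element of the internal parameter list
#'   (e.g. `artifactRate`, `bandProfiles`, `coupling`, `ageMean`).
#'
#' @return An object of class `CohortSpec`.
#' @export
#' @examples
#' spec <- cohortSpec(nPos = 3, nNeg = 4, duration = 180, seed = 1)
#' spec
cohortSpec <- function(nPos = 24, nNeg = 82, fs = 250, duration = 180,
                       effect = c("paper", "strong", "null"), seed = 1L,
                       ...) {
  effect <- match.arg(effect)
  bands <- bandDefinitions()$name
  one <- setNames(rep(1, 5), bands)
  ## the band profile is a pathology direction shared by every subject;
  ## each subject expresses it in proportion to its latent severity, so
  ## group contrasts and within-cohort severity correlations arise from the
  ## same mechanism (the groups differ only in severity distribution)
  profiles <- switch(effect,
    paper = {
      pathology <- c(delta = 1.26, theta = 1.27, alpha = 0.905,
                     beta = 0.985, gamma = 1.00)
      list(A_plus = pathology, A_minus = pathology)
    },
    strong = list(
      A_plus  = c(delta = 2.50, theta = 1.90, alpha = 0.40, beta = 0.90,
                  gamma = 1.00),
      A_minus = one),
    null = list(A_plus = one, A_minus = one))
  severity <- switch(effect,
    paper  = list(A_plus = c(mean = 2.20, sd = 1.00),
                  A_minus = c(mean = 1.20, sd = 1.00)),
    strong = list(A_plus = c(mean = 1.00, sd = 0.10),
                  A_minus = c(mean = 0.00, sd = 0.10)),
    null   = list(A_plus = c(mean = 0, sd = 0), A_minus = c(mean = 0, sd = 0)))
  alphaStrength <- switch(effect,
    paper = c(A_plus = 0.46, A_minus = 0.53),
    strong = c(A_plus = 0.20, A_minus = 0.70),
    null = c(A_plus = 0.54, A_minus = 0.54))
  deltaStrength <- switch(effect,
    paper = c(A_plus = 0.38, A_minus = 0.32),
    strong = c(A_plus = 0.60, A_minus = 0.20),
    null = c(A_plus = 0.32, A_minus = 0.32))
  params <- list(
    bandProfiles = profiles,
    severity = severity,
    ## per-band source RMS amplitude (uV) before group/topography scaling;
    ## solved together with the 1/f background so baseline relative powers
    ## sit at realistic eyes-closed values (delta ~23%, theta ~14%,
    ## alpha ~30% rising posteriorly, beta ~22%, gamma ~5%)
    bandRms = c(delta = 3.3, theta = 2.7, alpha = 4.9, beta = 3.6,
                gamma = 0.4),
    backgroundRms = 5.3, whiteRms = 1.3,
    ## per-subject per-band lognormal amplitude jitter (sdlog)
    jitterSd = if (effect == "strong") 0.10 else 0.25,
    coupling = list(
      list(channels = .posteriorChannels, band = "alpha", lagMs = 10,
           strength = alphaStrength),
      list(channels = .frontalChannels, band = "delta", lagMs = 16,
           strength = deltaStrength)),
    ageMean = c(A_plus = 73.42, A_minus = 69.82),
    ageSd = c(A_plus = 5.64, A_minus = 6.05),
    apoe4Rates = c(A_plus = 0.50, A_minus = 0.11),
    sexMaleRates = c(A_plus = 0.583, A_minus = 0.390),
    eduMean = c(A_plus = 12.71, A_minus = 11.04),
    eduSd = c(A_plus = 4.07, A_minus = 3.88),
    artifactRate = 2, artifactAmplitude = 400,
    scoreBaseline = 72, scoreSlope = 15, scoreNoiseSd = 5,
    scoreNames = c("MMSE", "BNT", "SVLT", "DSC"))
  if (effect == "null") {
    params$ageMean[] <- 70
    params$apoe4Rates[] <- 0.2
    params$sexMaleRates[] <- 0.45
    params$eduMean[] <- 11.5
  }
  override <- list(...)
  bad <- setdiff(names(override), names(params))
  if (length(bad))
    stop("unknown cohortSpec parameter(s): ", paste(bad, collapse = ", "))
  params[names(override)] <- override
  obj <- new("CohortSpec", nPos = as.integer(nPos), nNeg = as.integer(nNeg),
             fs = fs, duration = duration, seed = as.integer(seed),
             effect = effect, params = params)
  validObject(obj)
  obj
}

#' @rdname cohortSpec
#' @export
setClass("CohortSpec",
  representation(nPos = "integer", nNeg = "integer", fs = "numeric",
                 duration = "numeric", seed = "integer", effect = "character",
                 params = "list"))

setValidity("CohortSpec", function(object) {
  p <- object@params
  msg <- character()
  if (object@nPos < 2L || object@nNeg < 2L)
    msg <- c(msg, "both group sizes must be at least 2")
  if (object@fs <= 110)
    msg <- c(msg, "fs must exceed 110 Hz to support the 1-55 Hz range")
  bands <- bandDefinitions()$name
  for (g in names(p$bandProfiles))
    if (!setequal(names(p$bandProfiles[[g]]), bands))
      msg <- c(msg, sprintf("band profile for %s must name bands %s", g,
                            paste(bands, collapse = ", ")))
  for (cp in p$coupling) {
    if (!cp$band %in% bands)
      msg <- c(msg, sprintf("unknown coupling band '%s'", cp$band))
    if (any(cp$strength < 0 | cp$strength > 1))
      msg <- c(msg, "coupling strengths must lie in [0, 1]")
    if (cp$lagMs < 0) msg <- c(msg, "coupling lag must be >= 0 ms")
  }
  if (p$artifactRate < 0) msg <- c(msg, "artifactRate must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec ('%s' effect): %d A+ / %d A- subjects, %g s @ %g Hz, seed %d\n",
    object@effect, object@nPos, object@nNeg, object@duration, object@fs,
    object@seed))
})

## Per-band scalp topography gains: posterior-dominant alpha, frontal-leaning
## delta, flat elsewhere. Rows = bands, columns = the 19 montage channels.
.bandTopography <- function() {
  ch <- montage1020()
  topo <- matrix(1, 5, 19, dimnames = list(bandDefinitions()$name, ch))
  topo["alpha", ch %in% .posteriorChannels] <- 1.5
  topo["alpha", ch %in% .frontalChannels] <- 0.7
  topo["delta", ch %in% .frontalChannels] <- 1.3
  topo["delta", ch %in% .posteriorChannels] <- 0.9
  topo
}

## Complex-gaussian spectrum coefficients for bins `idx` of an N-point FFT,
## scaled so the real time-domain signal has unit variance.
.specCoefs <- function(idx, n) {
  m <- length(idx)
  scale <- n / sqrt(2 * m)
  complex(real = rnorm(m), imaginary = rnorm(m)) * (scale / sqrt(2))
}

## Positive-frequency bin indices (1-based into an N-point spectrum) with
## lo <= f < hi (hi inclusive when inclusiveHi).
.binIndices <- function(n, fs, lo, hi, inclusiveHi = FALSE) {
  k <- seq_len(floor(n / 2) - 1L)       # exclude DC and Nyquist
  f <- k * fs / n
  keep <- if (inclusiveHi) f >= lo & f <= hi else f >= lo & f < hi
  k[keep] + 1L
}

## Real signal from a positive-frequency half spectrum (named by bin index).
.spectrumToSignal <- function(halfSpec, n) {
  full <- complex(length.out = n)
  idx <- as.integer(names(halfSpec))
  full[idx] <- halfSpec
  full[n - idx + 2L] <- Conj(halfSpec)
  Re(fft(full, inverse = TRUE)) / n
}

#' Generate one subject's synthetic EEG recording
#'
#' Synthesises a 19-channel recording as a sum of band-limited stochastic
#' sources (some shared across channel groups with per-channel integer-sample
#' delays, implementing constant phase-lag coupling), a 1/f-shaped broadband
#' background and white sensor noise. Group membership and the subject's
#' latent severity scale the per-band amplitudes through the spec's band
#' profiles, so amyloid-positive subjects express elevated delta/theta and
#' reduced alpha power. Deterministic given `(spec, meta, seed)`.
#'
#' @param spec a [cohortSpec()] object.
#' @param meta one-row data.frame with at least `subject_id`, `group`
#'   (`"A_plus"` or `"A_minus"`) and `severity` columns, as produced by
#'   [generateCohort()].
#' @param seed integer seed for this subject.
#' @return An [EEGRecording-class] object (19 x samples, microvolts).
#' @export
generateSubjectRecording <- function(spec, meta, seed) {
  stopifnot(is(spec, "CohortSpec"))
  p <- spec@params
  group <- as.character(meta$group)
  if (!group %in% names(p$bandProfiles))
    stop("unknown group label: ", group)
  bands <- bandDefinitions()
  profile <- p$bandProfiles[[group]]
  severity <- as.numeric(meta$severity %||% 0)
  ch <- montage1020()
  n <- round(spec@duration * spec@fs)
  topo <- .bandTopography()

  withSeed(seed, {
    ## band multipliers: severity interpolates between the neutral profile
    ## (all 1) and the group's full profile; lognormal per-band jitter.
    mult <- pmax(0, 1 + severity * (profile[bands$name] - 1))
    jitter <- exp(rnorm(5, 0, p$jitterSd))
    amp <- p$bandRms[bands$name] * mult * jitter   # per-band RMS, pre-topography

    ## coupling bookkeeping: for each band, which channels take a shared
    ## source (and at what delay/strength)
    halfSpecs <- vector("list", 19)
    for (ci in seq_len(19)) halfSpecs[[ci]] <- list()
    addCoef <- function(ci, idx, coefs) {
      halfSpecs[[ci]][[length(halfSpecs[[ci]]) + 1L]] <<- list(idx = idx,
                                                              coefs = coefs)
    }
    for (bi in seq_len(nrow(bands))) {
      b <- bands$name[bi]
      idx <- .binIndices(n, spec@fs, bands$lo[bi], bands$hi[bi],
                         inclusiveHi = bands$name[bi] == "gamma")
      f <- (idx - 1L) * spec@fs / n
      coupled <- integer(0)
      for (cp in p$coupling) {
        if (cp$band != b) next
        rho <- unname(cp$strength[group])
        lagSamp <- round(cp$lagMs / 1000 * spec@fs)
        shared <- .specCoefs(idx, n)
        members <- match(cp$channels, ch)
        for (r in seq_along(members)) {
          ci <- members[r]
          d <- (r - 1L) * lagSamp
          phase <- exp(-2i * pi * (idx - 1L) * d / n)
          own <- .specCoefs(idx, n)
          coefs <- (sqrt(1 - rho^2) * own + rho * shared * phase) *
            (amp[b] * topo[b, ci])
          addCoef(ci, idx, coefs)
        }
        coupled <- c(coupled, members)
      }
      for (ci in setdiff(seq_len(19), coupled)) {
        coefs <- .specCoefs(idx, n) * (amp[b] * topo[b, ci])
        addCoef(ci, idx, coefs)
      }
    }
    ## 1/f background over the 1-55 Hz analysis range
    bgIdx <- .binIndices(n, spec@fs, 1, 55, inclusiveHi = TRUE)
    fbg <- (bgIdx - 1L) * spec@fs / n
    shape <- fbg^(-0.5)
    bgScale <- n / sqrt(2 * sum(shape^2))
    dat <- matrix(0, 19, n, dimnames = list(ch, NULL))
    for (ci in seq_len(19)) {
      g <- complex(real = rnorm(length(bgIdx)),
                   imaginary = rnorm(length(bgIdx))) / sqrt(2)
      bg <- g * shape * bgScale * p$backgroundRms
      ## merge component spectra (band supports overlap with the 1-55 Hz
      ## background support, which covers all of them)
      full <- complex(length.out = n)
      full[bgIdx] <- bg
      for (comp in halfSpecs[[ci]])
        full[comp$idx] <- full[comp$idx] + comp$coefs
      full[n - bgIdx + 2L] <- Conj(full[bgIdx])
      dat[ci, ] <- Re(fft(full, inverse = TRUE)) / n +
        rnorm(n, 0, p$whiteRms)
    }
    new("EEGRecording", subjectID = as.character(meta$subject_id), data = dat,
        fs = spec@fs, channels = ch, metadata = list())
  })
}

#' Inject high-amplitude transient artifacts into a recording
#'
#' Adds brief (0.3 s) half-sine transients of the given peak amplitude at
#' Poisson-distributed times on randomly chosen channels, emulating movement
#' or electrode-pop artifacts for exercising amplitude-based epoch rejection.
#' The event log (onset time, channel, amplitude) is kept in the returned
#' recording's metadata under `artifactEvents`.
#'
#' @param rec an [EEGRecording-class].
#' @param ratePerMin expected number of events per minute (>= 0).
#' @param amplitudeUV peak amplitude of each transient in microvolts (> 0).
#' @param seed integer seed.
#' @return A modified copy of `rec` with `metadata$artifactEvents` set.
#' @export
injectArtifacts <- function(rec, ratePerMin, amplitudeUV, seed) {
  stopifnot(is(rec, "EEGRecording"))
  if (ratePerMin < 0) stop("ratePerMin must be >= 0")
  if (amplitudeUV <= 0) stop("amplitudeUV must be positive")
  dur <- ncol(rec@data) / rec@fs
  width <- 0.3
  out <- rec
  events <- data.frame(time = numeric(0), channel = character(0),
                       amplitude = numeric(0))
  withSeed(seed, {
    nEvents <- rpois(1, ratePerMin * dur / 60)
    if (nEvents > 0) {
      times <- sort(runif(nEvents, 0, dur - width))
      chans <- sample(rec@channels, nEvents, replace = TRUE)
      signs <- sample(c(-1, 1), nEvents, replace = TRUE)
      pulseN <- round(width * rec@fs)
      pulse <- sin(pi * seq_len(pulseN) / pulseN)
      for (e in seq_len(nEvents)) {
        i0 <- floor(times[e] * rec@fs) + 1L
        ii <- i0:(i0 + pulseN - 1L)
        ci <- match(chans[e], rec@channels)
        out@data[ci, ii] <- out@data[ci, ii] + signs[e] * amplitudeUV * pulse
      }
      events <- data.frame(time = times, channel = chans,
                           amplitude = signs * amplitudeUV)
    }
  })
  out@metadata$artifactEvents <- events
  out
}

#' Attach severity-linked cognitive percentile scores to subject metadata
#'
#' Cognitive scores are percentiles generated as
#' `baseline - slope * severity + noise`, clipped to `[0, 100]`. Because the
#' same latent severity scales the subject's delta/theta-up, alpha-down EEG
#' profile, negative theta-score and positive alpha-score correlations are
#' planted by construction.
#'
#' @param meta one-or-more-row data.frame with a `severity` column.
#' @param spec a [cohortSpec()].
#' @param seed integer seed.
#' @return `meta` with one column per score name appended.
#' @export
generateCovariatesAndScores <- function(meta, spec, seed) {
  stopifnot(is(spec, "CohortSpec"), !is.null(meta$severity))
  p <- spec@params
  withSeed(seed, {
    for (s in p$scoreNames) {
      meta[[s]] <- clip01(p$scoreBaseline - p$scoreSlope * meta$severity +
                            rnorm(nrow(meta), 0, p$scoreNoiseSd))
    }
  })
  meta
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject metadata (group, age, sex, education, APOE4 carrier
#' status, latent severity, cognitive scores) and synthesises each subject's
#' recording with [generateSubjectRecording()], injecting artifacts at the
#' spec's rate. Subject seeds are derived from `spec@seed` by a stable
#' counter scheme.
#'
#' @param spec a [cohortSpec()].
#' @param recordings logical; set `FALSE` to generate metadata only
#'   (recordings can then be produced one at a time with
#'   [generateSubjectRecording()], which keeps memory flat for large
#'   cohorts).
#' @return A list with elements `meta` (data.frame, one row per subject) and
#'   `recordings` (list of [EEGRecording-class], or `NULL`).
#' @export
#' @examples
#' coh <- generateCohort(cohortSpec(nPos = 2, nNeg = 2, duration = 12,
#'                                  seed = 7), recordings = FALSE)
#' coh$meta[, c("subject_id", "group", "age", "apoe4")]
generateCohort <- function(spec, recordings = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  p <- spec@params
  nTot <- spec@nPos + spec@nNeg
  group <- rep(c("A_plus", "A_minus"), c(spec@nPos, spec@nNeg))
  meta <- withSeed(childSeed(spec@seed, 0L), {
    sev <- pmin(4.5, pmax(0, rnorm(nTot, p$severity[["A_plus"]]["mean"],
                                   p$severity[["A_plus"]]["sd"])))
    sevNeg <- pmin(4.5, pmax(0, rnorm(nTot, p$severity[["A_minus"]]["mean"],
                                      p$severity[["A_minus"]]["sd"])))
    sev[group == "A_minus"] <- sevNeg[group == "A_minus"]
    data.frame(
      subject_id = sprintf("S%03d", seq_len(nTot)),
      group = group,
      age = round(rnorm(nTot, p$ageMean[group], p$ageSd[group]), 1),
      sex = ifelse(runif(nTot) < p$sexMaleRates[group], "male", "female"),
      education_years = round(pmax(0, rnorm(nTot, p$eduMean[group],
                                            p$eduSd[group]))),
      apoe4 = runif(nTot) < p$apoe4Rates[group],
      severity = sev,
      stringsAsFactors = FALSE)
  })
  meta <- generateCovariatesAndScores(meta, spec, childSeed(spec@seed, 1L))
  recs <- NULL
  if (recordings) {
    recs <- lapply(seq_len(nTot), function(i)
      .subjectRecording(spec, meta[i, ], i))
    names(recs) <- meta$subject_id
  }
  list(meta = meta, recordings = recs)
}

## One subject's recording with artifacts, using the counter seed scheme.
.subjectRecording <- function(spec, metaRow, i) {
  rec <- generateSubjectRecording(spec, metaRow, childSeed(spec@seed, 10L + i))
  if (spec@params$artifactRate > 0)
    rec <- injectArtifacts(rec, spec@params$artifactRate,
                           spec@params$artifactAmplitude,
                           childSeed(spec@seed, 100000L + i))
  rec
}

#' Check that a recording satisfies the study's acquisition invariants
#'
#' Verifies the full 19-channel 10-20 montage (after label normalisation)
#' and at least 180 s of signal.
#'
#' @param rec an [EEGRecording-class].
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
checkStudyRecording <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  labs <- normalizeChannelLabels(rec@channels)
  if (!setequal(labs, montage1020()) || length(labs) != 19L)
    stop("recording must carry exactly the 19-channel 10-20 montage")
  if (ncol(rec@data) / rec@fs < 180)
    stop("recording must be at least 180 s long")
  invisible(TRUE)
}
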