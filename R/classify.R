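#' Assemble the subjects-by-features table
#'
#' Joins per-subject spectral and network features with metadata into a
#' [SummarizedExperiment::SummarizedExperiment] (features as rows, subjects
#' as columns, metadata as `colData`). In `"eeg"` mode the feature set is
#' the 305 EEG features (100 relative power, 100 clustering, 100 strength,
#' 5 efficiency) plus age — 306 columns in documented order. In
#' `"demographic"` mode it is age, sex, education, APOE4 status, the
#' cognitive scores and any additional numeric metadata columns.
#' No z-scoring is applied here: scaling is fitted inside cross-validation
#' (or globally, via the replicate-paper switch of [cvEvaluate()]).
#'
#' @param spectral subjects x 100 matrix from [spectralFeatures()] rows.
#' @param network subjects x 205 matrix from [networkFeatureVector()] rows.
#' @param meta data.frame with `subject_id`, `group` and demographic/score
#'   columns; every subject in `spectral`/`network` must be present.
#' @param mode `"eeg"` or `"demographic"`.
#' @return A `SummarizedExperiment`; `assay(x)` is features x subjects and
#'   `colData(x)$group` carries the labels (`A_plus` = positive class).
#' @export
buildFeatureTable <- function(spectral, network, meta,
                              mode = c("eeg", "demographic")) {
  mode <- match.arg(mode)
  ids <- rownames(spectral) %||% meta$subject_id
  if (is.null(rownames(spectral))) rownames(spectral) <- ids
  if (!setequal(ids, meta$subject_id) ||
      (mode == "eeg" && !setequal(ids, rownames(network))))
    stop("subject sets of features and metadata do not match")
  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  if (mode == "eeg") {
    network <- network[ids, , drop = FALSE]
    X <- cbind(spectral, network, age = meta$age)
  } else {
    num <- meta[, setdiff(colnames(meta),
                          c("subject_id", "group", "severity")),
                drop = FALSE]
    num$sex <- as.numeric(factor(num$sex)) - 1
    num$apoe4 <- as.numeric(num$apoe4)
    keep <- vapply(num, is.numeric, logical(1))
    X <- as.matrix(num[, keep, drop = FALSE])
    rownames(X) <- ids
  }
  if (anyNA(X)) stop("missing values in the assembled feature table")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    colData = S4Vectors::DataFrame(meta, row.names = ids),
    metadata = list(mode = mode))
}

## subjects x features matrix and positive-class logical from a feature SE.
## Subjects are sorted by identifier so results are invariant to the row
## order in which the table was assembled.
.tableXY <- function(table) {
  X <- t(SummarizedExperiment::assay(table, "features"))
  y <- SummarizedExperiment::colData(table)$group == "A_plus"
  ord <- order(rownames(X))
  list(X = X[ord, , drop = FALSE], y = y[ord])
}

#' Stream a synthetic cohort through the full feature pipeline
#'
#' Generates each subject, preprocesses (band-pass, 2-s epochs, artifact
#' rejection, selection of `nSelect` clean epochs) and extracts the 305 EEG
#' features, discarding the raw signal before the next subject so that
#' memory stays flat.
#'
#' @param spec a [cohortSpec()].
#' @param nSelect epochs retained per subject (default 60).
#' @param bands band definitions (default all five; relative power always
#'   uses all of these).
#' @param networkBands band names for which connectivity/network features
#'   are computed (default all; restrict for cheap targeted runs).
#' @param onFail `"error"` (default) propagates a failing subject's error
#'   (e.g. too few artifact-free epochs); `"skip"` drops that subject and
#'   lists it in the result's `failed` element, matching the cohort
#'   pipeline's continuation policy.
#' @return List with `spectral` (subjects x 100), `network`
#'   (subjects x 205, fewer if `networkBands` is restricted), `meta`
#'   (surviving subjects) and `failed` (character messages).
#' @export
extractCohortFeatures <- function(spec, nSelect = 60,
                                  bands = bandDefinitions(),
                                  thresholds = seq(0.05, 0.35, by = 0.05),
                                  networkBands = bands$name,
                                  onFail = c("error", "skip")) {
  onFail <- match.arg(onFail)
  coh <- generateCohort(spec, recordings = FALSE)
  meta <- coh$meta
  nb <- bands[bands$name %in% networkBands, , drop = FALSE]
  spectralRows <- list(); networkRows <- list()
  ok <- logical(nrow(meta)); failed <- character(0)
  for (i in seq_len(nrow(meta))) {
    res <- tryCatch({
      rec <- .subjectRecording(spec, meta[i, ], i)
      es <- preprocessRecording(rec, nSelect = nSelect,
                                seed = childSeed(spec@seed, 200000L + i))
      ft <- .epochFFT(es)
      psd <- welchPsd(es, ft)
      rel <- relativeBandPower(psd, bands)
      sv <- as.vector(t(rel))
      names(sv) <- paste0(rep(rownames(rel), each = ncol(rel)), "_power_",
                          rep(colnames(rel), nrow(rel)))
      list(sv = sv,
           net = networkFeatureVector(wpliAllBands(es, nb, ft), thresholds))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (onFail == "error") stop(res)
      failed <- c(failed, conditionMessage(res))
    } else {
      ok[i] <- TRUE
      spectralRows[[i]] <- res$sv
      networkRows[[i]] <- res$net
    }
  }
  meta <- meta[ok, , drop = FALSE]
  spectral <- do.call(rbind, spectralRows[ok])
  network <- do.call(rbind, networkRows[ok])
  rownames(spectral) <- rownames(network) <- meta$subject_id
  list(spectral = spectral, network = network, meta = meta, failed = failed)
}

#' Classification metrics from confusion counts
#'
#' @param tp,fp,tn,fn confusion counts (positive class = A+).
#' @return Named vector: accuracy, sensitivity, specificity, mcc, f1. MCC is
#'   0 by convention when any marginal factor vanishes; sensitivity /
#'   specificity / F1 are `NaN`-free (0/0 yields `NA` for sensitivity and
#'   specificity only when the relevant class is absent).
#' @export
classificationMetrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion table")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(accuracy = (tp + tn) / total, sensitivity = sens, specificity = spec,
    mcc = mcc, f1 = f1)
}

## Stratified fold assignment: per class, shuffle then round-robin, so fold
## class proportions stay within one member of the global proportions.
.stratifiedFolds <- function(y, nFolds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < nFolds)
        warning(sprintf(
          "class '%s' has %d members for %d folds; some folds lack it",
          cl, length(idx), nFolds))
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
  })
  fold
}

## Column-wise z-scoring fitted on the training rows; constant columns are
## floored to zero rather than dividing by ~0.
.zscale <- function(train, test = NULL) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  flat <- sdv < 1e-12
  sdv[flat] <- 1
  scaleIt <- function(M) {
    M <- sweep(M, 2, mu); M <- sweep(M, 2, sdv, `/`)
    M[, flat] <- 0
    M
  }
  list(train = scaleIt(train), test = if (!is.null(test)) scaleIt(test),
       flat = flat)
}

## Per-fold scaled + oversampled design matrices over the full feature set.
.foldData <- function(X, y, nFolds, useSmote, scale, seed) {
  fold <- .stratifiedFolds(y, nFolds, seed)
  if (scale == "global") {
    Xg <- .zscale(X)$train
  }
  lapply(seq_len(nFolds), function(f) {
    tr <- fold != f
    if (scale == "global") {
      Xtr <- Xg[tr, , drop = FALSE]; Xte <- Xg[!tr, , drop = FALSE]
    } else {
      sc <- .zscale(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      Xtr <- sc$train; Xte <- sc$test
    }
    ytr <- y[tr]
    if (useSmote && length(unique(ytr)) == 2) {
      if (min(table(ytr)) >= 6) {
        sm <- suppressWarnings(
          borderlineSmote(Xtr, ytr, seed = childSeed(seed, 3000L + f)))
        Xtr <- sm$X; ytr <- sm$y
      } else {
        warning("training fold minority too small for Borderline-SMOTE; ",
                "fold left unbalanced")
      }
    }
    list(Xtr = Xtr, ytr = ytr, Xte = Xte, yte = y[!tr])
  })
}

#' Greedy sequential forward feature selection for the boosted classifier
#'
#' At each step adds the feature that maximises the stratified k-fold CV
#' accuracy of the AdaBoost stump classifier on the current subset (ties
#' broken by MCC, then first feature in column order), up to `maxFeatures`;
#' the returned set is the prefix of the growth path with the best score.
#' Fold-wise scaling and Borderline-SMOTE are fitted once per fold on the
#' full feature set, so every candidate is compared on identical folds and
#' augmentation. Deterministic given `seed`.
#'
#' @param table feature `SummarizedExperiment` from [buildFeatureTable()].
#' @param maxFeatures selection cap (default 20).
#' @param seed integer seed (folds and oversampling).
#' @param nFolds folds of the selection CV (default 10).
#' @param useSmote oversample training folds (default TRUE).
#' @param scale `"fold"` (default) or `"global"` z-scoring.
#' @param rounds,lr boosting hyperparameters.
#' @return Character vector of selected features (selection order), with
#'   attributes `path` (full growth order) and `scores` (per-step CV
#'   accuracy/MCC).
#' @export
sfsSelect <- function(table, maxFeatures = 20, seed = 1L, nFolds = 10,
                      useSmote = TRUE, scale = c("fold", "global"),
                      rounds = 50, lr = 1) {
  scale <- match.arg(scale)
  if (maxFeatures < 1) stop("maxFeatures must be at least 1")
  xy <- .tableXY(table)
  folds <- .foldData(xy$X, xy$y, nFolds, useSmote, scale, seed)
  res <- cpp_sfs(lapply(folds, `[[`, "Xtr"),
                 lapply(folds, function(f) ifelse(f$ytr, 1L, -1L)),
                 lapply(folds, `[[`, "Xte"),
                 lapply(folds, function(f) ifelse(f$yte, 1L, -1L)),
                 as.integer(min(maxFeatures, ncol(xy$X))),
                 as.integer(rounds), lr)
  path <- colnames(xy$X)[res$order]
  best <- which.max(res$accuracy)     # earliest max: shortest best prefix
  sel <- path[seq_len(best)]
  attr(sel, "path") <- path
  attr(sel, "scores") <- data.frame(feature = path,
                                    accuracy = res$accuracy, mcc = res$mcc)
  sel
}

#' Stratified cross-validated evaluation of the boosted classifier
#'
#' Folds are stratified and fixed by `seed`. Per fold: z-scoring is fitted
#' on the training part (`scale = "global"` reproduces the all-data variant),
#' Borderline-SMOTE rebalances the training part only, an AdaBoost stump
#' ensemble is trained, and the held-out part is predicted. Confusion counts
#' are accumulated; pooled metrics come from the summed counts, and the
#' fold-wise mean and SD are reported alongside. A fold without positive
#' test members yields an undefined sensitivity for that fold and is
#' excluded from the fold-wise mean with a warning.
#'
#' @inheritParams sfsSelect
#' @param features character vector of feature names to use (e.g. from
#'   [sfsSelect()]); `NULL` uses all columns.
#' @return A [CVResult-class].
#' @export
cvEvaluate <- function(table, features = NULL, nFolds = 10, useSmote = TRUE,
                       seed = 1L, scale = c("fold", "global"), rounds = 50,
                       lr = 1) {
  scale <- match.arg(scale)
  xy <- .tableXY(table)
  X <- xy$X
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(X))
    if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  folds <- .foldData(X, xy$y, nFolds, useSmote, scale, seed)
  foldRows <- lapply(seq_along(folds), function(f) {
    fd <- folds[[f]]
    fit <- cpp_boost_fit(fd$Xtr, ifelse(fd$ytr, 1L, -1L),
                         as.integer(rounds), lr)
    pred <- cpp_boost_margin(fit, fd$Xte) > 0
    data.frame(fold = f,
               tp = sum(pred & fd$yte), fp = sum(pred & !fd$yte),
               tn = sum(!pred & !fd$yte), fn = sum(!pred & fd$yte))
  })
  folds_df <- do.call(rbind, foldRows)
  perFold <- t(apply(folds_df, 1, function(r)
    classificationMetrics(r["tp"], r["fp"], r["tn"], r["fn"])))
  if (anyNA(perFold[, "sensitivity"]))
    warning("fold(s) without positive test members excluded from the ",
            "fold-wise sensitivity mean")
  folds_df <- cbind(folds_df, perFold)
  pooled <- classificationMetrics(sum(folds_df$tp), sum(folds_df$fp),
                                  sum(folds_df$tn), sum(folds_df$fn))
  metrics <- data.frame(metric = names(pooled), pooled = unname(pooled),
                        mean = colMeans(perFold, na.rm = TRUE),
                        sd = apply(perFold, 2, sd, na.rm = TRUE),
                        row.names = NULL)
  new("CVResult", folds = folds_df, metrics = metrics,
      selectedFeatures = features %||% colnames(X),
      permP = numeric(0), nFolds = as.integer(nFolds),
      seed = as.integer(seed))
}

#' Permutation significance of cross-validated performance
#'
#' Shuffles the class labels `B` times and reruns the full evaluation
#' (fold stratification, scaling, oversampling and training) per shuffle;
#' with `refitSelection = TRUE` the forward selection is also rerun inside
#' every permutation (expensive — intended for reduced `B`). The p-value per
#' metric is `(1 + #{permuted >= observed}) / (B + 1)`, so the smallest
#' attainable p at B = 5000 is about 0.0002.
#'
#' @inheritParams cvEvaluate
#' @param observed a [CVResult-class] from [cvEvaluate()] on the true
#'   labels, evaluated with the same settings.
#' @param B permutation count (default 5000).
#' @param refitSelection rerun [sfsSelect()] per permutation.
#' @param maxFeatures selection cap when `refitSelection = TRUE`.
#' @return The `observed` CVResult with its `permP` slot filled (pooled
#'   metrics compared).
#' @export
permutationPvalue <- function(table, observed, B = 5000, seed = 1L,
                              refitSelection = FALSE, maxFeatures = 20,
                              nFolds = 10, useSmote = TRUE,
                              scale = c("fold", "global"), rounds = 50,
                              lr = 1) {
  scale <- match.arg(scale)
  if (B < 1) stop("B must be at least 1")
  obs <- setNames(observed@metrics$pooled, observed@metrics$metric)
  xy <- .tableXY(table)
  exceed <- setNames(numeric(length(obs)), names(obs))
  for (b in seq_len(B)) {
    sb <- childSeed(seed, 50000L + b)
    yPerm <- withSeed(sb, sample(xy$y))
    permTable <- table
    SummarizedExperiment::colData(permTable)$group <-
      ifelse(yPerm, "A_plus", "A_minus")
    feats <- if (refitSelection)
      sfsSelect(permTable, maxFeatures = maxFeatures, seed = sb,
                nFolds = nFolds, useSmote = useSmote, scale = scale,
                rounds = rounds, lr = lr)
    else observed@selectedFeatures
    cv <- suppressWarnings(
      cvEvaluate(permTable, feats, nFolds = nFolds, useSmote = useSmote,
                 seed = sb, scale = scale, rounds = rounds, lr = lr))
    pm <- setNames(cv@metrics$pooled, cv@metrics$metric)
    exceed <- exceed + as.numeric(!is.na(pm) & pm >= obs)
  }
  observed@permP <- (1 + exceed) / (B + 1)
  observed
}
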