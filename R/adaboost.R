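#' Fit an AdaBoost ensemble of decision stumps
#'
#' Discrete AdaBoost with depth-1 stumps, 50 rounds and learning rate 1 by
#' default — deliberately plain, fixed hyperparameters (no tuning), which
#' suits small imbalanced cohorts and keeps results reproducible. The stump
#' search and boosting loop run in C++.
#'
#' @param X numeric matrix (samples x features, named columns).
#' @param y binary labels; `TRUE`/positive level is the positive
#'   (amyloid-positive) class.
#' @param rounds boosting rounds (default 50).
#' @param lr learning rate multiplying each stump's vote (default 1).
#' @return Object of class `adaboostStumps`.
#' @export
fitAdaBoost <- function(X, y, rounds = 50, lr = 1) {
  X <- as.matrix(X)
  yy <- .toSigns(y)
  if (length(unique(yy)) < 2) stop("both classes must be present")
  fit <- cpp_boost_fit(X, yy, as.integer(rounds), lr)
  structure(list(model = fit, features = colnames(X), rounds = rounds,
                 lr = lr),
            class = "adaboostStumps")
}

.toSigns <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1L, -1L))
  if (all(y %in% c(-1, 1))) return(as.integer(y))
  f <- factor(y)
  if (nlevels(f) != 2) stop("y must be binary")
  ifelse(f == levels(f)[1], 1L, -1L)  # first level = positive class
}

#' Predict with an AdaBoost stump ensemble
#'
#' @param object an `adaboostStumps` model.
#' @param newdata samples x features matrix with the model's features.
#' @param type `"margin"` for the real-valued ensemble score (positive
#'   pushes toward the positive class) or `"class"` for the sign decision
#'   (margin 0 resolves to the negative class).
#' @param ... unused.
#' @return Numeric margins or logical class predictions.
#' @export
predict.adaboostStumps <- function(object, newdata, type = c("margin",
                                                             "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (!all(object$features %in% colnames(newdata)) &&
        ncol(newdata) != length(object$features))
      stop("newdata feature count/names do not match the model")
    if (!is.null(colnames(newdata)))
      newdata <- newdata[, object$features, drop = FALSE]
  }
  m <- cpp_boost_margin(object$model, newdata)
  if (type == "margin") m else m > 0
}

#' Exact Shapley attributions for a stump ensemble
#'
#' For an ensemble of depth-1 stumps the model margin is additive across
#' features, so Shapley values have a closed form: the attribution of
#' feature `j` for sample `x` is the summed vote of the stumps split on `j`,
#' centred on its background mean. Additivity
#' `baseValue + sum_j phi_j(x) = margin(x)` holds exactly; a feature that is
#' constant across the background and the sample receives attribution 0.
#' Positive values push the prediction toward the positive
#' (amyloid-positive) class.
#'
#' @param model an `adaboostStumps` fit.
#' @param X samples x features matrix to explain.
#' @param background reference matrix defining the expectation (default
#'   `X`).
#' @param k number of top-ranked features to report (default 5).
#' @return A [ShapSummary-class].
#' @export
shapSummary <- function(model, X, background = X, k = 5) {
  stopifnot(inherits(model, "adaboostStumps"))
  X <- as.matrix(X); background <- as.matrix(background)
  p <- length(model$features %||% seq_len(ncol(X)))
  if (ncol(X) != p)
    stop("feature count mismatch between model and X")
  featNames <- model$features %||% colnames(X) %||% paste0("f", seq_len(p))
  fit <- model$model
  phi <- matrix(0, nrow(X), p, dimnames = list(rownames(X), featNames))
  base <- 0
  for (t in seq_along(fit$feature)) {
    j <- fit$feature[t]
    vote <- function(M) fit$alpha[t] * fit$polarity[t] *
      ifelse(M[, j] > fit$threshold[t], 1, -1)
    ref <- mean(vote(background))
    phi[, j] <- phi[, j] + vote(X) - ref
    base <- base + ref
  }
  meanAbs <- colMeans(abs(phi))
  new("ShapSummary", values = phi, baseValue = base, meanAbs = meanAbs,
      topK = names(sort(meanAbs, decreasing = TRUE))[
        seq_len(min(k, p))])
}
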