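## Discriminant modelling for single-, cross- and multi-block matrices:
## LDA via the generalized eigenproblem of between- vs within-class
## scatter, with ridge regularization for the wide fused matrices, and
## stratified k-fold cross-validated accuracy.

#' Fit a linear discriminant model
#'
#' Solves the generalized eigenproblem of within-class^-1 x between-class
#' scatter by symmetric whitening. The within-class scatter is ridge
#' regularized as \code{Sw + gamma (tr(Sw)/p) I} (gamma = 1e-6), which
#' keeps the solution defined and deterministic when \code{Sw} is singular
#' (as can happen for the 44-feature fused matrix on 48-sample training
#' folds). Axes are sorted by eigenvalue with a fixed sign convention
#' (largest-magnitude loading positive); explained-variance fractions are
#' the eigenvalue shares over the discriminant subspace.
#'
#' @param X numeric matrix, samples x features (normally auto-scaled).
#' @param y class labels (factor/character), >= 2 classes, each with >= 2
#'   samples.
#' @param nComponents number of discriminants to report in score plots
#'   (<= classes - 1); the model retains the full discriminant space.
#' @param gamma ridge coefficient (default 1e-6).
#' @return object of class \code{peelLDA}: \code{axes} (p x m loadings),
#'   \code{eigenvalues}, \code{explainedVariance}, \code{scores} (n x m),
#'   \code{classes}, \code{classMeans} (class centroids in discriminant
#'   space), \code{grandMean}, \code{nComponents}.
#' @export
ldaFit <- function(X, y, nComponents = 2L, gamma = 1e-6) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  k <- nlevels(y)
  if (k < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  p <- ncol(X)
  m <- min(k - 1L, p)
  if (nComponents > k - 1L)
    stop("'nComponents' cannot exceed classes - 1")
  grand <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in levels(y)) {
    Xc <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    d <- sweep(Xc, 2L, mc)
    Sw <- Sw + crossprod(d)
    db <- mc - grand
    Sb <- Sb + nrow(Xc) * tcrossprod(db)
  }
  ridge <- gamma * (sum(diag(Sw)) / p)
  if (ridge <= 0) ridge <- gamma
  Swr <- Sw + ridge * diag(p)
  ew <- eigen(Swr, symmetric = TRUE)
  vals <- pmax(ew$values, max(ew$values) * 1e-14)
  Whalf <- ew$vectors %*% (t(ew$vectors) / sqrt(vals))
  M <- Whalf %*% Sb %*% Whalf
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  axes <- Whalf %*% em$vectors[, seq_len(m), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(m)) {
    v <- axes[, j]
    if (v[which.max(abs(v))] < 0) axes[, j] <- -v
  }
  eig <- pmax(em$values[seq_len(m)], 0)
  posSum <- sum(pmax(em$values, 0))
  colnames(axes) <- paste0("LD", seq_len(m))
  rownames(axes) <- colnames(X)
  scores <- sweep(X, 2L, grand) %*% axes
  centroids <- rowsum(scores, y) / as.vector(table(y))
  structure(list(axes = axes, eigenvalues = eig,
                 explainedVariance = if (posSum > 0) eig / posSum else eig,
                 scores = scores, classes = levels(y),
                 classMeans = centroids, grandMean = grand,
                 nComponents = as.integer(nComponents)),
            class = "peelLDA")
}

#' @export
print.peelLDA <- function(x, ...) {
  cat(sprintf("LDA model: %d classes, %d discriminants\n",
              length(x$classes), ncol(x$axes)))
  ev <- round(100 * x$explainedVariance[seq_len(min(2L, ncol(x$axes)))], 2)
  cat("explained variance LD1/LD2 (%):", paste(ev, collapse = " / "), "\n")
  invisible(x)
}

#' Project new data into a fitted discriminant space
#'
#' @param model a \code{peelLDA} fit.
#' @param X matrix with the same features (and scaling) as the training
#'   data.
#' @return scores matrix, samples x discriminants.
#' @export
ldaTransform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$axes))
    stop("feature count mismatch with the fitted model")
  sweep(X, 2L, model$grandMean) %*% model$axes
}

#' Classify samples by nearest class centroid in discriminant space
#'
#' Uses the full discriminant space (all k - 1 axes), the standard LDA
#' rule under shared within-class covariance; score plots use LD1-LD2
#' only.
#'
#' @param model a \code{peelLDA} fit.
#' @param X matrix of samples to classify (same features/scaling).
#' @return factor of predicted class labels.
#' @export
ldaPredict <- function(model, X) {
  sc <- ldaTransform(model, X)
  d2 <- vapply(seq_along(model$classes), function(ci) {
    rowSums(sweep(sc, 2L, model$classMeans[ci, ])^2)
  }, numeric(nrow(sc)))
  if (nrow(sc) == 1L) d2 <- matrix(d2, nrow = 1L)
  factor(model$classes[max.col(-d2, ties.method = "first")],
         levels = model$classes)
}

## Deterministic stratified fold assignment: within each class the sample
## order is shuffled under the seed and folds dealt round-robin.
.stratifiedFolds <- function(y, folds, seed) {
  foldId <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      foldId[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  foldId
}

#' Stratified k-fold cross-validated LDA accuracy
#'
#' Folds are stratified so every fold contains every class (class
#' shuffling is seeded and deterministic given seed and labels).
#' \code{scaleMode = "global"} auto-scales once on the full matrix before
#' splitting, replicating a scale-before-analysis design (the scaling
#' leakage this implies is documented); \code{"per_fold"} refits the
#' scaler inside each training fold.
#'
#' @param X raw samples x features matrix.
#' @param y class labels; every class must have >= \code{folds} samples.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param scaleMode \code{"global"} (default) or \code{"per_fold"}.
#' @param gamma ridge coefficient for the fold models.
#' @return object of class \code{peelCV}: \code{foldAccuracy} (one value
#'   per fold), \code{mean}, \code{sd}, plus the settings.
#' @export
cvAccuracy <- function(X, y, folds = 5L, seed = 1L,
                       scaleMode = c("global", "per_fold"), gamma = 1e-6) {
  scaleMode <- match.arg(scaleMode)
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (any(table(y) < folds))
    stop("every class needs at least 'folds' samples for stratification")
  foldId <- .stratifiedFolds(y, folds, seed)
  if (scaleMode == "global") Xs <- .autoscaleMatrix(X)
  acc <- vapply(seq_len(folds), function(f) {
    test <- foldId == f
    if (scaleMode == "global") {
      Xtr <- Xs[!test, , drop = FALSE]
      Xte <- Xs[test, , drop = FALSE]
    } else {
      sc <- .autoscaleMatrix(X[!test, , drop = FALSE])
      Xtr <- sc
      Xte <- scaleApply(sc, X[test, , drop = FALSE])
    }
    fit <- ldaFit(Xtr, y[!test], nComponents = 2L, gamma = gamma)
    mean(as.character(ldaPredict(fit, Xte)) == as.character(y[test]))
  }, 0)
  structure(list(foldAccuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 folds = folds, seed = seed, scaleMode = scaleMode),
            class = "peelCV")
}

#' @export
print.peelCV <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV accuracy: %.3f +/- %.3f\n",
              x$folds, x$mean, x$sd))
  invisible(x)
}
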