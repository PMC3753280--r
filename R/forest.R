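# Thin R wrapper around the Rcpp random forest.

#' Fit a classification random forest
#'
#' Bagged CART trees with gini splits and per-split feature subsampling.
#' Defaults follow standard random-forest practice: 500 trees, `mtry =
#' floor(sqrt(d))`, unlimited depth. All randomness is drawn from R's RNG,
#' so a prior `set.seed()` (or the `seed` argument) makes the fit
#' reproducible.
#'
#' @param x Numeric feature matrix (rows = cases).
#' @param y Factor (or coercible) of class labels.
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param min_node Minimum node size to attempt a split on.
#' @param seed Optional integer seed applied with [set.seed()].
#' @return Object of class `rf_model`.
#' @export
rf_fit <- function(x, y, ntree = 500L, mtry = NULL, min_node = 1L,
                   seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  if (nlevels(y) < 2L)
    stop("degenerate training set: only one class present")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(seed)) set.seed(seed)
  trees <- rf_train_cpp(x, as.integer(y) - 1L, nlevels(y),
                        as.integer(ntree), as.integer(mtry),
                        as.integer(min_node))
  structure(list(trees = trees, levels = levels(y), nfeat = ncol(x),
                 ntree = ntree, mtry = mtry),
            class = "rf_model")
}

#' Predict classes from a fitted forest
#'
#' Majority vote over trees; vote ties resolve to the class earliest in the
#' factor level order (deterministic).
#'
#' @param object An `rf_model`.
#' @param x Feature matrix with the training column count.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.rf_model <- function(object, x, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != object$nfeat)
    stop("feature count mismatch: model expects ", object$nfeat)
  votes <- rf_votes_cpp(object$trees, x, length(object$levels))
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.rf_model <- function(x, ...) {
  cat("Random forest:", x$ntree, "trees, mtry", x$mtry, ", classes:",
      paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}
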