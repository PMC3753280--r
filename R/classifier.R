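# Junction topology classifier: two random forests per degree, predicting
# the coaxial-stack configuration first and the family second (the family
# forest sees the stack class as an extra feature, since family definitions
# presuppose a stacking pattern).

#' Train the junction topology classifier
#'
#' @param data A `junction_dataset`, degree-homogeneous.
#' @param degree Junction degree; inferred when the dataset is homogeneous.
#' @param ntree,mtry Forest size and per-split feature draw (see [rf_fit()]).
#' @param seed Optional integer seed; a fixed seed makes the two forests and
#'   all downstream predictions reproducible.
#' @return Object of class `junction_classifier`.
#' @export
train_junction_classifier <- function(data, degree = NULL, ntree = 500L,
                                      mtry = NULL, seed = NULL) {
  degs <- unique(data$degree)
  if (is.null(degree)) {
    if (length(degs) != 1L)
      stop("dataset mixes degrees ", paste(degs, collapse = ","),
           "; pass `degree`")
    degree <- degs
  }
  data <- data[data$degree == degree, , drop = FALSE]
  if (nrow(data) < 2L) stop("need at least two records")
  X <- dataset_features(data)
  y_stack <- factor(data$stacks, levels = all_stack_labels(degree))
  y_stack <- droplevels(y_stack)
  if (anyNA(y_stack)) stop("stack label outside the admissible set")
  y_family <- factor(data$family,
                     levels = if (degree == 3L) THREEWAY_FAMILIES
                              else FOURWAY_FAMILIES)
  y_family <- droplevels(y_family)
  if (!is.null(seed)) set.seed(seed)
  stack_forest <- rf_fit(X, y_stack, ntree = ntree, mtry = mtry)
  Xfam <- cbind(X, stack_code = as.integer(y_stack))
  family_forest <- rf_fit(Xfam, y_family, ntree = ntree, mtry = mtry)
  structure(list(degree = degree, stack_forest = stack_forest,
                 family_forest = family_forest,
                 stack_levels = levels(y_stack),
                 feature_names = colnames(X)),
            class = "junction_classifier")
}

#' @export
print.junction_classifier <- function(x, ...) {
  cat(sprintf("junction classifier (%d-way): %d features, stacks {%s}\n",
              x$degree, length(x$feature_names),
              paste(x$stack_levels, collapse = ", ")))
  invisible(x)
}

classifier_features <- function(clf, j) {
  f <- if (inherits(j, "rna_junction")) {
    if (j$degree != clf$degree)
      stop("junction degree ", j$degree, " does not match classifier degree ",
           clf$degree)
    extract_features(j)
  } else if (is.numeric(j)) {
    j
  } else {
    extract_features(j)
  }
  if (!identical(names(f), clf$feature_names))
    f <- f[clf$feature_names]
  if (anyNA(f)) stop("feature vector does not match the trained feature set")
  f
}

#' Predict the topology of a junction
#'
#' Two-stage prediction: coaxial stacks first, then the family with the
#' predicted stack class appended to the features. A 3-way junction
#' predicted to have no stack is assigned family `"none"`.
#'
#' @param clf A `junction_classifier`.
#' @param j An `rna_junction` of matching degree, a single dataset record,
#'   or a named feature vector.
#' @return A `junction_topology`.
#' @export
predict_topology <- function(clf, j) {
  f <- classifier_features(clf, j)
  X <- matrix(f, nrow = 1L, dimnames = list(NULL, clf$feature_names))
  stack_pred <- as.character(predict(clf$stack_forest, X))
  code <- match(stack_pred, clf$stack_levels)
  fam_pred <- as.character(
    predict(clf$family_forest, cbind(X, stack_code = code)))
  if (clf$degree == 3L && stack_pred == "none") fam_pred <- "none"
  junction_topology(stack_pred, fam_pred, clf$degree)
}

#' Leave-one-out cross-validation of the topology classifier
#'
#' Trains on k-1 records and predicts the held-out one, for every record.
#'
#' @inheritParams train_junction_classifier
#' @return Object of class `loocv_report`: per-record predictions plus
#'   counts of correct stack and family calls.
#' @export
loocv <- function(data, degree = NULL, ntree = 500L, mtry = NULL,
                  seed = NULL) {
  degs <- unique(data$degree)
  if (is.null(degree)) {
    if (length(degs) != 1L) stop("dataset mixes degrees; pass `degree`")
    degree <- degs
  }
  data <- data[data$degree == degree, , drop = FALSE]
  k <- nrow(data)
  if (k < 3L) stop("LOOCV needs at least three records")
  if (is.null(seed)) seed <- 1L
  pred_stack <- pred_family <- character(k)
  for (q in seq_len(k)) {
    clf <- train_junction_classifier(data[-q, , drop = FALSE], degree,
                                     ntree = ntree, mtry = mtry,
                                     seed = seed + q)
    top <- predict_topology(clf, data[q, , drop = FALSE])
    pred_stack[q] <- top$stacks
    pred_family[q] <- top$family
  }
  per <- data.frame(id = data$id,
                    stacks = data$stacks, pred_stacks = pred_stack,
                    family = data$family, pred_family = pred_family,
                    stringsAsFactors = FALSE)
  structure(list(n = k, degree = degree, predictions = per,
                 stack_correct = sum(per$stacks == per$pred_stacks),
                 family_correct = sum(per$family == per$pred_family)),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("LOOCV over %d %d-way junctions: stacks %d/%d, family %d/%d\n",
              x$n, x$degree, x$stack_correct, x$n, x$family_correct, x$n))
  invisible(x)
}

#' Save / load a trained classifier as JSON
#'
#' Tree tables are serialized as plain JSON arrays, keeping model files
#' text-only and portable.
#'
#' @param clf A `junction_classifier`.
#' @param path File path.
#' @export
write_classifier <- function(clf, path) {
  ser_forest <- function(fz) list(levels = fz$levels, nfeat = fz$nfeat,
                                  ntree = fz$ntree, mtry = fz$mtry,
                                  trees = fz$trees)
  obj <- list(degree = clf$degree, stack_levels = clf$stack_levels,
              feature_names = clf$feature_names,
              stack_forest = ser_forest(clf$stack_forest),
              family_forest = ser_forest(clf$family_forest))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_forest <- function(fz) {
    trees <- lapply(seq_len(nrow_or_len(fz$trees)), function(t) {
      tr <- if (is.data.frame(fz$trees)) fz$trees[t, ] else fz$trees[[t]]
      list(feature = as.integer(tr$feature[[1]]),
           threshold = as.numeric(tr$threshold[[1]]),
           left = as.integer(tr$left[[1]]), right = as.integer(tr$right[[1]]),
           pred = as.integer(tr$pred[[1]]))
    })
    structure(list(trees = trees, levels = fz$levels, nfeat = fz$nfeat,
                   ntree = fz$ntree, mtry = fz$mtry), class = "rf_model")
  }
  structure(list(degree = obj$degree,
                 stack_forest = de_forest(obj$stack_forest),
                 family_forest = de_forest(obj$family_forest),
                 stack_levels = obj$stack_levels,
                 feature_names = obj$feature_names),
            class = "junction_classifier")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
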