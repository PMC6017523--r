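#' Classifier factories for cross-validation
#'
#' Each factory returns a classifier specification: a function
#' `f(features, labels, seed)` returning a fitted object that supports
#' `predict(object, newdata)`, plus a printable label. These plug into
#' [cross_validate()], [grid_search_architecture()],
#' [rank_property_indices()] and [search_index_combinations()].
#'
#' `majority_classifier()` (always predicts the most frequent training
#' class) is a degenerate reference used for null checks.
#'
#' @param cfg A [deep_net_config()] (its `seed` is overridden per fold).
#' @param k Neighbourhood size for k-NN.
#' @param params Baseline parameters, see [train_baseline()].
#' @param size Hidden-layer size for the MLP baseline.
#' @return A list of class `seqrbm_classifier` with elements `fit` and
#'   `label`.
#' @name classifiers
NULL

new_classifier <- function(fit, label) {
  structure(list(fit = fit, label = label), class = "seqrbm_classifier")
}

#' @rdname classifiers
#' @export
rbm_classifier <- function(cfg = deep_net_config()) {
  new_classifier(
    fit = function(X, y, seed) {
      cfg$seed <- as.integer(seed)
      stack <- pretrain_stack(X, cfg)
      fine_tune(stack, X, y, cfg)
    },
    label = sprintf("rbm[%s]", paste(cfg$hidden_layers, collapse = ","))
  )
}

#' @rdname classifiers
#' @export
knn_classifier <- function(k = 1L) {
  new_classifier(
    fit = function(X, y, seed) train_baseline(X, y, "knn", list(k = k), seed = seed),
    label = sprintf("knn[k=%d]", k)
  )
}

#' @rdname classifiers
#' @export
dt_classifier <- function(params = list()) {
  new_classifier(
    fit = function(X, y, seed) train_baseline(X, y, "dt", params, seed = seed),
    label = "dt"
  )
}

#' @rdname classifiers
#' @export
mlp_classifier <- function(size = 10L, params = list()) {
  new_classifier(
    fit = function(X, y, seed) {
      train_baseline(X, y, "mlp", c(list(size = size), params), seed = seed)
    },
    label = sprintf("mlp[size=%d]", size)
  )
}

#' @rdname classifiers
#' @export
svm_classifier <- function(params = list()) {
  new_classifier(
    fit = function(X, y, seed) train_baseline(X, y, "svm-rbf", params, seed = seed),
    label = "svm-rbf"
  )
}

#' @rdname classifiers
#' @export
majority_classifier <- function() {
  new_classifier(
    fit = function(X, y, seed) {
      maj <- names(which.max(table(y)))
      structure(list(label = maj), class = "seqrbm_majority")
    },
    label = "majority"
  )
}

#' @export
predict.seqrbm_majority <- function(object, newdata, ...) {
  rep(object$label, nrow(as_numeric_matrix(newdata)))
}

#' Stratified k-fold assignment
#'
#' Splits indices into `k` folds preserving class proportions: within each
#' class, a seeded shuffle followed by round-robin assignment, so per-class
#' fold sizes differ by at most one.
#'
#' @param labels Class label vector.
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return An integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2) abort("`k` must be at least 2")
  sizes <- table(labels)
  if (any(sizes < k)) {
    abort(sprintf(
      "class '%s' has %d members, fewer than k = %d folds",
      names(sizes)[which(sizes < k)[1]], min(sizes), k
    ))
  }
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of a feature/classifier pipeline
#'
#' Per fold, min-max normalization is fitted on the training part and
#' applied (with clipping) to the held-out part — `normalize_scope =
#' "dataset"` instead fits it once on the whole table, the behaviour of
#' toolbox-level preprocessing. The classifier is refitted on each training
#' part with a per-fold seed derived from `seed`.
#'
#' @param features A feature table with labels.
#' @param classifier A classifier specification, e.g. [rbm_classifier()].
#' @param k Number of folds.
#' @param seed Master seed for fold assignment and per-fold training.
#' @param normalize_scope `"fold"` (leakage-free, default), `"dataset"`, or
#'   `"none"`.
#' @return An object of class `seqrbm_cv`: fold assignment, per-fold and
#'   pooled confusion matrices, per-fold metrics, their means, and per-class
#'   recall from the pooled matrix. See [tidy.seqrbm_cv()] /
#'   [glance.seqrbm_cv()].
#' @export
cross_validate <- function(features, classifier, k = 10L, seed = 1L,
                           normalize_scope = c("fold", "dataset", "none")) {
  normalize_scope <- match.arg(normalize_scope)
  stopifnot(inherits(classifier, "seqrbm_classifier"))
  y <- feature_labels(features)
  classes <- sort(unique(y))
  folds <- stratified_kfold(y, k, seed)
  if (normalize_scope == "dataset") features <- minmax_normalize(features)
  fold_result <- lapply(seq_len(k), function(f) {
    tr <- features[folds != f, , drop = FALSE]
    te <- features[folds == f, , drop = FALSE]
    if (normalize_scope == "fold") {
      tr <- minmax_normalize(tr)
      te <- minmax_normalize(te, stats = minmax_stats(tr))
    }
    model <- classifier$fit(tr, feature_labels(tr), seed = seed * 1000L + f)
    pred <- as.character(predict(model, te))
    confusion_matrix(feature_labels(te), pred, classes = classes)
  })
  pooled <- Reduce(`+`, lapply(fold_result, unclass))
  pooled <- structure(pooled, class = c("seqrbm_confusion", "matrix", "array"))
  fold_metrics <- tibble(
    fold = seq_len(k),
    accuracy = vapply(fold_result, accuracy, numeric(1)),
    mcc = vapply(fold_result, mcc, numeric(1)),
    ber = vapply(fold_result, ber, numeric(1))
  )
  structure(
    list(
      folds = folds, fold_confusions = fold_result, pooled_confusion = pooled,
      fold_metrics = fold_metrics,
      mean_accuracy = mean(fold_metrics$accuracy),
      mean_mcc = mean(fold_metrics$mcc),
      mean_ber = mean(fold_metrics$ber),
      per_class_recall = per_class_recall(pooled),
      classes = classes, k = k, seed = seed,
      classifier = classifier$label, normalize_scope = normalize_scope
    ),
    class = "seqrbm_cv"
  )
}

#' @export
print.seqrbm_cv <- function(x, ...) {
  cat(sprintf(
    "<seqrbm_cv: %s, %d-fold (seed %d)>\n  accuracy %.4f  MCC %.4f  BER %.4f\n",
    x$classifier, x$k, x$seed, x$mean_accuracy, x$mean_mcc, x$mean_ber
  ))
  invisible(x)
}
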