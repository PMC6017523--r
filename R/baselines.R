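# Thin wrappers over established learners, sharing one predict contract with
# the deep model. The SVM grid follows the conventional RBF search ranges
# C in [1, 16] and gamma in [2^-10, 2^5].

new_baseline <- function(kind, fit, classes, extra = list()) {
  structure(c(list(kind = kind, fit = fit, classes = classes), extra),
    class = "seqrbm_baseline"
  )
}

#' Default RBF-SVM hyperparameter grid
#'
#' Powers of two spanning `C` in `[1, 16]` and `gamma` in `[2^-10, 2^5]`.
#'
#' @return A list with numeric vectors `cost` and `gamma`.
#' @export
svm_default_grid <- function() {
  list(cost = 2^(0:4), gamma = 2^seq(-10, 5, by = 1))
}

#' Train a baseline classifier
#'
#' Fits one of the conventional reference classifiers: k-nearest neighbour
#' (`class::knn`), a classification tree (`rpart`), a single-hidden-layer
#' perceptron trained by backpropagation (`nnet`) or an RBF-kernel SVM
#' (`e1071::svm`). When an SVM parameter has several candidate values, the
#' combination with the best stratified 3-fold CV accuracy on the training
#' data is selected.
#'
#' @param X A feature table or numeric matrix.
#' @param y Labels; defaults to the feature-table labels.
#' @param kind One of `"knn"`, `"dt"`, `"mlp"`, `"svm-rbf"`.
#' @param params Named list of parameters: `k` (knn, default 1); `size`,
#'   `maxit`, `decay` (mlp); `cost`, `gamma` (svm, scalars or candidate
#'   vectors, default [svm_default_grid()]); rpart control parameters (dt).
#' @param seed Seed for any internal randomness (MLP init, SVM grid folds).
#' @return A fitted model of class `seqrbm_baseline`.
#' @export
train_baseline <- function(X, y = NULL, kind = c("knn", "dt", "mlp", "svm-rbf"),
                           params = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(y)) {
    if (!inherits(X, "seqrbm_features")) abort("`y` is required when `X` is a bare matrix")
    y <- feature_labels(X)
  }
  Xm <- as_numeric_matrix(X)
  y <- factor(as.character(y))
  classes <- levels(y)
  switch(kind,
    knn = new_baseline("knn",
      fit = list(X = Xm, y = y, k = params$k %||% 1L), classes = classes
    ),
    dt = {
      d <- data.frame(.y = y, Xm, check.names = TRUE)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class")
      new_baseline("dt", fit = fit, classes = classes)
    },
    mlp = {
      fit <- with_local_seed(seed, nnet::nnet(
        x = Xm, y = stats::model.matrix(~ y - 1),
        size = params$size %||% 10L, softmax = TRUE,
        maxit = params$maxit %||% 200L, decay = params$decay %||% 1e-4,
        MaxNWts = 1e6, trace = FALSE
      ))
      new_baseline("mlp", fit = fit, classes = classes)
    },
    `svm-rbf` = {
      grid <- svm_default_grid()
      cost <- params$cost %||% grid$cost
      gamma <- params$gamma %||% grid$gamma
      pick <- if (length(cost) > 1 || length(gamma) > 1) {
        tune_svm_grid(Xm, y, cost, gamma, seed)
      } else {
        list(cost = cost, gamma = gamma)
      }
      fit <- e1071::svm(Xm, y, kernel = "radial", cost = pick$cost, gamma = pick$gamma)
      new_baseline("svm-rbf", fit = fit, classes = classes,
        extra = list(cost = pick$cost, gamma = pick$gamma)
      )
    }
  )
}

tune_svm_grid <- function(Xm, y, cost, gamma, seed) {
  folds <- stratified_kfold(y, k = min(3L, min(table(y))), seed = seed)
  combos <- expand.grid(cost = cost, gamma = gamma)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    mean(vapply(sort(unique(folds)), function(f) {
      fit <- e1071::svm(Xm[folds != f, , drop = FALSE], y[folds != f],
        kernel = "radial", cost = combos$cost[i], gamma = combos$gamma[i]
      )
      mean(predict(fit, Xm[folds == f, , drop = FALSE]) == y[folds == f])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)
  list(cost = combos$cost[best], gamma = combos$gamma[best])
}

#' @export
predict.seqrbm_baseline <- function(object, newdata, ...) {
  Xm <- as_numeric_matrix(newdata)
  out <- switch(object$kind,
    knn = class::knn(object$fit$X, Xm, object$fit$y, k = object$fit$k),
    dt = predict(object$fit, data.frame(Xm, check.names = TRUE), type = "class"),
    mlp = {
      p <- predict(object$fit, Xm)
      object$classes[max.col(p, ties.method = "first")]
    },
    `svm-rbf` = predict(object$fit, Xm)
  )
  as.character(out)
}
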