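test_that("stratified folds preserve class proportions to within one", {
  f <- stratified_kfold(c("a", "a", "a", "a", "b", "b"), k = 2, seed = 1)
  expect_equal(as.integer(table(f)), c(3L, 3L))
  for (fold in 1:2) {
    expect_equal(sum(f == fold & c(rep(TRUE, 4), FALSE, FALSE)), 2)
  }

  # a 36-member class splits into folds of 3 or 4 over k = 10
  labels <- rep(c("Cs", "big"), times = c(36, 100))
  f10 <- stratified_kfold(labels, k = 10, seed = 3)
  cs_sizes <- table(f10[labels == "Cs"])
  expect_true(all(cs_sizes %in% c(3, 4)))
  expect_length(cs_sizes, 10)

  # general property: per-class fold sizes differ by at most 1
  withr::with_seed(5, {
    lab <- sample(letters[1:4], 200, replace = TRUE, prob = c(.1, .2, .3, .4))
    fx <- stratified_kfold(lab, k = 5, seed = 9)
    for (cl in letters[1:4]) {
      sz <- table(factor(fx[lab == cl], levels = 1:5))
      expect_lte(diff(range(sz)), 1)
    }
    expect_setequal(unique(fx), 1:5)
  })
})

test_that("folds are deterministic in the seed and reject tiny classes", {
  lab <- rep(letters[1:3], times = c(12, 15, 20))
  expect_identical(
    stratified_kfold(lab, 4, seed = 7),
    stratified_kfold(lab, 4, seed = 7)
  )
  expect_false(identical(
    stratified_kfold(lab, 4, seed = 7),
    stratified_kfold(lab, 4, seed = 8)
  ))
  expect_error(stratified_kfold(c("a", "a", "b"), k = 2), "'b'")
})

test_that("a majority classifier recovers the majority proportion", {
  spec <- synthetic_spec(
    class_sizes = c(a = 30, b = 18, c = 12), alignment_length = 30,
    effect = 0, seed = 2
  )
  f <- encode_sequences(generate_sequences(spec), generate_property_index(1))
  cv <- cross_validate(f, majority_classifier(), k = 6, seed = 1)
  expect_equal(accuracy(cv$pooled_confusion), 0.5)
  expect_equal(cv$mean_accuracy, 0.5, tolerance = 1e-12)
})

test_that("cross-validation is reproducible and conserves counts", {
  spec <- synthetic_spec(
    class_sizes = c(a = 20, b = 20, c = 20), alignment_length = 40,
    effect = 3, seed = 4
  )
  seqs <- generate_sequences(spec)
  idx <- generate_property_index(7, discriminative_for = c("A", "R", "N"))
  f <- encode_sequences(seqs, idx)
  cv1 <- cross_validate(f, knn_classifier(1), k = 5, seed = 11)
  cv2 <- cross_validate(f, knn_classifier(1), k = 5, seed = 11)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
  expect_identical(unclass(cv1$pooled_confusion), unclass(cv2$pooled_confusion))

  # pooled confusion equals the sum over folds; folds partition the records
  expect_equal(
    unclass(cv1$pooled_confusion),
    Reduce(`+`, lapply(cv1$fold_confusions, unclass))
  )
  expect_equal(sum(cv1$pooled_confusion), nrow(f))
  expect_equal(sort(unique(cv1$folds)), 1:5)

  # tidy/glance expose fold metrics and the summary
  expect_equal(nrow(tidy(cv1)), 5)
  expect_equal(glance(cv1)$accuracy, cv1$mean_accuracy)
})

test_that("a null-effect dataset yields near-zero pooled MCC", {
  spec <- synthetic_spec(scale = 0.6, effect = 0, seed = 6)
  seqs <- generate_sequences(spec)
  idx <- generate_property_index(7,
    discriminative_for = seqrbm:::class_anchors(names(spec$class_sizes))
  )
  f <- encode_sequences(seqs, idx)
  cv <- cross_validate(f, knn_classifier(1), k = 10, seed = 2)
  expect_lt(abs(mcc(cv$pooled_confusion)), 0.1)
})

test_that("fold-scoped normalization keeps held-out features in [0, 1]", {
  spec <- synthetic_spec(class_sizes = c(a = 10, b = 10), alignment_length = 12, effect = 1, seed = 8)
  f <- encode_sequences(generate_sequences(spec), generate_property_index(3))
  # a classifier spy that checks the test matrix it receives
  spy <- seqrbm:::new_classifier(
    fit = function(X, y, seed) {
      expect_true(all(feature_matrix(X) >= 0 & feature_matrix(X) <= 1))
      structure(list(label = names(which.max(table(y)))), class = "seqrbm_majority")
    },
    label = "spy"
  )
  cv <- cross_validate(f, spy, k = 2, seed = 1, normalize_scope = "fold")
  expect_s3_class(cv, "seqrbm_cv")
})
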