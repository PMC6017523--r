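test_that("confusion matrix counts true-by-predicted cases", {
  C <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(unclass(C), matrix(c(1L, 0L, 1L, 1L), 2,
    dimnames = list(truth = c("a", "b"), pred = c("a", "b"))
  ))
  expect_equal(sum(C), 3)
  # perfect prediction is diagonal
  Cd <- confusion_matrix(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(sum(Cd) - sum(diag(Cd)), 0)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("a", "c", classes = c("a", "b")), "outside")
})

test_that("accuracy, BER, MCC and recall reproduce hand-computed cases", {
  C <- structure(matrix(c(3L, 2L, 1L, 4L), 2, dimnames = list(truth = c("a", "b"), pred = c("a", "b"))),
    class = c("seqrbm_confusion", "matrix", "array")
  )
  expect_equal(accuracy(C), 0.7)
  expect_equal(ber(C), (1 / 4 + 2 / 6) / 2)
  # binary MCC closed form
  tp <- 3; fn <- 1; fp <- 2; tn <- 4
  expect_equal(
    mcc(C),
    (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  )
  expect_equal(unname(per_class_recall(C)), c(3 / 4, 4 / 6))

  Cdiag <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(accuracy(Cdiag), 1)
  expect_equal(ber(Cdiag), 0)
  expect_equal(mcc(Cdiag), 1)
  expect_equal(unname(per_class_recall(Cdiag)), rep(1, 3))

  # extreme misclassification and single-class prediction
  Cx <- structure(matrix(c(0L, 5L, 4L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b"))),
    class = c("seqrbm_confusion", "matrix", "array")
  )
  expect_equal(ber(Cx), 1)
  Cone <- confusion_matrix(c("a", "a", "b", "c"), rep("a", 4))
  expect_equal(mcc(Cone), 0)
})

test_that("matrix metrics agree with direct label-vector computation", {
  withr::with_seed(7, {
    for (rep in 1:1000) {
      G <- sample(2:7, 1)
      C <- random_confusion(G)
      lab <- confusion_to_labels(C)
      expect_equal(accuracy(C), mean(lab$truth == lab$pred), tolerance = 1e-12)
      C2 <- confusion_matrix(lab$truth, lab$pred, classes = rownames(C))
      expect_equal(unclass(C2), unclass(C))
      expect_equal(ber(C), ber(C2), tolerance = 1e-12)
      expect_equal(mcc(C), mcc(C2), tolerance = 1e-12)
      if (G == 2) {
        tp <- C[1, 1]; fn <- C[1, 2]; fp <- C[2, 1]; tn <- C[2, 2]
        den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
        bin <- if (den == 0) 0 else (tp * tn - fp * fn) / den
        expect_equal(mcc(C), bin, tolerance = 1e-12)
      }
    }
  })
})

test_that("BER is exactly one minus mean per-class recall", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      C <- random_confusion(sample(2:7, 1))
      expect_identical(ber(C), 1 - mean(per_class_recall(C)))
    }
  })
})

test_that("MCC is invariant under simultaneous class permutation", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      G <- sample(2:7, 1)
      C <- random_confusion(G)
      p <- sample(G)
      Cp <- structure(unclass(C)[p, p], class = class(C))
      expect_equal(mcc(Cp), mcc(C), tolerance = 1e-12)
    }
  })
})

test_that("degenerate inputs raise the documented errors", {
  C0 <- structure(matrix(c(0L, 3L, 0L, 2L), 2, dimnames = list(c("a", "b"), c("a", "b"))),
    class = c("seqrbm_confusion", "matrix", "array")
  )
  expect_error(ber(C0), "zero row sum")
  expect_error(per_class_recall(C0), "zero row sum")
})

test_that("confusion matrices tidy into truth/pred/n triples", {
  C <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  td <- tidy(C)
  expect_equal(sum(td$n), 3)
  expect_equal(td$n[td$truth == "a" & td$pred == "b"], 1)
})
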