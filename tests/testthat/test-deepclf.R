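# Small separable fixtures for network checks.
three_cluster_data <- function(n_per = 30, d = 10, sep = 6, seed = 5) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(stats::rnorm(n_per * d), n_per),
      matrix(stats::rnorm(n_per * d, mean = sep), n_per),
      matrix(stats::rnorm(n_per * d, mean = -sep), n_per)
    )
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = rep(c("a", "b", "c"), each = n_per))
  })
}

quick_cfg <- function(...) {
  deep_net_config(
    hidden_layers = c(16, 16), pretrain_epochs = 3, finetune_epochs = 30,
    seed = 1, ...
  )
}

test_that("pretrained stacks chain dimensions input -> hidden layers", {
  dat <- three_cluster_data(n_per = 20, d = 12)
  cfg <- deep_net_config(hidden_layers = c(8, 5, 4), pretrain_epochs = 2, finetune_epochs = 5)
  st <- pretrain_stack(dat$X, cfg)
  expect_equal(dim(st$layers[[1]]$W), c(12, 8))
  expect_equal(dim(st$layers[[2]]$W), c(8, 5))
  expect_equal(dim(st$layers[[3]]$W), c(5, 4))
  expect_true(st$layers[[1]]$gaussian)
  expect_false(st$layers[[2]]$gaussian)
  # h hidden layers -> h + 1 weight matrices, output width = G
  model <- fine_tune(st, dat$X, dat$y, cfg)
  expect_length(model$weights, 4)
  expect_equal(ncol(model$weights[[4]]), 3)
})

test_that("training is bit-reproducible under a fixed seed", {
  dat <- three_cluster_data()
  cfg <- quick_cfg()
  s1 <- pretrain_stack(dat$X, cfg)
  s2 <- pretrain_stack(dat$X, cfg)
  expect_identical(s1$layers[[1]]$W, s2$layers[[1]]$W)
  expect_identical(s1$layers[[2]]$W, s2$layers[[2]]$W)
  m1 <- fine_tune(s1, dat$X, dat$y, cfg)
  m2 <- fine_tune(s2, dat$X, dat$y, cfg)
  expect_identical(m1$final_loss, m2$final_loss)
  expect_identical(predict(m1, dat$X), predict(m2, dat$X))
})

test_that("reconstruction error trends downward during pretraining", {
  # two Gaussian clusters; CD-1 is stochastic, so the 5-epoch moving average
  # is required to be non-increasing up to a small sampling jitter while the
  # error at least halves overall
  X <- withr::with_seed(2, rbind(
    matrix(stats::rnorm(50 * 8), 50),
    matrix(stats::rnorm(50 * 8, mean = 3), 50)
  ))
  cfg <- deep_net_config(
    hidden_layers = 12, pretrain_epochs = 50, finetune_epochs = 1,
    pretrain_lr_gaussian = 0.02, seed = 4
  )
  st <- pretrain_stack(X, cfg)
  tr <- st$layers[[1]]$recon_error
  ma <- stats::filter(tr, rep(1 / 5, 5), sides = 1)[5:50]
  expect_true(all(diff(ma) <= 0.05 * ma[1]))
  expect_lt(ma[length(ma)], 0.6 * ma[1])
})

test_that("fine-tuned models fit separable data and beat the majority rate", {
  dat <- three_cluster_data(n_per = 100, d = 10, sep = 6)
  cfg <- quick_cfg()
  model <- train_deep_classifier(dat$X, dat$y, cfg)
  expect_gte(model$train_accuracy, 0.95)
  maj <- max(table(dat$y)) / length(dat$y)
  expect_gte(model$train_accuracy, maj)
  # recorded training accuracy is reproduced by predict()
  expect_equal(mean(predict(model, dat$X) == dat$y), model$train_accuracy)
})

test_that("probability rows sum to one and ties resolve to the lowest ordinal", {
  dat <- three_cluster_data(n_per = 15)
  model <- train_deep_classifier(dat$X, dat$y, quick_cfg())
  p <- predict(model, dat$X, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)

  # zero the output layer: all logits tie, lowest class ordinal must win
  tied <- model
  tied$weights[[length(tied$weights)]][] <- 0
  tied$biases[[length(tied$biases)]][] <- 0
  expect_equal(unique(predict(tied, dat$X)), model$classes[1])
})

test_that("usage errors: single class, width mismatch", {
  dat <- three_cluster_data(n_per = 10)
  cfg <- quick_cfg()
  st <- pretrain_stack(dat$X, cfg)
  expect_error(fine_tune(st, dat$X, rep("a", nrow(dat$X)), cfg), "two classes")
  model <- fine_tune(st, dat$X, dat$y, cfg)
  expect_error(predict(model, dat$X[, 1:3]), "width")
  expect_error(pretrain_stack(cbind(c(1, NA, 3)), cfg), "finite")
})

test_that("serialized models predict identically after reload", {
  dat <- three_cluster_data(n_per = 12)
  model <- train_deep_classifier(dat$X, dat$y, quick_cfg())
  f <- withr::local_tempfile(fileext = ".json")
  write_deep_model(model, f)
  back <- read_deep_model(f)
  expect_equal(predict(back, dat$X, type = "prob"), predict(model, dat$X, type = "prob"),
    tolerance = 1e-12
  )
  expect_identical(predict(back, dat$X), predict(model, dat$X))
})

test_that("baseline classifiers honour their contracts", {
  dat <- three_cluster_data(n_per = 25, d = 6)
  # 1-NN memorizes its training set
  knn <- train_baseline(dat$X, dat$y, "knn", list(k = 1))
  expect_equal(mean(predict(knn, dat$X) == dat$y), 1.0)
  # a threshold-separable toy is solved exactly by a decision tree
  Xt <- cbind(x = c(1:10, 101:110))
  yt <- rep(c("lo", "hi"), each = 10)
  dt <- train_baseline(Xt, yt, "dt")
  expect_equal(mean(predict(dt, Xt) == yt), 1.0)
  # MLP predicts labels within the class set
  mlp <- train_baseline(dat$X, dat$y, "mlp", list(size = 4, maxit = 50))
  expect_true(all(predict(mlp, dat$X) %in% dat$y))
  # the default SVM grid spans C in [1,16], gamma in [2^-10, 2^5]
  g <- svm_default_grid()
  expect_equal(range(g$cost), c(1, 16))
  expect_equal(range(g$gamma), c(2^-10, 2^5))
  svm <- train_baseline(dat$X, dat$y, "svm-rbf", list(cost = 1, gamma = 0.1))
  expect_gte(mean(predict(svm, dat$X) == dat$y), 0.9)
})
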