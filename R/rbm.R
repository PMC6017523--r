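# Stacked Gaussian-Bernoulli restricted Boltzmann machine:
# layer-wise contrastive-divergence pretraining, then supervised softmax
# fine-tuning by backpropagation with Nesterov-accelerated gradient descent.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Configuration of the stacked-RBM classifier
#'
#' Architecture and training hyperparameters for [pretrain_stack()] /
#' [fine_tune()]. The defaults are conventional settings for
#' Gaussian-Bernoulli deep belief networks: CD-1; pretraining at a small
#' learning rate for the Gaussian visible layer (0.001) and a larger one for
#' the Bernoulli layers (0.01); fine-tuning with Nesterov momentum 0.9,
#' learning rate 0.1 halved every 50 epochs, batch size 32 and weight decay
#' 1e-4.
#'
#' @param hidden_layers Integer vector of hidden-layer widths (one RBM per
#'   entry); default `c(500, 500)`.
#' @param cd_steps Contrastive-divergence Gibbs steps (CD-k).
#' @param pretrain_epochs,finetune_epochs Training epochs per phase.
#' @param pretrain_lr_gaussian,pretrain_lr_bernoulli Pretraining learning
#'   rates for the first (Gaussian-visible) and subsequent RBMs.
#' @param finetune_lr Initial fine-tuning learning rate.
#' @param lr_decay,lr_decay_every Step decay factor for the fine-tuning rate
#'   and its epoch period.
#' @param momentum Nesterov momentum coefficient in `[0, 1)`.
#' @param batch_size Mini-batch size.
#' @param weight_decay L2 penalty on weights.
#' @param seed Integer seed; all randomness in training flows from it.
#' @return A list of class `seqrbm_net_config`.
#' @export
deep_net_config <- function(hidden_layers = c(500, 500), cd_steps = 1,
                            pretrain_epochs = 100, finetune_epochs = 200,
                            pretrain_lr_gaussian = 0.001, pretrain_lr_bernoulli = 0.01,
                            finetune_lr = 0.1, lr_decay = 0.5, lr_decay_every = 50,
                            momentum = 0.9, batch_size = 32, weight_decay = 1e-4,
                            seed = 1L) {
  stopifnot(
    all(hidden_layers >= 1), cd_steps >= 1,
    pretrain_epochs >= 1, finetune_epochs >= 1,
    pretrain_lr_gaussian > 0, pretrain_lr_bernoulli > 0, finetune_lr > 0,
    momentum >= 0, momentum < 1, batch_size >= 1, weight_decay >= 0
  )
  structure(
    list(
      hidden_layers = as.integer(hidden_layers), cd_steps = as.integer(cd_steps),
      pretrain_epochs = as.integer(pretrain_epochs),
      finetune_epochs = as.integer(finetune_epochs),
      pretrain_lr_gaussian = pretrain_lr_gaussian,
      pretrain_lr_bernoulli = pretrain_lr_bernoulli,
      finetune_lr = finetune_lr, lr_decay = lr_decay,
      lr_decay_every = as.integer(lr_decay_every),
      momentum = momentum, batch_size = as.integer(batch_size),
      weight_decay = weight_decay, seed = as.integer(seed)
    ),
    class = "seqrbm_net_config"
  )
}

as_numeric_matrix <- function(X) {
  if (inherits(X, "seqrbm_features")) feature_matrix(X) else as.matrix(X)
}

# Train one RBM by CD-k. `gaussian` selects a Gaussian (linear, unit
# variance) visible layer; hidden units are sampled on the positive phase,
# probabilities are used in the negative phase and when propagating upward.
train_rbm <- function(V, n_hidden, lr, cfg, gaussian) {
  n <- nrow(V)
  W <- matrix(stats::rnorm(ncol(V) * n_hidden, sd = 0.01), ncol(V), n_hidden)
  b <- rep(0, ncol(V))
  cc <- rep(0, n_hidden)
  recon <- numeric(cfg$pretrain_epochs)
  for (epoch in seq_len(cfg$pretrain_epochs)) {
    ord <- sample.int(n)
    err <- 0
    nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      v0 <- V[idx, , drop = FALSE]
      m <- nrow(v0)
      hp <- sigmoid(sweep(v0 %*% W, 2, cc, "+"))
      hs0 <- (matrix(stats::runif(m * n_hidden), m) < hp) * 1
      hs <- hs0
      for (k in seq_len(cfg$cd_steps)) {
        vk <- sweep(hs %*% t(W), 2, b, "+")
        if (!gaussian) vk <- sigmoid(vk)
        hpk <- sigmoid(sweep(vk %*% W, 2, cc, "+"))
        hs <- if (k < cfg$cd_steps) (matrix(stats::runif(m * n_hidden), m) < hpk) * 1 else hpk
      }
      dW <- (crossprod(v0, hs0) - crossprod(vk, hpk)) / m - cfg$weight_decay * W
      W <- W + lr * dW
      b <- b + lr * colMeans(v0 - vk)
      cc <- cc + lr * colMeans(hs0 - hpk)
      err <- err + mean((v0 - vk)^2)
      nb <- nb + 1
    }
    recon[epoch] <- err / nb
    if (!is.finite(recon[epoch])) {
      abort("RBM pretraining diverged (non-finite reconstruction error); try a smaller learning rate",
        class = "seqrbm_training_error"
      )
    }
  }
  list(W = W, b = b, c = cc, recon_error = recon, gaussian = gaussian)
}

#' Layer-wise contrastive-divergence pretraining
#'
#' Trains a stack of RBMs without supervision. Inputs are z-scored
#' internally (the Gaussian visible layer assumes unit-variance inputs) and
#' the first RBM is Gaussian-Bernoulli; each subsequent RBM is
#' Bernoulli-Bernoulli, trained on the previous layer's hidden activation
#' probabilities.
#'
#' @param X A feature table or numeric matrix (rows = samples).
#' @param cfg A [deep_net_config()].
#' @return A list of class `seqrbm_stack`: per-layer `W`, visible/hidden
#'   biases, per-epoch reconstruction-error traces, and the input
#'   standardization statistics.
#' @export
pretrain_stack <- function(X, cfg = deep_net_config()) {
  X <- as_numeric_matrix(X)
  if (!all(is.finite(X))) abort("non-finite values in the input matrix")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  layers <- with_local_seed(cfg$seed, {
    out <- vector("list", length(cfg$hidden_layers))
    V <- Z
    for (i in seq_along(cfg$hidden_layers)) {
      gaussian <- i == 1L
      lr <- if (gaussian) cfg$pretrain_lr_gaussian else cfg$pretrain_lr_bernoulli
      out[[i]] <- train_rbm(V, cfg$hidden_layers[i], lr, cfg, gaussian)
      V <- sigmoid(sweep(V %*% out[[i]]$W, 2, out[[i]]$c, "+"))
    }
    out
  })
  structure(
    list(layers = layers, standardization = list(mean = mu, sd = sd), config = cfg),
    class = "seqrbm_stack"
  )
}

forward_hidden <- function(weights, biases, Z) {
  a <- Z
  acts <- vector("list", length(weights))
  for (i in seq_along(weights)) {
    a <- sigmoid(sweep(a %*% weights[[i]], 2, biases[[i]], "+"))
    acts[[i]] <- a
  }
  acts
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Supervised fine-tuning of a pretrained stack
#'
#' Appends a softmax output layer (one unit per class) to the pretrained
#' hidden layers and minimizes the cross-entropy by mini-batch gradient
#' descent with Nesterov momentum and step-decayed learning rate — standard
#' error backpropagation through the unrolled deep belief network.
#'
#' @param stack A [pretrain_stack()] result.
#' @param X The training features (same matrix the stack was pretrained on,
#'   or any matrix of matching width).
#' @param y Class labels, at least two distinct values.
#' @param cfg A [deep_net_config()]; defaults to the stack's own.
#' @return A fitted model of class `seqrbm_deepmodel` with per-layer weights
#'   and biases, class ordering, the training configuration, and the final
#'   training loss/accuracy.
#' @export
fine_tune <- function(stack, X, y, cfg = stack$config) {
  X <- as_numeric_matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) abort("`X` and `y` differ in length")
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("fine-tuning needs at least two classes")
  if (ncol(X) != length(stack$standardization$mean)) {
    abort("`X` width does not match the pretrained stack")
  }
  Z <- sweep(sweep(X, 2, stack$standardization$mean), 2, stack$standardization$sd, "/")
  Y <- outer(y, classes, "==") * 1
  n <- nrow(Z)
  G <- length(classes)
  weights <- lapply(stack$layers, `[[`, "W")
  biases <- lapply(stack$layers, `[[`, "c")
  h_top <- ncol(weights[[length(weights)]])
  fit <- with_local_seed(cfg$seed + 1L, {
    weights <- c(weights, list(matrix(stats::rnorm(h_top * G, sd = 0.01), h_top, G)))
    biases <- c(biases, list(rep(0, G)))
    vel_w <- lapply(weights, function(w) w * 0)
    vel_b <- lapply(biases, function(b) b * 0)
    nl <- length(weights)
    mu <- cfg$momentum
    for (epoch in seq_len(cfg$finetune_epochs)) {
      lr <- cfg$finetune_lr * cfg$lr_decay^((epoch - 1) %/% cfg$lr_decay_every)
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        zb <- Z[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        m <- nrow(zb)
        # Nesterov: gradient at the lookahead point theta + mu * v
        we <- Map(function(w, v) w + mu * v, weights, vel_w)
        be <- Map(function(b, v) b + mu * v, biases, vel_b)
        acts <- vector("list", nl)
        a <- zb
        for (i in seq_len(nl - 1)) {
          a <- sigmoid(sweep(a %*% we[[i]], 2, be[[i]], "+"))
          acts[[i]] <- a
        }
        probs <- softmax_rows(sweep(a %*% we[[nl]], 2, be[[nl]], "+"))
        delta <- (probs - yb) / m
        for (i in rev(seq_len(nl))) {
          a_prev <- if (i == 1) zb else acts[[i - 1]]
          gw <- crossprod(a_prev, delta) + cfg$weight_decay * we[[i]]
          gb <- colSums(delta)
          if (i > 1) {
            delta <- (delta %*% t(we[[i]])) * acts[[i - 1]] * (1 - acts[[i - 1]])
          }
          vel_w[[i]] <- mu * vel_w[[i]] - lr * gw
          vel_b[[i]] <- mu * vel_b[[i]] - lr * gb
          weights[[i]] <- weights[[i]] + vel_w[[i]]
          biases[[i]] <- biases[[i]] + vel_b[[i]]
        }
      }
    }
    list(weights = weights, biases = biases)
  })
  model <- structure(
    list(
      weights = fit$weights, biases = fit$biases, classes = classes,
      standardization = stack$standardization, config = cfg,
      recon_error = lapply(stack$layers, `[[`, "recon_error")
    ),
    class = "seqrbm_deepmodel"
  )
  pr <- predict(model, X, type = "prob")
  ll <- -mean(log(pmax(pr[cbind(seq_len(n), match(y, classes))], 1e-15)))
  if (!is.finite(ll)) {
    abort("fine-tuning diverged (non-finite loss); try a smaller learning rate",
      class = "seqrbm_training_error"
    )
  }
  model$final_loss <- ll
  model$train_accuracy <- mean(predict(model, X) == y)
  model
}

#' Train a stacked-RBM classifier end to end
#'
#' Convenience wrapper: [pretrain_stack()] followed by [fine_tune()].
#'
#' @param X A feature table (labels taken from it) or numeric matrix.
#' @param y Labels; defaults to the feature-table labels.
#' @param cfg A [deep_net_config()].
#' @return A `seqrbm_deepmodel`.
#' @export
train_deep_classifier <- function(X, y = NULL, cfg = deep_net_config()) {
  if (is.null(y)) {
    if (!inherits(X, "seqrbm_features")) abort("`y` is required when `X` is a bare matrix")
    y <- feature_labels(X)
  }
  stack <- pretrain_stack(X, cfg)
  fine_tune(stack, X, y, cfg)
}

#' Predict classes or class probabilities from a fitted deep model
#'
#' Probability rows sum to 1; the predicted label is the argmax class, with
#' exact ties broken toward the lowest class ordinal.
#'
#' @param object A `seqrbm_deepmodel`.
#' @param newdata Feature table or numeric matrix of matching width.
#' @param type `"class"` (default) for labels, `"prob"` for the softmax
#'   probability matrix.
#' @param ... Unused.
#' @export
predict.seqrbm_deepmodel <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_numeric_matrix(newdata)
  if (ncol(X) != length(object$standardization$mean)) {
    abort("`newdata` width does not match the model input width")
  }
  Z <- sweep(sweep(X, 2, object$standardization$mean), 2, object$standardization$sd, "/")
  nl <- length(object$weights)
  a <- Z
  for (i in seq_len(nl - 1)) {
    a <- sigmoid(sweep(a %*% object$weights[[i]], 2, object$biases[[i]], "+"))
  }
  probs <- softmax_rows(sweep(a %*% object$weights[[nl]], 2, object$biases[[nl]], "+"))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' Serialize / restore a fitted deep model as JSON
#'
#' A portable plain-text archive: metadata plus all weight matrices.
#'
#' @param model A `seqrbm_deepmodel`.
#' @param path File path.
#' @return `write_deep_model()`: `path` invisibly; `read_deep_model()`: the
#'   model.
#' @export
write_deep_model <- function(model, path) {
  payload <- list(
    classes = model$classes,
    weights = lapply(model$weights, unclass),
    biases = model$biases,
    standardization = model$standardization,
    config = unclass(model$config),
    final_loss = model$final_loss,
    train_accuracy = model$train_accuracy
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_deep_model
#' @export
read_deep_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      weights = lapply(p$weights, function(w) as.matrix(w)),
      biases = lapply(p$biases, as.numeric),
      classes = p$classes,
      standardization = list(
        mean = as.numeric(p$standardization$mean),
        sd = as.numeric(p$standardization$sd)
      ),
      config = do.call(deep_net_config, p$config[names(p$config) %in% names(formals(deep_net_config))]),
      final_loss = p$final_loss, train_accuracy = p$train_accuracy
    ),
    class = "seqrbm_deepmodel"
  )
}
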