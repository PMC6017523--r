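# Shared fixtures, all built in code.

# A tiny aligned set over a few labels.
tiny_aligned <- function() {
  seq_set(
    id = c("s1", "s2", "s3"),
    label = c("mG", "Cs", "mG"),
    residues = c("ACD-", "AC-D", "AAAA"),
    aligned = TRUE
  )
}

# A property index with recognisable values (A 1.8, C 2.5, D -3.5, rest 0).
toy_index <- function() {
  v <- stats::setNames(rep(0, 20), seqrbm:::AA_ORDER)
  v[c("A", "C", "D")] <- c(1.8, 2.5, -3.5)
  property_index(v, accession = "TOY")
}

# Random sequence set (unaligned) for transform oracles.
random_seqs <- function(n, len, alphabet = seqrbm:::AA_ORDER, seed = 42) {
  withr::with_seed(seed, {
    seq_set(
      id = sprintf("r%02d", seq_len(n)),
      label = rep_len(c("a", "b"), n),
      residues = vapply(
        seq_len(n),
        function(i) paste(sample(alphabet, len, replace = TRUE), collapse = ""),
        character(1)
      )
    )
  })
}

# Study-scale synthetic conditions: seven unbalanced classes (total 1199),
# L = 259, 10% signal positions, 5% gaps, with the anchor-separating index.
study_conditions <- function(effect, seed = 3) {
  spec <- synthetic_spec(scale = 1, effect = effect, seed = seed)
  seqs <- generate_sequences(spec)
  idx <- generate_property_index(7,
    discriminative_for = seqrbm:::class_anchors(names(spec$class_sizes))
  )
  list(spec = spec, seqs = seqs, index = idx, features = encode_sequences(seqs, idx))
}

# Training budget used for study-scale RBM runs in tests and examples.
study_net_config <- function(seed = 1L) {
  deep_net_config(
    hidden_layers = c(128, 128), pretrain_epochs = 15, finetune_epochs = 120,
    seed = seed
  )
}

# Draw a random G-class confusion matrix with counts <= max_count and at
# least one sample per class row.
random_confusion <- function(G, max_count = 50) {
  C <- matrix(sample(0:max_count, G * G, replace = TRUE), G)
  diag(C) <- diag(C) + 1 # keep row sums positive
  dimnames(C) <- list(truth = letters[1:G], pred = letters[1:G])
  structure(C, class = c("seqrbm_confusion", "matrix", "array"))
}

# Expand a confusion matrix back into truth/pred label vectors.
confusion_to_labels <- function(C) {
  cls <- rownames(C)
  truth <- character(0)
  pred <- character(0)
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      truth <- c(truth, rep(cls[i], C[i, j]))
      pred <- c(pred, rep(cls[j], C[i, j]))
    }
  }
  list(truth = truth, pred = pred)
}
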