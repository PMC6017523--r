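test_that("composition is the normalized residue frequency", {
  s <- seq_set("s1", "a", "AAAC")
  f <- feature_matrix(aacomp(s))
  expect_equal(unname(f[1, "f_A"]), 0.75)
  expect_equal(unname(f[1, "f_C"]), 0.25)
  expect_equal(sum(f[1, ]), 1, tolerance = 1e-12)
  expect_length(feature_names(aacomp(s)), 20)
  # gaps are ignored, all-gap records are data errors
  expect_equal(
    unname(feature_matrix(aacomp(seq_set("g", "a", "A-A-")))[1, "f_A"]),
    1
  )
  expect_error(aacomp(seq_set("g", "a", "--")), "no standard residues")
})

test_that("pseaa has length 20 + n*lambda and matches its definition", {
  s <- random_seqs(4, 40)
  cfg <- transform_config(lambda = 21, n_props = 2)
  f <- pseaa(s, cfg)
  expect_length(feature_names(f), 62)

  sc <- builtin_scales()
  for (i in c(1, 4)) {
    expect_equal(
      unname(feature_matrix(f)[i, ]),
      unname(pseaa_oracle(s$residues[i], 21, list(sc$hydrophobicity, sc$hydrophilicity), 0.05)),
      tolerance = 1e-12
    )
  }
})

test_that("pseaa at lambda = 0 equals composition exactly", {
  s <- random_seqs(5, 30)
  expect_equal(
    feature_matrix(pseaa(s, transform_config(lambda = 0))),
    feature_matrix(aacomp(s))
  )
})

test_that("homopolymer lag-1 correlation factor is h(A)^2", {
  s <- seq_set("homo", "a", strrep("A", 30))
  cfg <- transform_config(lambda = 1, n_props = 1, pseaa_weight = 0.05)
  sc <- builtin_scales()
  h <- (sc$hydrophobicity - mean(sc$hydrophobicity)) /
    sqrt(mean((sc$hydrophobicity - mean(sc$hydrophobicity))^2))
  tau <- unname(h["A"]^2)
  f <- feature_matrix(pseaa(s, cfg))
  expect_length(f[1, ], 21)
  expect_equal(unname(f[1, 21]), 0.05 * tau / (1 + 0.05 * tau), tolerance = 1e-12)
})

test_that("short sequences relative to lambda are data errors", {
  s <- seq_set("short", "a", "ACDEF")
  expect_error(pseaa(s, transform_config(lambda = 21)), "short")
})

test_that("wavelet multiscale energy matches the basis-function oracle", {
  s <- random_seqs(3, 100)
  m <- 5
  f <- feature_matrix(mse_wavelet(s, m = m))
  expect_equal(ncol(f), m + 1)
  sc <- builtin_scales()$FHscale
  for (i in 1:3) {
    w <- haar_oracle(sc[strsplit(s$residues[i], "")[[1]]], m)
    expect_equal(
      unname(f[i, ]),
      c(sapply(w$details, function(d) sqrt(mean(d^2))), sqrt(mean(w$approx^2))),
      tolerance = 1e-10
    )
  }
})

test_that("constant signals concentrate all energy in the approximation", {
  m <- 4
  cval <- 2.5
  # sequence of one residue whose scale value we control via an ad-hoc scale
  sc <- stats::setNames(rep(cval, 20), seqrbm:::AA_ORDER)
  s <- seq_set("const", "a", strrep("A", 2^m))
  f <- feature_matrix(mse_wavelet(s, scale = sc, m = m))
  expect_equal(unname(f[1, 1:m]), rep(0, m), tolerance = 1e-12)
  expect_equal(unname(f[1, m + 1]), cval * 2^(m / 2), tolerance = 1e-12)
})

test_that("identical sequences give identical wavelet rows", {
  s <- seq_set(c("a1", "a2"), c("x", "y"), rep("ACDKLMNPQR", 2))
  f <- feature_matrix(mse_wavelet(s, m = 3))
  expect_equal(f[1, ], f[2, ])
})

test_that("pseaa-mse concatenates its two component blocks", {
  s <- random_seqs(3, 80)
  cfg <- transform_config(lambda = 21, n_props = 2, wavelet_level = 6)
  f <- feature_matrix(pseaa_mse(s, cfg))
  expect_equal(ncol(f), 62 + 7)
  expect_equal(f[, 1:62], feature_matrix(pseaa(s, cfg)))
  expect_equal(
    f[, 63:69],
    feature_matrix(mse_wavelet(s, m = 6))
  )
})

test_that("acc has 25 * Lag features and matches the double-loop oracle", {
  f <- acc_transform(random_seqs(2, 30), transform_config(acc_lag = 13))
  expect_length(feature_names(f), 325)

  s3 <- random_seqs(5, 30, alphabet = c("A", "K", "W"), seed = 9)
  cfg <- transform_config(acc_lag = 2, acc_p = 0.5)
  f3 <- feature_matrix(acc_transform(s3, cfg))
  zs <- builtin_scales()$zscales
  for (i in 1:5) {
    expect_equal(
      unname(f3[i, ]),
      unname(acc_oracle(s3$residues[i], zs, 2, 0.5)),
      tolerance = 1e-10
    )
  }
})

test_that("homopolymers have identically zero auto-cross-covariance", {
  s <- seq_set("homo", "a", strrep("W", 40))
  f <- feature_matrix(acc_transform(s, transform_config(acc_lag = 5)))
  expect_equal(unname(f[1, ]), rep(0, 125))
})

test_that("acc is invariant to per-descriptor mean shifts", {
  s <- random_seqs(3, 35, seed = 11)
  zs <- builtin_scales()$zscales
  zs_shift <- zs
  zs_shift[, 2] <- zs_shift[, 2] + 7.3
  cfg <- transform_config(acc_lag = 4)
  expect_equal(
    feature_matrix(acc_transform(s, cfg, zscales = zs_shift)),
    feature_matrix(acc_transform(s, cfg, zscales = zs)),
    tolerance = 1e-10
  )
})

test_that("sequences not longer than the maximum lag are data errors", {
  s <- seq_set("short", "a", "ACDEF")
  expect_error(acc_transform(s, transform_config(acc_lag = 5)), "short")
})

test_that("alignment-free transforms depend only on the record itself", {
  s <- random_seqs(4, 50)
  perm <- c(3, 1, 4, 2)
  sp <- seq_set(s$id[perm], s$label[perm], s$residues[perm])
  for (fn in list(
    aacomp,
    function(x) pseaa(x, transform_config(lambda = 3)),
    function(x) acc_transform(x, transform_config(acc_lag = 3))
  )) {
    expect_equal(feature_matrix(fn(sp)), feature_matrix(fn(s))[perm, ])
  }
})
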