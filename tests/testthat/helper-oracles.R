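# Independent brute-force oracles for the alignment-free transforms.

# PseAA by direct evaluation of its definition (composition + per-property
# lag correlations, jointly normalized).
pseaa_oracle <- function(residues, lambda, props, w) {
  r <- strsplit(residues, "")[[1]]
  f <- as.numeric(table(factor(r, levels = seqrbm:::AA_ORDER))) / length(r)
  hs <- lapply(props, function(p) {
    v <- p[seqrbm:::AA_ORDER]
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  })
  taus <- unlist(lapply(hs, function(h) {
    v <- h[r]
    sapply(seq_len(lambda), function(l) {
      mean(v[seq_len(length(v) - l)] * v[(1 + l):length(v)])
    })
  }))
  denom <- 1 + w * sum(taus)
  c(f / denom, w * taus / denom)
}

# Haar coefficients as inner products with explicit orthonormal basis
# functions on the zero-padded signal.
haar_oracle <- function(x, m) {
  n <- 2^max(ceiling(log2(max(length(x), 2))), m)
  x <- c(x, rep(0, n - length(x)))
  details <- lapply(seq_len(m), function(j) {
    half <- 2^(j - 1)
    sapply(seq_len(n / 2^j), function(k) {
      seg <- x[((k - 1) * 2^j + 1):(k * 2^j)]
      2^(-j / 2) * (sum(seg[seq_len(half)]) - sum(seg[half + seq_len(half)]))
    })
  })
  approx <- sapply(seq_len(n / 2^m), function(k) {
    2^(-m / 2) * sum(x[((k - 1) * 2^m + 1):(k * 2^m)])
  })
  list(details = details, approx = approx)
}

# Auto/cross-covariance by a literal double loop.
acc_oracle <- function(residues, zs, lag_max, p) {
  r <- strsplit(residues, "")[[1]]
  V <- zs[r, , drop = FALSE]
  n <- nrow(V)
  vbar <- colMeans(V)
  out <- c()
  for (l in seq_len(lag_max)) {
    ac <- sapply(1:5, function(d) {
      s <- 0
      for (i in 1:(n - l)) s <- s + (V[i, d] - vbar[d]) * (V[i + l, d] - vbar[d])
      s / (n - l)^p
    })
    cc <- c()
    for (d in 1:5) {
      for (dp in setdiff(1:5, d)) {
        s <- 0
        for (i in 1:(n - l)) s <- s + (V[i, d] - vbar[d]) * (V[i + l, dp] - vbar[dp])
        cc <- c(cc, s / (n - l)^p)
      }
    }
    out <- c(out, ac, cc)
  }
  out
}

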