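#' Configuration for the alignment-free transforms
#'
#' Defaults follow the standard class C GPCR setup: lambda = 21 correlation
#' levels over n = 2 properties (hydrophobicity + hydrophilicity) for
#' pseudo-amino-acid composition, Haar decomposition level m = 11
#' (`"auto"` = floor(log2(max sequence length))), and auto-cross-covariance
#' with maximum lag 13 and normalization degree p = 0.5.
#'
#' @param lambda Number of correlation levels (lags) for PseAA; `lambda = 0`
#'   reduces PseAA to plain composition.
#' @param n_props Number of physicochemical properties for PseAA (1 or 2).
#' @param pseaa_weight Weight `w` of the correlation block in the PseAA
#'   normalization denominator.
#' @param wavelet_level Haar decomposition level `m`, or `"auto"`.
#' @param acc_lag Maximum lag for the auto-cross-covariance transform; must
#'   be smaller than the shortest sequence.
#' @param acc_p Degree of normalization `p` in the covariance denominator
#'   `(n - l)^p`.
#' @return A list of class `seqrbm_transform_config`.
#' @export
transform_config <- function(lambda = 21, n_props = 2, pseaa_weight = 0.05,
                             wavelet_level = 11, acc_lag = 13, acc_p = 0.5) {
  stopifnot(lambda >= 0, n_props %in% 1:2, pseaa_weight > 0, acc_lag >= 1, acc_p > 0, acc_p <= 1)
  if (!identical(wavelet_level, "auto")) stopifnot(wavelet_level >= 1)
  structure(
    list(
      lambda = as.integer(lambda), n_props = as.integer(n_props),
      pseaa_weight = pseaa_weight, wavelet_level = wavelet_level,
      acc_lag = as.integer(acc_lag), acc_p = acc_p
    ),
    class = "seqrbm_transform_config"
  )
}

residues_list <- function(seqs) {
  bare <- degap(seqs$residues)
  empty <- nchar(bare) == 0
  if (any(empty)) {
    abort(sprintf("record '%s' has no standard residues", seqs$id[which(empty)[1]]))
  }
  strsplit(bare, "", fixed = TRUE)
}

#' Amino-acid composition
#'
#' Relative frequency of each of the 20 standard residues per sequence
#' (gaps and ambiguity codes are ignored). Rows sum to 1.
#'
#' @param seqs A [seq_set()] tibble (aligned or not).
#' @return An `N x 20` feature table in canonical residue order.
#' @export
aacomp <- function(seqs) {
  res <- residues_list(seqs)
  m <- t(vapply(
    res,
    function(r) as.numeric(table(factor(r, levels = AA_ORDER))) / length(r),
    numeric(20)
  ))
  colnames(m) <- paste0("f_", AA_ORDER)
  new_feature_tbl(m, seqs$id, seqs$label, tag = "aacomp")
}

# Property values standardized to zero mean / unit (population) SD over the
# 20 residues, as in standard pseudo-amino-acid composition.
standardize_scale <- function(scale) {
  v <- scale[AA_ORDER]
  (v - mean(v)) / sqrt(mean((v - mean(v))^2))
}

#' Pseudo-amino-acid composition (amphiphilic form)
#'
#' Composition augmented with lag-correlation factors of standardized
#' physicochemical property values along the sequence: for property `p` and
#' lag `l`, `tau[p,l] = mean_i h_p(R_i) * h_p(R_(i+l))`. The feature vector
#' `[P_1..P_20, P_21..P_Lambda]` has length `Lambda = 20 + n * lambda`, with
#' `P_u = f_u / (1 + w * sum(tau))` for the 20 composition terms and
#' `P_(20+j) = w * tau_j / (1 + w * sum(tau))` for the correlation terms,
#' ordered property-major (all lags of property 1, then property 2).
#'
#' @param seqs A [seq_set()] tibble.
#' @param cfg A [transform_config()].
#' @param scales Scale tables; `hydrophobicity` and `hydrophilicity` are used.
#' @return An `N x (20 + n*lambda)` feature table.
#' @export
pseaa <- function(seqs, cfg = transform_config(), scales = builtin_scales()) {
  props <- list(scales$hydrophobicity, scales$hydrophilicity)[seq_len(cfg$n_props)]
  props <- lapply(props, standardize_scale)
  lam <- cfg$lambda
  res <- residues_list(seqs)
  short <- vapply(res, length, integer(1)) <= lam
  if (any(short)) {
    abort(sprintf(
      "record '%s' is too short for lambda = %d (needs length > %d)",
      seqs$id[which(short)[1]], lam, lam
    ))
  }
  comp <- feature_matrix(aacomp(seqs))
  rows <- t(vapply(seq_along(res), function(i) {
    r <- res[[i]]
    taus <- if (lam == 0) numeric(0) else {
      unlist(lapply(props, function(h) {
        v <- h[r]
        vapply(seq_len(lam), function(l) {
          n <- length(v)
          mean(v[1:(n - l)] * v[(1 + l):n])
        }, numeric(1))
      }))
    }
    denom <- 1 + cfg$pseaa_weight * sum(taus)
    c(comp[i, ] / denom, cfg$pseaa_weight * taus / denom)
  }, numeric(20 + cfg$n_props * lam)))
  cn <- c(paste0("f_", AA_ORDER))
  if (lam > 0) {
    cn <- c(cn, paste0(
      "tau_p", rep(seq_len(cfg$n_props), each = lam), "_l", rep(seq_len(lam), cfg$n_props)
    ))
  }
  colnames(rows) <- cn
  new_feature_tbl(rows, seqs$id, seqs$label,
    tag = sprintf("pseaa[lambda=%d,n=%d,w=%g]", lam, cfg$n_props, cfg$pseaa_weight)
  )
}

# Orthonormal Haar analysis step: x of even length -> list(approx, detail).
haar_step <- function(x) {
  odd <- x[seq(1, length(x), by = 2)]
  even <- x[seq(2, length(x), by = 2)]
  list(a = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2))
}

# Full m-level Haar DWT of a signal zero-padded to the next power of two
# >= max(length(x), 2^m). Returns detail coefficient vectors for levels
# 1..m and the level-m approximation.
haar_dwt <- function(x, m) {
  n_pad <- 2^max(ceiling(log2(max(length(x), 2))), m)
  x <- c(x, rep(0, n_pad - length(x)))
  details <- vector("list", m)
  for (lev in seq_len(m)) {
    s <- haar_step(x)
    details[[lev]] <- s$d
    x <- s$a
  }
  list(details = details, approx = x)
}

rms <- function(v) sqrt(mean(v^2))

#' Haar-wavelet multiscale energy
#'
#' Converts each sequence to a numeric signal via a hydrophobicity scale and
#' computes the root-mean-square energy of the Haar detail coefficients at
#' scales `1..m` plus the RMS energy of the level-`m` approximation, giving
#' `m + 1` features per sequence. Signals are zero-padded to the next power
#' of two so `m` levels always exist; `m = "auto"` uses
#' `floor(log2(max sequence length))` across the dataset so vectors share a
#' common depth.
#'
#' @param seqs A [seq_set()] tibble.
#' @param scale A 20-residue numeric scale (default the FHscale).
#' @param m Decomposition level, or `"auto"`.
#' @return An `N x (m+1)` feature table `d1..dm, am`.
#' @export
mse_wavelet <- function(seqs, scale = builtin_scales()$FHscale, m = "auto") {
  res <- residues_list(seqs)
  lens <- vapply(res, length, integer(1))
  if (any(lens < 2)) {
    abort(sprintf("record '%s' is too short for a wavelet transform", seqs$id[which(lens < 2)[1]]))
  }
  if (identical(m, "auto")) m <- floor(log2(max(lens)))
  m <- as.integer(m)
  stopifnot(m >= 1)
  sc <- scale[AA_ORDER]
  rows <- t(vapply(res, function(r) {
    w <- haar_dwt(sc[r], m)
    c(vapply(w$details, rms, numeric(1)), rms(w$approx))
  }, numeric(m + 1)))
  colnames(rows) <- c(paste0("d", seq_len(m)), paste0("a", m))
  new_feature_tbl(rows, seqs$id, seqs$label, tag = sprintf("mse[m=%d]", m))
}

#' Hybrid PseAA + multiscale-energy features
#'
#' Concatenates the [pseaa()] vector with the [mse_wavelet()] vector, giving
#' length `20 + n*lambda + m + 1` (74 at the defaults lambda = 21, n = 2,
#' m = 11).
#'
#' @inheritParams pseaa
#' @return An `N x (Lambda + m + 1)` feature table.
#' @export
pseaa_mse <- function(seqs, cfg = transform_config(), scales = builtin_scales()) {
  a <- pseaa(seqs, cfg, scales)
  b <- mse_wavelet(seqs, scales$FHscale, cfg$wavelet_level)
  m <- cbind(feature_matrix(a), feature_matrix(b))
  new_feature_tbl(m, seqs$id, seqs$label,
    tag = paste(attr(a, "transform_tag"), attr(b, "transform_tag"), sep = "+")
  )
}

#' Auto-cross-covariance transform over the five z-scales
#'
#' Each sequence is translated into five per-residue z-scale descriptors.
#' For each lag `l = 1..Lag` the transform computes 5 auto-covariance terms
#' `AC_d(l) = sum_i (v[d,i] - vbar_d)(v[d,i+l] - vbar_d) / (n - l)^p`
#' and 20 cross-covariance terms `CC_dd'(l)` over ordered descriptor pairs
#' `d != d'` (lexicographic: (1,2), (1,3), ..., (5,4)); per-lag blocks are
#' concatenated, giving `25 * Lag` features.
#'
#' @param seqs A [seq_set()] tibble; every sequence must be longer than
#'   `cfg$acc_lag`.
#' @param cfg A [transform_config()].
#' @param zscales A 20 x 5 descriptor matrix (default the bundled z-scales).
#' @return An `N x (25*Lag)` feature table.
#' @export
acc_transform <- function(seqs, cfg = transform_config(), zscales = builtin_scales()$zscales) {
  lag_max <- cfg$acc_lag
  p <- cfg$acc_p
  res <- residues_list(seqs)
  short <- vapply(res, length, integer(1)) <= lag_max
  if (any(short)) {
    abort(sprintf(
      "record '%s' is shorter than acc_lag = %d", seqs$id[which(short)[1]], lag_max
    ))
  }
  D <- ncol(zscales)
  pairs <- expand.grid(dp = seq_len(D), d = seq_len(D))[, 2:1]
  pairs <- pairs[pairs$d != pairs$dp, ]
  pairs <- pairs[order(pairs$d, pairs$dp), ]
  rows <- t(vapply(res, function(r) {
    V <- zscales[r, , drop = FALSE] # n x D
    n <- nrow(V)
    Vc <- sweep(V, 2, colMeans(V))
    unlist(lapply(seq_len(lag_max), function(l) {
      i <- seq_len(n - l)
      denom <- (n - l)^p
      ac <- vapply(seq_len(D), function(d) sum(Vc[i, d] * Vc[i + l, d]) / denom, numeric(1))
      cc <- mapply(function(d, dp) sum(Vc[i, d] * Vc[i + l, dp]) / denom, pairs$d, pairs$dp)
      c(ac, cc)
    }))
  }, numeric(25 * lag_max)))
  colnames(rows) <- unlist(lapply(seq_len(lag_max), function(l) {
    c(
      sprintf("ac_d%d_l%d", seq_len(D), l),
      sprintf("cc_d%d_d%d_l%d", pairs$d, pairs$dp, l)
    )
  }))
  new_feature_tbl(rows, seqs$id, seqs$label,
    tag = sprintf("acc[lag=%d,p=%g]", lag_max, p)
  )
}
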