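# Bundled physicochemical scale tables.
#
# FH_HYDROPHOBICITY: Fauchere & Pliska (1983) octanol/water hydrophobicity
#   (AAindex accession FAUJ830101); drives the wavelet multiscale-energy signal.
# PSEAA_HYDROPHOBICITY: Eisenberg consensus hydrophobicity as used by the
#   standard pseudo-amino-acid composition tables.
# PSEAA_HYDROPHILICITY: Hopp & Woods (1981) hydrophilicity
#   (AAindex accession HOPT810101).
# ZSCALES: Sandberg et al. (1998) five principal-property z-scales for the
#   20 coded amino acids (z1 lipophilicity, z2 steric/bulk, z3 polarity,
#   z4/z5 electronic effects).

FH_HYDROPHOBICITY <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

PSEAA_HYDROPHOBICITY <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
  Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
  L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
  S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08
)

PSEAA_HYDROPHILICITY <- c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
  Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8,
  L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
  S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5
)

ZSCALES <- local({
  m <- rbind(
    A = c(0.24, -2.32, 0.60, -0.14, 1.30),
    R = c(3.52, 2.50, -3.50, 1.99, -0.17),
    N = c(3.05, 1.62, 1.04, -1.15, 1.61),
    D = c(3.98, 0.93, 1.93, -2.46, 0.75),
    C = c(0.84, -1.67, 3.71, 0.18, -2.65),
    Q = c(1.75, 0.50, -1.44, -1.34, 0.66),
    E = c(3.11, 0.26, -0.11, -3.04, -0.25),
    G = c(2.05, -4.06, 0.36, -0.82, -0.38),
    H = c(2.47, 1.95, 0.26, 3.90, 0.09),
    I = c(-3.89, -1.73, -1.71, -0.84, 0.26),
    L = c(-4.28, -1.30, -1.49, -0.72, 0.84),
    K = c(2.29, 0.89, -2.49, 1.49, 0.31),
    M = c(-2.85, -0.22, 0.47, 1.94, -0.98),
    F = c(-4.22, 1.94, 1.06, 0.54, -0.62),
    P = c(-1.66, 0.27, 1.84, 0.70, 2.00),
    S = c(2.39, -1.07, 1.15, -1.39, 0.67),
    T = c(0.75, -2.18, -1.12, -1.46, -0.40),
    W = c(-4.36, 3.94, 0.59, 3.44, -1.59),
    Y = c(-2.54, 2.44, 0.43, 0.04, -1.47),
    V = c(-2.59, -2.64, -1.54, -0.85, -0.02)
  )
  colnames(m) <- paste0("z", 1:5)
  m[AA_ORDER, ]
})

#' Bundled physicochemical scale tables
#'
#' Returns the fixed scale tables used by the alignment-free transforms:
#' the Fauchere-Pliska hydrophobicity scale (`FHscale`, the wavelet signal),
#' the hydrophobicity and hydrophilicity tables of standard pseudo-amino-acid
#' composition, and the five Sandberg z-scales used by the
#' auto-cross-covariance transform.
#'
#' @return A list with elements `FHscale`, `hydrophobicity`, `hydrophilicity`
#'   (named 20-residue numeric vectors) and `zscales` (a 20 x 5 matrix, rows
#'   in canonical residue order, columns `z1`..`z5`).
#' @examples
#' sc <- builtin_scales()
#' dim(sc$zscales) # 20 x 5
#' @export
builtin_scales <- function() {
  list(
    FHscale = FH_HYDROPHOBICITY[AA_ORDER],
    hydrophobicity = PSEAA_HYDROPHOBICITY[AA_ORDER],
    hydrophilicity = PSEAA_HYDROPHILICITY[AA_ORDER],
    zscales = ZSCALES
  )
}
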