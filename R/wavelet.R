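# Orthogonal discrete wavelet transform machinery.
#
# The denoiser needs three things from the transform: (i) the forward map
# w = W x for an orthogonal m x m matrix W, (ii) its inverse W', and
# (iii) the matrix of squared entries (W.W), which propagates pointwise
# noise variances into the coefficient domain. The transform is the
# periodized pyramid algorithm: with orthonormal quadrature-mirror filters
# and an even signal length, every analysis level is an orthogonal map, so
# the composed W satisfies W'W = I exactly — the property the variance
# propagation and the energy bound of the shrinker both rest on.

# Decomposition low-pass filters. sym8 is the least-asymmetric Daubechies
# filter with 8 vanishing moments (16 taps), the standard "Symmlet 8".
WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
            0.03169508781149298,    0.007607487324917605,
           -0.1432942383508097,    -0.061273359067658524,
            0.4813596512583722,     0.7771857517005235,
            0.3644418948353314,    -0.05194583810770904,
           -0.027219029917056003,   0.049137179673607506,
            0.003808752013890615,  -0.01495225833704823,
           -0.0003029205147213668,  0.0018899503327594609)
)

#' Wavelet design: basis, depth, boundary and padding policy
#'
#' Bundles the choices that determine the orthogonal transform matrix W.
#' The default basis is Symmlet 8; Haar is provided mainly because its W is
#' small and explicit enough to verify by hand. Boundary handling is
#' periodization (the only extension that keeps the finite transform
#' exactly orthogonal); signals whose length is not a power of two are
#' symmetrically reflection-padded up to the next power of two, processed,
#' and cropped. Decomposition depth defaults to the maximum number of
#' halvings for which the current length still covers the filter.
#'
#' @param basis `"sym8"` (default) or `"haar"`.
#' @param levels decomposition depth, or `NULL` (default) for maximal.
#' @param pad_policy `"reflect"` (symmetric reflection to the next power of
#'   two; default) or `"none"` (error on non-dyadic lengths).
#' @return An object of class `"wavelet_design"`.
#' @export
wavelet_design <- function(basis = c("sym8", "haar"), levels = NULL,
                           pad_policy = c("reflect", "none")) {
  basis <- match.arg(basis)
  pad_policy <- match.arg(pad_policy)
  if (!is.null(levels)) {
    levels <- as.integer(levels)
    if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  }
  structure(list(basis = basis, levels = levels, boundary = "periodic",
                 pad_policy = pad_policy),
            class = "wavelet_design")
}

# Quadrature mirror high-pass from the low-pass: g[k] = (-1)^k h[L-1-k].
qmf_highpass <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

# Maximal depth: halve while the working length is >= the filter length.
max_dwt_levels <- function(m, filter_length) {
  lev <- 0L
  len <- m
  while (len >= filter_length && len %% 2L == 0L && len > 1L) {
    lev <- lev + 1L
    len <- len %/% 2L
  }
  lev
}

resolve_levels <- function(m, d) {
  h <- WAVELET_FILTERS[[d$basis]]
  maxlev <- max_dwt_levels(m, length(h))
  if (is.null(d$levels)) return(maxlev)
  if (d$levels > maxlev)
    stop(sprintf("requested %d levels but length %d admits only %d",
                 d$levels, m, maxlev), call. = FALSE)
  d$levels
}

is_pow2 <- function(m) m >= 1 && bitwAnd(m, m - 1L) == 0L

next_pow2 <- function(m) {
  p <- 1L
  while (p < m) p <- p * 2L
  p
}

# Symmetric (half-sample) reflection pad of a vector to length target.
# Padding is appended on the right; for target < 2*m the reflected tail of
# x supplies it. Lengths here always satisfy target <= 2*m - 1 is not
# guaranteed for tiny m, so the reflection is recycled if needed.
reflect_pad <- function(x, target) {
  m <- length(x)
  if (m >= target) return(x[seq_len(target)])
  ext <- x
  mirror <- rev(x)
  while (length(ext) < target) {
    ext <- c(ext, mirror)
    mirror <- rev(mirror)
  }
  ext[seq_len(target)]
}

# One periodized analysis level applied to the rows of a matrix: each
# column of A is an independent signal of length c (even). Returns the
# approximation and detail halves, each c/2 rows.
dwt_level_matrix <- function(A, h, g) {
  c_len <- nrow(A)
  half <- c_len %/% 2L
  L <- length(h)
  base <- 2L * (seq_len(half) - 1L)           # 0, 2, 4, ...
  approx <- matrix(0, nrow = half, ncol = ncol(A))
  detail <- matrix(0, nrow = half, ncol = ncol(A))
  for (t in seq_len(L)) {
    idx <- (base + (t - 1L)) %% c_len + 1L
    approx <- approx + h[t] * A[idx, , drop = FALSE]
    detail <- detail + g[t] * A[idx, , drop = FALSE]
  }
  list(approx = approx, detail = detail)
}

# Forward periodized DWT of the columns of X (dyadic row count assumed).
# Coefficient ordering: [approx_J, detail_J, detail_{J-1}, ..., detail_1].
dwt_forward_matrix <- function(X, basis, levels) {
  h <- WAVELET_FILTERS[[basis]]
  g <- qmf_highpass(h)
  A <- X
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    lv <- dwt_level_matrix(A, h, g)
    A <- lv$approx
    details[[levels - j + 1L]] <- lv$detail   # store deepest first
  }
  do.call(rbind, c(list(A), details))
}

dwt_forward <- function(x, basis, levels) {
  drop(dwt_forward_matrix(matrix(x, ncol = 1L), basis, levels))
}

# Inverse via one synthesis level at a time (transpose of analysis).
idwt_forward <- function(w, basis, levels) {
  h <- WAVELET_FILTERS[[basis]]
  g <- qmf_highpass(h)
  m <- length(w)
  alen <- m %/% (2L^levels)
  A <- w[seq_len(alen)]
  pos <- alen
  for (j in seq_len(levels)) {
    half <- length(A)
    D <- w[pos + seq_len(half)]
    pos <- pos + half
    c_len <- 2L * half
    x <- numeric(c_len)
    base <- 2L * (seq_len(half) - 1L)
    for (t in seq_along(h)) {
      idx <- (base + (t - 1L)) %% c_len + 1L
      x[idx] <- x[idx] + h[t] * A + g[t] * D
    }
    A <- x
  }
  A
}

# Cache of explicit transform matrices keyed by (m, basis, levels).
.W_cache <- new.env(parent = emptyenv())

#' Explicit orthogonal transform matrix
#'
#' Builds the m x m matrix W of the periodized DWT by transforming the m
#' unit vectors (all at once, as the columns of the identity). The result
#' is cached per (length, basis, depth): the denoiser applies W, W' and the
#' squared-entry matrix (W.W) many times per run, and W depends only on the
#' design, never on the data. `m` must be a power of two — callers are
#' responsible for padding (see [shrink_spectrum()]).
#'
#' @param m signal length (power of two).
#' @param d a [wavelet_design()].
#' @return m x m orthogonal matrix W with `w = W %*% x`.
#' @export
transform_matrix <- function(m, d) {
  stopifnot(inherits(d, "wavelet_design"))
  if (!is_pow2(m))
    stop(sprintf("transform_matrix needs a power-of-two length (got %d)", m),
         call. = FALSE)
  levels <- resolve_levels(m, d)
  if (levels == 0L) return(diag(m))
  key <- sprintf("W_%d_%s_%d", m, d$basis, levels)
  if (!is.null(.W_cache[[key]])) return(.W_cache[[key]])
  W <- dwt_forward_matrix(diag(m), d$basis, levels)
  .W_cache[[key]] <- W
  W
}

#' Squared-transform operator (W.W)
#'
#' Returns the matrix whose (i, j) entry is the square of W's (i, j) entry.
#' Applied to a vector of pointwise noise variances it yields the exact
#' variance of each wavelet coefficient under independent pointwise noise:
#' Var(w_i) = sum_j W_ij^2 Var(x_j). Because W is orthogonal every row of
#' (W.W) sums to 1, so a constant variance vector passes through unchanged.
#' Cached alongside W.
#'
#' @inheritParams transform_matrix
#' @return m x m matrix of squared entries of W.
#' @export
squared_transform_matrix <- function(m, d) {
  W <- transform_matrix(m, d)
  levels <- resolve_levels(m, d)
  key <- sprintf("W2_%d_%s_%d", m, d$basis, levels)
  if (!is.null(.W_cache[[key]])) return(.W_cache[[key]])
  W2 <- W * W
  .W_cache[[key]] <- W2
  W2
}

#' Apply the squared-transform operator to a variance vector
#'
#' @param v nonnegative numeric vector (pointwise variances), length a
#'   power of two.
#' @param d a [wavelet_design()].
#' @return `(W.W) %*% v` as a plain vector.
#' @export
apply_squared_transform <- function(v, d) {
  drop(squared_transform_matrix(length(v), d) %*% v)
}
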