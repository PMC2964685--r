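#' Mean spectrum of a replicate set
#'
#' Pointwise arithmetic mean of the n aligned spectra. Under the NEF-QVF
#' detector model each point of the mean spectrum has expectation mu(t) and
#' variance V(mu(t))/n, so averaging a homogeneous group both suppresses
#' noise and lets peak detection run once on the group rather than
#' per-spectrum (sidestepping peak matching entirely).
#'
#' @param s a [spectrum_set()].
#' @return A [spectrum()] on the same grid.
#' @export
mean_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  spectrum(s$mz, rowMeans(s$intensities),
           meta = list(condition = s$condition_label, n = s$n,
                       kind = "mean_spectrum"))
}

# Pad a vector per the design's pad policy; returns the padded vector and
# the original length for cropping.
pad_vector <- function(x, d) {
  m <- length(x)
  if (is_pow2(m)) return(list(x = x, m = m, padded = FALSE))
  if (d$pad_policy == "none")
    stop(sprintf("length %d is not a power of two and pad_policy is 'none'", m),
         call. = FALSE)
  target <- next_pow2(m)
  list(x = reflect_pad(x, target), m = m, padded = TRUE)
}

#' Per-coefficient noise variance in the wavelet domain
#'
#' Computes the noise variance of each wavelet coefficient of the mean
#' spectrum under the quadratic variance model:
#'
#'   sigma2_tilde = (W.W) Vdag(x) / (n (1 + v2))
#'
#' where Vdag is the clamped variance function `max(V(x), v0)`, (W.W) is
#' the squared-entry transform matrix, the 1/(1+v2) factor corrects for the
#' signal's own contribution to the quadratic term, and the 1/n factor
#' reflects that the input is a mean of n replicate spectra (n = 1 treats
#' the input as a single raw spectrum). When the grid length is not a power
#' of two, the pointwise variance vector is reflection-padded exactly like
#' the signal, so the row-sum property holds on the operator actually used;
#' the returned vector then has the padded length.
#'
#' @param x_mean a [spectrum()] (typically a mean spectrum).
#' @param p a [qvf_params()].
#' @param d a [wavelet_design()].
#' @param n replicate count behind `x_mean` (default 1).
#' @return Nonnegative numeric vector of coefficient-domain variances.
#' @export
sigma2_tilde <- function(x_mean, p, d = wavelet_design(), n = 1L) {
  stopifnot(inherits(x_mean, "spectrum"), inherits(p, "qvf_params"))
  if (1 + p$v2 <= 0)
    stop("QVF model violation: 1 + v2 must be positive", call. = FALSE)
  if (n < 1L) stop("replicate count n must be >= 1", call. = FALSE)
  v <- variance_clamped(p, x_mean$intensity) / n
  pv <- pad_vector(v, d)
  out <- apply_squared_transform(pv$x, d) / (1 + p$v2)
  pmax(out, 0)
}

#' Heteroscedastic wavelet shrinkage of a mean spectrum
#'
#' Estimates the underlying signal mu(t) from a (mean) spectrum whose noise
#' follows the quadratic variance model. The spectrum is transformed into
#' an orthogonal wavelet basis (w = W x), each coefficient is shrunk by the
#' nonlinear factor
#'
#'   h(i) = max(w(i)^2 - sigma2(i), 0) / w(i)^2
#'
#' with per-coefficient noise variance sigma2(i) from [sigma2_tilde()], and
#' the result is transformed back: mu = W' diag(h) w. Coefficients whose
#' squared magnitude does not exceed their modeled noise variance are
#' zeroed; the rest are attenuated in proportion to their estimated
#' signal-to-total-energy ratio. h(i) is defined as 0 where w(i) = 0 (the
#' limiting value; the coefficient contributes nothing either way).
#'
#' Non-dyadic grids are symmetrically reflection-padded to the next power
#' of two, denoised, and cropped back; the output grid is identical to the
#' input grid.
#'
#' @inheritParams sigma2_tilde
#' @param diagnostics logical; also return the shrinkage internals.
#' @return The denoised [spectrum()]; if `diagnostics = TRUE`, a list
#'   `list(mu_tilde=, diagnostics=)` where diagnostics holds `w` (wavelet
#'   coefficients), `sigma2_tilde`, `h` (shrinkage factors, all in [0,1])
#'   and `kept_fraction` (share of coefficients with h > 0).
#' @export
shrink_spectrum <- function(x_mean, p, d = wavelet_design(), n = 1L,
                            diagnostics = FALSE) {
  stopifnot(inherits(x_mean, "spectrum"))
  px <- pad_vector(x_mean$intensity, d)
  mpad <- length(px$x)
  W <- transform_matrix(mpad, d)
  w <- drop(W %*% px$x)
  s2 <- sigma2_tilde(x_mean, p, d, n)
  h <- ifelse(w == 0, 0, pmax(w^2 - s2, 0) / w^2)
  mu_pad <- drop(crossprod(W, h * w))
  mu <- mu_pad[seq_len(px$m)]
  out <- spectrum(x_mean$mz, mu,
                  meta = c(x_mean$meta, list(kind = "denoised")))
  if (!diagnostics) return(out)
  list(mu_tilde = out,
       diagnostics = list(w = w, sigma2_tilde = s2, h = h,
                          kept_fraction = mean(h > 0)))
}

#' Squared-error distance between two spectra on one grid
#'
#' Sum over the grid of the squared intensity difference — the empirical
#' squared-error norm used to compare an estimate of the underlying signal
#' against a known truth. Averaging over simulation replicates (done by the
#' caller) gives the Monte-Carlo mean squared error of the estimator.
#'
#' @param estimate,truth [spectrum()] objects on identical grids.
#' @return A scalar, `sum((estimate - truth)^2)`.
#' @export
spectrum_mse <- function(estimate, truth) {
  stopifnot(inherits(estimate, "spectrum"), inherits(truth, "spectrum"))
  if (length(estimate$mz) != length(truth$mz) ||
      any(estimate$mz != truth$mz))
    stop("spectrum_mse requires identical grids", call. = FALSE)
  sum((estimate$intensity - truth$intensity)^2)
}
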