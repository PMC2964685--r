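#' Pointwise moments of a replicate spectrum set
#'
#' For each grid point of a set of repeated matrix-only (buffer) spectra,
#' computes the sample mean and the unbiased (n-1 denominator) sample
#' variance of intensity across the replicates. Across-spectrum readings at
#' a fixed mass point are treated as approximately i.i.d. draws from the
#' detector's response distribution at that mean intensity; the resulting
#' (mean, variance) scatter is the detector response curve that
#' [fit_qvf()] summarizes.
#'
#' @param buffer a [spectrum_set()] of replicate buffer spectra, `n >= 3`.
#' @param window optional `c(lo, hi)` mass window in Da applied before
#'   computing moments (e.g. `c(3000, 30000)` for the mass-focused region).
#' @return An object of class `"moment_curve"`: list with `mz`, `mean`,
#'   `variance`, `n` and `window`.
#' @export
pointwise_moments <- function(buffer, window = NULL) {
  stopifnot(inherits(buffer, "spectrum_set"))
  if (buffer$n < 3L)
    stop("pointwise variance needs at least 3 replicate spectra",
         call. = FALSE)
  if (!is.null(window))
    buffer <- restrict_window(buffer, window[1], window[2])
  mu <- rowMeans(buffer$intensities)
  va <- rowSums((buffer$intensities - mu)^2) / (buffer$n - 1L)
  structure(list(mz = buffer$mz, mean = mu, variance = va, n = buffer$n,
                 window = if (is.null(window)) range(buffer$mz) else window),
            class = "moment_curve")
}

#' Quadratic variance function parameters
#'
#' Container for the detector noise model V(mu) = v0 + v1*mu + v2*mu^2.
#' The intercept v0 has intensity-squared units (additive electronic noise
#' floor), v1 has intensity units (Poisson-like counting term), and v2 is
#' dimensionless. Validity requires V > 0 over the intensity range the
#' model will be evaluated on, and 1 + v2 > 0 (the divisor of the
#' coefficient-variance propagation in the denoiser).
#'
#' @param v0,v1,v2 coefficients of the quadratic variance function.
#' @param mu_range intensity range over which positivity of V is checked;
#'   `NULL` skips the range check (positivity at evaluation time is still
#'   the caller's concern).
#' @param fit_diagnostics optional list of fit diagnostics.
#' @return An object of class `"qvf_params"`.
#' @export
qvf_params <- function(v0, v1, v2, mu_range = NULL, fit_diagnostics = NULL) {
  if (!is.finite(v0) || !is.finite(v1) || !is.finite(v2))
    stop("QVF coefficients must be finite", call. = FALSE)
  if (1 + v2 <= 0)
    stop(sprintf("QVF requires 1 + v2 > 0 (got v2 = %g)", v2), call. = FALSE)
  p <- structure(list(v0 = v0, v1 = v1, v2 = v2,
                      fit_diagnostics = fit_diagnostics),
                 class = "qvf_params")
  if (!is.null(mu_range)) {
    bad <- qvf_min_violation(p, mu_range[1], mu_range[2])
    if (!is.null(bad))
      stop(sprintf("fitted V(mu) is not positive on the observed range: V(%g) = %g",
                   bad$mu, bad$value), call. = FALSE)
  }
  p
}

# Minimum of the quadratic on [lo, hi]: at an endpoint or, when v2 > 0, at
# the vertex -v1/(2 v2) if it lies inside. Returns NULL if min > 0.
qvf_min_violation <- function(p, lo, hi) {
  cand <- c(lo, hi)
  if (p$v2 > 0) {
    vertex <- -p$v1 / (2 * p$v2)
    if (vertex > lo && vertex < hi) cand <- c(cand, vertex)
  }
  vals <- p$v0 + p$v1 * cand + p$v2 * cand^2
  k <- which.min(vals)
  if (vals[k] <= 0) list(mu = cand[k], value = vals[k]) else NULL
}

#' @export
print.qvf_params <- function(x, ...) {
  cat(sprintf("<qvf_params> V(mu) = %.6g + %.6g*mu + %.6g*mu^2\n",
              x$v0, x$v1, x$v2))
  if (!is.null(x$fit_diagnostics))
    cat(sprintf("  fit: R^2 = %.4f on %d points\n",
                x$fit_diagnostics$r_squared, x$fit_diagnostics$n_points))
  invisible(x)
}

#' Fit the quadratic variance function to a moment curve
#'
#' Regresses pointwise sample variance on (1, mean, mean^2). Every grid
#' point contributes one fit point; no binning or aggregation of the
#' scatter is applied. The default criterion is ordinary least squares; an
#' optional weighted variant downweights large sample variances (weights
#' proportional to 1/variance^2), reflecting that the sampling error of a
#' sample variance scales with its magnitude.
#'
#' Individually negative coefficients are permitted — the model constrains
#' only V itself, which must be positive over the observed mean range, and
#' 1 + v2 > 0.
#'
#' @param moments a `"moment_curve"` from [pointwise_moments()].
#' @param weighted logical; use 1/variance^2 weights (default `FALSE`).
#' @return A [qvf_params()] with fit diagnostics (`r_squared`, residual
#'   quantiles, `n_points`).
#' @export
fit_qvf <- function(moments, weighted = FALSE) {
  stopifnot(inherits(moments, "moment_curve"))
  mu <- moments$mean
  va <- moments$variance
  if (length(unique(mu)) < 3L)
    stop("QVF fit needs at least 3 distinct mean values", call. = FALSE)
  df <- data.frame(va = va, mu = mu)
  if (weighted) {
    w <- 1 / pmax(va, .Machine$double.eps)^2
    fit <- stats::lm(va ~ mu + I(mu^2), data = df, weights = w)
  } else {
    fit <- stats::lm(va ~ mu + I(mu^2), data = df)
  }
  cf <- unname(stats::coef(fit))
  res <- stats::residuals(fit)
  tss <- sum((va - mean(va))^2)
  diag <- list(
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    residual_quantiles = stats::quantile(res, c(0, .25, .5, .75, 1),
                                         names = FALSE),
    n_points = length(va),
    weighted = weighted
  )
  qvf_params(cf[1], cf[2], cf[3], mu_range = range(mu),
             fit_diagnostics = diag)
}

#' Evaluate the quadratic variance function
#'
#' @param p a [qvf_params()].
#' @param mu numeric vector of mean intensities.
#' @return `v0 + v1*mu + v2*mu^2`, elementwise.
#' @export
variance_at <- function(p, mu) {
  stopifnot(inherits(p, "qvf_params"))
  p$v0 + p$v1 * mu + p$v2 * mu^2
}

#' Evaluate the clamped variance function
#'
#' Returns `max(V(mu), v0)` elementwise. The clamp keeps the modeled noise
#' from being underestimated in low-signal regions, where the raw quadratic
#' can dip below the electronic noise floor v0; the denoiser uses this
#' variant when propagating variances into the wavelet coefficient domain.
#'
#' @inheritParams variance_at
#' @return Elementwise `pmax(V(mu), v0)`.
#' @export
variance_clamped <- function(p, mu) {
  pmax(variance_at(p, mu), p$v0)
}

#' Serialize / deserialize QVF parameters as JSON
#'
#' @param p a [qvf_params()].
#' @param path output (input) file path.
#' @param window_da optional mass window recorded alongside the fit.
#' @param n_spectra optional replicate count recorded alongside the fit.
#' @return `write_qvf` returns `path` invisibly; `read_qvf` returns a
#'   [qvf_params()].
#' @export
write_qvf <- function(p, path, window_da = NULL, n_spectra = NULL) {
  stopifnot(inherits(p, "qvf_params"))
  obj <- list(v0 = p$v0, v1 = p$v1, v2 = p$v2)
  if (!is.null(window_da)) obj$window_da <- window_da
  if (!is.null(n_spectra)) obj$n_spectra <- n_spectra
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qvf
#' @export
read_qvf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("v0", "v1", "v2"))
    if (is.null(obj[[f]]))
      stop(sprintf("QVF JSON missing field '%s'", f), call. = FALSE)
  qvf_params(obj$v0, obj$v1, obj$v2)
}
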