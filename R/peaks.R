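# Combined baseline removal and peak detection.
#
# The denoised mean spectrum is modeled as protein signal s(t) — a sparse
# sum of truncated Gaussian peaks — riding on a slowly varying matrix-ion
# baseline b(t). Because s(t) is mostly zero, the local minima of the
# denoised spectrum can be assumed to touch the baseline, so baseline
# estimation reduces to interpolating through those minima; the local
# maxima are the peak candidates. Both steps therefore come from one
# extrema scan, replacing the usual separate baseline-subtraction and
# peak-picking passes.

#' Interior local extrema of a spectrum
#'
#' One-pass scan for strict interior local minima and maxima. A plateau (a
#' run of equal values flanked on both sides by strictly lower values, or
#' strictly higher values) is reported as a single maximum (minimum) at the
#' run's center index. Grid endpoints are never reported. Between two
#' consecutive reported maxima there is exactly one reported minimum, and
#' vice versa.
#'
#' @param mu_tilde a [spectrum()] with at least 3 points.
#' @return List with integer index vectors `minima` and `maxima` (either
#'   may be empty).
#' @export
find_extrema <- function(mu_tilde) {
  stopifnot(inherits(mu_tilde, "spectrum"))
  y <- mu_tilde$intensity
  m <- length(y)
  if (m < 3L) stop("extrema scan needs at least 3 points", call. = FALSE)
  # collapse plateaus: runs of equal consecutive values
  r <- rle(y)
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  minima <- integer(0)
  maxima <- integer(0)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      center <- (starts[j] + ends[j]) %/% 2L
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        maxima <- c(maxima, center)
      else if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L])
        minima <- c(minima, center)
    }
  }
  list(minima = minima, maxima = maxima)
}

#' Baseline through the local minima
#'
#' Fits a monotonicity-preserving piecewise cubic Hermite interpolant
#' (Fritsch--Carlson) through the local minima of the denoised spectrum and
#' evaluates it on the full grid. The interpolant passes through every knot
#' exactly and never overshoots between adjacent knots, which keeps the
#' estimated baseline from dipping below or bulging above the envelope the
#' minima trace out. Beyond the first/last minimum the baseline continues
#' as a constant at the nearest knot's value. With fewer than two minima
#' there is nothing to interpolate and the baseline degenerates to the
#' constant `min(mu_tilde)` (with a warning).
#'
#' @param mu_tilde a [spectrum()], typically the output of
#'   [shrink_spectrum()].
#' @param minima integer indices of the local minima (from
#'   [find_extrema()]).
#' @return An object of class `"baseline_model"`: list with `knots_idx`,
#'   `knots_mz`, `knots_value` and `values` (baseline on the full grid).
#' @export
estimate_baseline <- function(mu_tilde, minima) {
  stopifnot(inherits(mu_tilde, "spectrum"))
  mz <- mu_tilde$mz
  y <- mu_tilde$intensity
  if (length(minima) < 2L) {
    warning("fewer than 2 local minima; using constant baseline min(mu_tilde)",
            call. = FALSE)
    b <- rep(min(y), length(y))
    return(structure(list(knots_idx = minima, knots_mz = mz[minima],
                          knots_value = y[minima], values = b),
                     class = "baseline_model"))
  }
  minima <- sort(unique(as.integer(minima)))
  kx <- mz[minima]
  ky <- y[minima]
  b <- numeric(length(mz))
  inside <- mz >= kx[1] & mz <= kx[length(kx)]
  # shape-preserving piecewise cubic Hermite (Fritsch-Carlson slopes);
  # with exactly two knots the Hermite segment with secant end slopes is
  # the chord itself
  b[inside] <- if (length(kx) == 2L)
    stats::approx(kx, ky, xout = mz[inside])$y
  else signal::pchip(kx, ky, mz[inside])
  b[mz < kx[1]] <- ky[1]
  b[mz > kx[length(kx)]] <- ky[length(ky)]
  structure(list(knots_idx = minima, knots_mz = kx, knots_value = ky,
                 values = b),
            class = "baseline_model")
}

#' Detect and quantify peaks above the baseline
#'
#' Produces one peak per interior local maximum of the denoised spectrum.
#' Height is the spectrum minus the baseline at the apex; area is the
#' trapezoidal integral of `max(mu_tilde - baseline, 0)` between the
#' flanking local minima (the grid endpoint substitutes where a flank has
#' no minimum). Maxima whose apex does not rise above the baseline are kept
#' with height/area 0 — discarding them is the threshold's job, so that the
#' threshold sweep alone determines the operating point.
#'
#' @param mu_tilde a [spectrum()].
#' @param baseline a `"baseline_model"` from [estimate_baseline()].
#' @param maxima integer indices of local maxima (from [find_extrema()]).
#' @return An object of class `"peak_list"`: a data.frame with columns
#'   `mz_apex`, `height`, `area`, `left_min`, `right_min` (flanking m/z),
#'   sorted by `mz_apex`.
#' @export
detect_peaks <- function(mu_tilde, baseline, maxima) {
  stopifnot(inherits(mu_tilde, "spectrum"),
            inherits(baseline, "baseline_model"))
  mz <- mu_tilde$mz
  y <- mu_tilde$intensity
  b <- baseline$values
  m <- length(mz)
  maxima <- sort(unique(as.integer(maxima)))
  minima <- baseline$knots_idx
  excess <- pmax(y - b, 0)
  peaks <- data.frame(mz_apex = numeric(0), height = numeric(0),
                      area = numeric(0), left_min = numeric(0),
                      right_min = numeric(0))
  for (apex in maxima) {
    lo <- minima[minima < apex]
    hi <- minima[minima > apex]
    li <- if (length(lo)) max(lo) else 1L
    ri <- if (length(hi)) min(hi) else m
    seg <- li:ri
    area <- if (length(seg) >= 2L)
      sum(diff(mz[seg]) * (excess[seg][-length(seg)] + excess[seg][-1]) / 2)
    else 0
    height <- max(y[apex] - b[apex], 0)
    if (height == 0) area <- 0
    peaks <- rbind(peaks, data.frame(
      mz_apex = mz[apex], height = height, area = area,
      left_min = mz[li], right_min = mz[ri]))
  }
  peaks <- peaks[order(peaks$mz_apex), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_list", "data.frame"))
}

#' Threshold a peak list by area
#'
#' Retains the peaks with `area > area_threshold`. Larger thresholds give
#' nested subsets, which is what makes the operating-characteristic sweep
#' well defined.
#'
#' @param pl a `"peak_list"`.
#' @param area_threshold nonnegative scalar.
#' @return A `"peak_list"` containing the surviving peaks.
#' @export
threshold_peaks <- function(pl, area_threshold) {
  stopifnot(inherits(pl, "peak_list"))
  if (area_threshold < 0)
    stop("area_threshold must be >= 0", call. = FALSE)
  out <- pl[pl$area > area_threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"))
}

#' Full peak-calling pass on a denoised spectrum
#'
#' Convenience wrapper: extrema scan, baseline interpolation through the
#' minima, and peak quantification, in one call.
#'
#' @param mu_tilde a [spectrum()].
#' @return List with `peaks` (a `"peak_list"`), `baseline` (a
#'   `"baseline_model"`) and `extrema`.
#' @export
call_peaks <- function(mu_tilde) {
  ex <- find_extrema(mu_tilde)
  bl <- estimate_baseline(mu_tilde, ex$minima)
  pl <- detect_peaks(mu_tilde, bl, ex$maxima)
  list(peaks = pl, baseline = bl, extrema = ex)
}

#' Read/write a peak list as CSV
#'
#' Columns: `mz_apex`, `height`, `area`, `left_min`, `right_min`.
#'
#' @param pl a `"peak_list"`.
#' @param path file path.
#' @return `write_peak_list` returns `path` invisibly; `read_peak_list`
#'   returns a `"peak_list"`.
#' @export
write_peak_list <- function(pl, path) {
  utils::write.csv(as.data.frame(pl), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path)
  need <- c("mz_apex", "height", "area", "left_min", "right_min")
  if (!all(need %in% names(df)))
    stop("peak list CSV must have columns mz_apex, height, area, left_min, right_min",
         call. = FALSE)
  df <- df[order(df$mz_apex), need, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_list", "data.frame"))
}
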