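# Operating-characteristic evaluation of peak predictions against the
# virtual-protein truth. Matching uses relative mass tolerance (0.3% by
# default); FDR = FP/(FP+TP) and TPR = TP/(TP+FN) trace out an operating
# characteristic as the area threshold sweeps; per-dataset curves are
# loess-smoothed onto a common FDR grid, averaged, and summarized by
# normalized partial AUC over the low-FDR windows of interest.

# Common FDR evaluation grid for all curve arithmetic.
OC_FDR_GRID <- seq(0, 1, length.out = 101L)

#' Match predicted m/z values to a truth list
#'
#' A prediction p matches a true protein t when `|p - t| / t <= tol_rel`.
#' Counting is per-truth on one side and per-prediction on the other: TP is
#' the number of true proteins with at least one matching prediction (one
#' prediction may credit several nearby truths); FP is the number of
#' predictions matching no truth at all; FN is the number of unmatched
#' truths. A prediction within tolerance of any truth is never counted as
#' a false positive.
#'
#' @param truth_mz numeric vector of true protein m/z values (Da).
#' @param predicted_mz numeric vector of predicted m/z values (Da).
#' @param tol_rel relative tolerance (default 0.003 = 0.3%).
#' @return An object of class `"match_result"`: list with `tp`, `fp`,
#'   `fn`, `tol_rel`.
#' @export
match_predictions <- function(truth_mz, predicted_mz, tol_rel = 0.003) {
  if (tol_rel <= 0) stop("tol_rel must be > 0", call. = FALSE)
  nt <- length(truth_mz)
  np <- length(predicted_mz)
  if (nt == 0L)
    stop("empty truth list: nothing to match against", call. = FALSE)
  if (np == 0L) {
    res <- list(tp = 0L, fp = 0L, fn = nt, tol_rel = tol_rel)
    return(structure(res, class = "match_result"))
  }
  # nt x np matrix of relative errors, scaled by the truth mass
  rel <- abs(outer(truth_mz, predicted_mz, "-")) /
    matrix(truth_mz, nrow = nt, ncol = np)
  hit <- rel <= tol_rel
  tp <- sum(rowSums(hit) > 0L)
  fp <- sum(colSums(hit) == 0L)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(nt - tp), tol_rel = tol_rel),
            class = "match_result")
}

#' FDR and TPR of a match result
#'
#' FDR = FP/(FP+TP), defined as 0 when no predictions were made (so the
#' empty-prediction end of a threshold sweep anchors the operating
#' characteristic at the origin); TPR = TP/(TP+FN).
#'
#' @param m a `"match_result"`.
#' @return List with `fdr` and `tpr`, both in \[0, 1\].
#' @export
oc_rates <- function(m) {
  stopifnot(inherits(m, "match_result"))
  if (m$tp + m$fn == 0L)
    stop("tp + fn == 0: truth list was empty", call. = FALSE)
  fdr <- if (m$tp + m$fp == 0L) 0 else m$fp / (m$fp + m$tp)
  list(fdr = fdr, tpr = m$tp / (m$tp + m$fn))
}

#' Operating points from an area-threshold sweep
#'
#' For each threshold, keeps the peaks with area above it, matches the
#' surviving apexes against the truth, and records (FDR, TPR). Because
#' thresholded peak lists are nested, TPR is non-increasing along the
#' sweep. The default sweep uses every achievable operating point: 0 plus
#' the sorted unique peak areas themselves.
#'
#' @param mean_peaks a `"peak_list"` from the denoised mean spectrum.
#' @param truth_mz numeric vector of true protein m/z values.
#' @param thresholds ascending numeric vector of area thresholds, or
#'   `NULL` (default) for the achievable sweep.
#' @param tol_rel relative matching tolerance (default 0.003).
#' @return An object of class `"oc_curve"`: list with `points` (data.frame
#'   `threshold`, `tp`, `fp`, `fn`, `fdr`, `tpr`) and `smoothed = NULL`.
#' @export
oc_sweep <- function(mean_peaks, truth_mz, thresholds = NULL,
                     tol_rel = 0.003) {
  stopifnot(inherits(mean_peaks, "peak_list"))
  if (is.null(thresholds))
    thresholds <- c(0, sort(unique(mean_peaks$area)))
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending", call. = FALSE)
  rows <- lapply(thresholds, function(th) {
    kept <- threshold_peaks(mean_peaks, th)
    m <- match_predictions(truth_mz, kept$mz_apex, tol_rel)
    r <- oc_rates(m)
    data.frame(threshold = th, tp = m$tp, fp = m$fp, fn = m$fn,
               fdr = r$fdr, tpr = r$tpr)
  })
  structure(list(points = do.call(rbind, rows), smoothed = NULL,
                 dataset_id = NA_character_),
            class = "oc_curve")
}

#' Loess-smooth an operating characteristic onto the common FDR grid
#'
#' Fits a locally weighted regression of TPR on FDR through the operating
#' points and evaluates it on a fixed 101-point FDR grid over \[0, 1\],
#' clipping to \[0, 1\]. Outside the range of observed FDR values the
#' nearest fitted value is carried constant (a threshold sweep rarely
#' reaches FDR = 1). With fewer than 3 distinct points — too few for any
#' local fit — the smoother falls back to monotone step interpolation with
#' a warning.
#'
#' @param curve an `"oc_curve"` from [oc_sweep()], or a data.frame with
#'   `fdr` and `tpr` columns.
#' @param span loess span (default 0.5).
#' @return The `"oc_curve"` with `smoothed` set to a data.frame
#'   (`fdr`, `tpr`) on the common grid (a bare data.frame input returns
#'   the smoothed data.frame directly).
#' @export
smooth_oc_curve <- function(curve, span = 0.5) {
  pts <- if (inherits(curve, "oc_curve")) curve$points else curve
  stopifnot(all(c("fdr", "tpr") %in% names(pts)))
  grid <- OC_FDR_GRID
  dup <- !duplicated(pts[, c("fdr", "tpr")])
  upts <- pts[dup, , drop = FALSE]
  n_distinct <- nrow(unique(upts[, c("fdr", "tpr")]))
  smoothed <- NULL
  if (n_distinct >= 3L && length(unique(upts$fdr)) >= 3L) {
    fit <- tryCatch(
      stats::loess(tpr ~ fdr, data = upts, span = span,
                   degree = 1, family = "gaussian",
                   control = stats::loess.control(surface = "direct")),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      inside <- grid >= min(upts$fdr) & grid <= max(upts$fdr)
      yhat <- rep(NA_real_, length(grid))
      yhat[inside] <- stats::predict(fit, data.frame(fdr = grid[inside]))
      smoothed <- yhat
    }
  }
  if (is.null(smoothed)) {
    if (n_distinct < 3L)
      warning("fewer than 3 distinct operating points; using step interpolation",
              call. = FALSE)
    o <- order(pts$fdr, pts$tpr)
    sf <- stats::approxfun(pts$fdr[o], pts$tpr[o], method = "constant",
                           rule = 2, ties = max, f = 0)
    smoothed <- sf(grid)
  } else {
    # constant continuation outside the observed FDR range
    first <- which(!is.na(smoothed))[1]
    last <- max(which(!is.na(smoothed)))
    smoothed[seq_len(first - 1L)] <- smoothed[first]
    if (last < length(smoothed))
      smoothed[(last + 1L):length(smoothed)] <- smoothed[last]
  }
  sm <- data.frame(fdr = grid, tpr = pmin(pmax(smoothed, 0), 1))
  if (inherits(curve, "oc_curve")) {
    curve$smoothed <- sm
    curve
  } else sm
}

#' Aggregate smoothed operating characteristics across datasets
#'
#' Pointwise mean and 25%/75% quantile curves across datasets, evaluated
#' on the common FDR grid. The mean curve is what the partial-AUC scores
#' summarize; the quartile curves show across-dataset spread.
#'
#' @param curves list of `"oc_curve"` objects with `smoothed` filled in
#'   (see [smooth_oc_curve()]), or list of smoothed data.frames.
#' @return List with data.frames `mean`, `q25`, `q75` (each `fdr`, `tpr`).
#' @export
aggregate_oc_curves <- function(curves) {
  if (length(curves) < 1L) stop("need at least one curve", call. = FALSE)
  mats <- vapply(curves, function(cv) {
    sm <- if (inherits(cv, "oc_curve")) cv$smoothed else cv
    if (is.null(sm))
      stop("curve has no smoothed component; run smooth_oc_curve first",
           call. = FALSE)
    if (nrow(sm) != length(OC_FDR_GRID) || any(sm$fdr != OC_FDR_GRID))
      stop("curves must share the common FDR grid", call. = FALSE)
    sm$tpr
  }, numeric(length(OC_FDR_GRID)))
  mats <- matrix(mats, nrow = length(OC_FDR_GRID))
  list(mean = data.frame(fdr = OC_FDR_GRID, tpr = rowMeans(mats)),
       q25 = data.frame(fdr = OC_FDR_GRID,
                        tpr = apply(mats, 1, stats::quantile, probs = 0.25)),
       q75 = data.frame(fdr = OC_FDR_GRID,
                        tpr = apply(mats, 1, stats::quantile, probs = 0.75)))
}

#' Normalized partial area under an operating characteristic
#'
#' Trapezoidal area under the TPR-vs-FDR curve over \[0, fdr_max\],
#' normalized so a perfect curve (TPR = 1 everywhere) scores exactly 100:
#' the raw area is divided by `fdr_max` and multiplied by 100. The
#' conventional summaries are `fdr_max = 0.25` ("PAUC25") and
#' `fdr_max = 0.5` ("PAUC").
#'
#' @param curve data.frame with `fdr` and `tpr` columns (typically the
#'   mean curve from [aggregate_oc_curves()]).
#' @param fdr_max upper FDR limit, in (0, 1].
#' @return Score on the 0--100 scale.
#' @export
pauc <- function(curve, fdr_max) {
  stopifnot(is.data.frame(curve), all(c("fdr", "tpr") %in% names(curve)))
  if (!(fdr_max > 0 && fdr_max <= 1))
    stop("fdr_max must be in (0, 1]", call. = FALSE)
  o <- order(curve$fdr)
  x <- curve$fdr[o]
  y <- curve$tpr[o]
  # clip the integration domain to [0, fdr_max], interpolating the cut
  if (fdr_max < max(x)) {
    ycut <- stats::approx(x, y, xout = fdr_max, ties = mean)$y
    keep <- x < fdr_max
    x <- c(x[keep], fdr_max)
    y <- c(y[keep], ycut)
  }
  if (length(x) < 2L) stop("curve needs at least 2 points below fdr_max",
                           call. = FALSE)
  area <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  100 * area / fdr_max
}

#' Operating-characteristic scores for a collection of curves
#'
#' Smooths each dataset's operating points, aggregates, and computes the
#' normalized partial-AUC pair. Per-dataset spread is reported as the
#' standard deviation of per-dataset scores.
#'
#' @param curves list of `"oc_curve"` objects (smoothed or not).
#' @param span loess span passed to [smooth_oc_curve()].
#' @return List with `pauc25`, `pauc` (both on the mean curve),
#'   `per_dataset` (data.frame of per-dataset scores) and `aggregated`
#'   (output of [aggregate_oc_curves()]).
#' @export
oc_scores <- function(curves, span = 0.5) {
  curves <- lapply(curves, function(cv)
    if (inherits(cv, "oc_curve") && is.null(cv$smoothed))
      smooth_oc_curve(cv, span) else cv)
  agg <- aggregate_oc_curves(curves)
  per <- data.frame(
    pauc25 = vapply(curves, function(cv)
      pauc(if (inherits(cv, "oc_curve")) cv$smoothed else cv, 0.25),
      numeric(1)),
    pauc = vapply(curves, function(cv)
      pauc(if (inherits(cv, "oc_curve")) cv$smoothed else cv, 0.5),
      numeric(1)))
  list(pauc25 = pauc(agg$mean, 0.25),
       pauc = pauc(agg$mean, 0.5),
       per_dataset = per,
       per_dataset_sd = c(pauc25 = stats::sd(per$pauc25),
                          pauc = stats::sd(per$pauc)),
       aggregated = agg)
}
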