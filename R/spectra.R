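#' Construct a single mass spectrum
#'
#' A spectrum is one intensity series observed on a discrete mass (or,
#' equivalently, time-of-flight) grid. The grid must be strictly increasing;
#' intensities must be finite but may be negative, since raw SELDI exports
#' occasionally contain small negative readings after vendor-side processing.
#'
#' @param mz numeric vector of mass-to-charge values in Da, strictly
#'   increasing, length at least 2.
#' @param intensity numeric vector of detector intensities (arbitrary
#'   units), same length as `mz`.
#' @param meta named list of free-form annotations (instrument settings,
#'   dataset id, provenance).
#' @return An object of class `"spectrum"`: a list with elements `mz`,
#'   `intensity` and `meta`.
#' @export
#' @examples
#' s <- spectrum(c(3000, 3001, 3002), c(1.2, 1.5, 1.1))
#' length(s$mz)
spectrum <- function(mz, intensity, meta = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (length(mz) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(mz) || any(!is.finite(mz)))
    stop("mz values must be finite", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity values must be finite", call. = FALSE)
  if (any(diff(mz) <= 0))
    stop("mz grid must be strictly increasing", call. = FALSE)
  structure(list(mz = mz, intensity = intensity, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, m/z %.1f..%.1f Da\n",
              length(x$mz), x$mz[1], x$mz[length(x$mz)]))
  invisible(x)
}

#' Construct a set of aligned spectra
#'
#' A spectrum set holds n replicate spectra from one homogeneous condition
#' (for example, repeated buffer-only acquisitions under fixed machine
#' settings) that share one identical m/z grid. Intensities are stored as an
#' m x n matrix, one column per spectrum.
#'
#' @param mz common m/z grid (Da), strictly increasing.
#' @param intensities numeric matrix, `length(mz)` rows and one column per
#'   spectrum; or a list of equal-length intensity vectors.
#' @param condition_label string naming the condition the replicates share.
#' @return An object of class `"spectrum_set"` with elements `mz`,
#'   `intensities` (m x n matrix), `n` and `condition_label`.
#' @export
spectrum_set <- function(mz, intensities, condition_label = "") {
  if (is.list(intensities))
    intensities <- do.call(cbind, intensities)
  intensities <- as.matrix(intensities)
  mz <- as.numeric(mz)
  if (nrow(intensities) != length(mz))
    stop("intensity matrix must have one row per grid point", call. = FALSE)
  if (ncol(intensities) < 1L)
    stop("a spectrum set needs at least one spectrum", call. = FALSE)
  if (length(mz) < 2L || any(diff(mz) <= 0))
    stop("mz grid must be strictly increasing with at least 2 points",
         call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensity values must be finite", call. = FALSE)
  structure(list(mz = mz, intensities = intensities,
                 n = ncol(intensities),
                 condition_label = as.character(condition_label)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> n = %d spectra on %d-point grid (%s)\n",
              x$n, length(x$mz),
              if (nzchar(x$condition_label)) x$condition_label else "unlabeled"))
  invisible(x)
}

#' Extract one member spectrum from a set
#'
#' @param s a `spectrum_set`.
#' @param i column index.
#' @return A `spectrum`.
#' @export
set_member <- function(s, i) {
  stopifnot(inherits(s, "spectrum_set"))
  spectrum(s$mz, s$intensities[, i],
           meta = list(condition = s$condition_label, member = i))
}

# Parse a two-column delimited text file (comma or tab autodetected).
# Lines starting with '#' or whose first token is non-numeric are treated as
# headers/comments and skipped; the count of skipped lines is reported via
# message() so silent truncation cannot pass unnoticed.
parse_two_column <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("'%s': empty file", path), call. = FALSE)
  sep <- if (sum(grepl("\t", lines)) >= sum(grepl(",", lines))) "\t" else ","
  mz <- numeric(length(lines))
  intensity <- numeric(length(lines))
  keep <- logical(length(lines))
  skipped <- 0L
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (startsWith(ln, "#")) { skipped <- skipped + 1L; next }
    fields <- strsplit(ln, sep, fixed = TRUE)[[1]]
    fields <- trimws(fields)
    v1 <- suppressWarnings(as.numeric(fields[1]))
    if (is.na(v1)) { skipped <- skipped + 1L; next }
    if (length(fields) < 2L)
      stop(sprintf("'%s' line %d: expected two columns, found %d",
                   path, k, length(fields)), call. = FALSE)
    v2 <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(v2))
      stop(sprintf("'%s' line %d: malformed intensity value '%s'",
                   path, k, fields[2]), call. = FALSE)
    mz[k] <- v1; intensity[k] <- v2; keep[k] <- TRUE
  }
  if (skipped > 0L)
    message(sprintf("read_spectrum: skipped %d header/comment line(s) in '%s'",
                    skipped, basename(path)))
  if (sum(keep) < 2L)
    stop(sprintf("'%s': fewer than 2 data points", path), call. = FALSE)
  list(mz = mz[keep], intensity = intensity[keep])
}

#' Read a spectrum from disk
#'
#' The native interchange format is two-column delimited text: column 1 =
#' m/z (Da), column 2 = intensity. Comma or tab separators are autodetected
#' and header/comment lines are skipped with a logged count. A non-monotone
#' m/z grid is an error — the reader never silently reorders points. mzML
#' input is supported read-only when the `mzR` package is available.
#'
#' @param path file path.
#' @param dialect `"two-column-delimited"` (default) or `"mzml"`.
#' @param scan for mzML input, which scan to extract (default 1).
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("two-column-delimited", "mzml"),
                          scan = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (dialect == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("mzML support requires the 'mzR' package", call. = FALSE)
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    pk <- mzR::peaks(handle, scan)
    return(spectrum(pk[, 1], pk[, 2], meta = list(source = path)))
  }
  parsed <- parse_two_column(path)
  if (any(diff(parsed$mz) <= 0))
    stop(sprintf("'%s': m/z grid is not strictly increasing", path),
         call. = FALSE)
  spectrum(parsed$mz, parsed$intensity, meta = list(source = path))
}

#' Write a spectrum as two-column delimited text
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @param digits significant digits to print (default 15, enough for a
#'   float round trip at the precision downstream arithmetic uses).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",", digits = 15L) {
  stopifnot(inherits(s, "spectrum"))
  lines <- paste(formatC(s$mz, digits = digits, format = "g"),
                 formatC(s$intensity, digits = digits, format = "g"),
                 sep = sep)
  writeLines(lines, path)
  invisible(path)
}

#' Read a set of aligned spectra from disk
#'
#' All files must share an identical m/z grid: downstream pointwise moments
#' and the mean spectrum assume exact alignment, and this reader enforces it
#' rather than resampling. A tolerance of 0 (the default) demands exact
#' equality; a small absolute tolerance can be allowed for exports that
#' differ in the last printed digit, in which case the first file's grid is
#' used verbatim.
#'
#' @param paths character vector of file paths (two-column delimited text).
#' @param condition_label label for the shared condition.
#' @param grid_tol absolute tolerance for grid identity (default 0 = exact).
#' @return A [spectrum_set()].
#' @export
read_spectrum_set <- function(paths, condition_label = "", grid_tol = 0) {
  if (length(paths) < 1L)
    stop("need at least one path", call. = FALSE)
  first <- read_spectrum(paths[[1]])
  m <- length(first$mz)
  mat <- matrix(NA_real_, nrow = m, ncol = length(paths))
  mat[, 1] <- first$intensity
  if (length(paths) > 1L) {
    for (k in 2:length(paths)) {
      s <- read_spectrum(paths[[k]])
      if (length(s$mz) != m || any(abs(s$mz - first$mz) > grid_tol))
        stop(sprintf("grid mismatch: '%s' does not share the grid of '%s'",
                     paths[[k]], paths[[1]]), call. = FALSE)
      mat[, k] <- s$intensity
    }
  }
  spectrum_set(first$mz, mat, condition_label = condition_label)
}

#' Restrict a spectrum or set to a mass window
#'
#' Retains exactly the grid points with `lo <= mz <= hi`, preserving order.
#' Used to cut spectra down to the mass-focused region (3--30 kDa in the
#' instrument settings this package models) before any statistics are
#' computed, since detector behavior outside the focused window — notably
#' saturation near the baseline maximum around 2--2.5 kDa — is not covered
#' by the quadratic variance model.
#'
#' @param s a [spectrum()] or [spectrum_set()].
#' @param lo,hi window bounds in Da, `lo < hi`.
#' @return Object of the same class restricted to the window.
#' @export
restrict_window <- function(s, lo, hi) {
  if (!(lo < hi)) stop("window requires lo < hi", call. = FALSE)
  keep <- s$mz >= lo & s$mz <= hi
  if (!any(keep))
    stop(sprintf("window [%g, %g] Da contains no grid points", lo, hi),
         call. = FALSE)
  if (inherits(s, "spectrum")) {
    spectrum(s$mz[keep], s$intensity[keep], meta = s$meta)
  } else if (inherits(s, "spectrum_set")) {
    spectrum_set(s$mz[keep], s$intensities[keep, , drop = FALSE],
                 condition_label = s$condition_label)
  } else {
    stop("restrict_window expects a spectrum or spectrum_set", call. = FALSE)
  }
}
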