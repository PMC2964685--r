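# Shared fixture builders. Everything is generated in code at test time;
# temp files are cleaned up by withr-style on.exit in the tests that make
# them.

# Write a two-column delimited spectrum file and return its path.
write_spectrum_file <- function(mz, intensity, dir = tempdir(),
                                sep = ",", header = NULL) {
  path <- tempfile("spec_", tmpdir = dir, fileext = ".csv")
  lines <- paste(mz, intensity, sep = sep)
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path)
  path
}

# A small spectrum set with identical grids: intensities[i, k] for grid
# point i of spectrum k.
make_set <- function(mz, intensities, label = "test") {
  spectrum_set(mz, intensities, condition_label = label)
}

# Uniform grid helper.
ugrid <- function(lo, hi, m) seq(lo, hi, length.out = m)

# Brute-force O(m^2) extremum scan used as the oracle for find_extrema on
# plateau-free signals: index i is a maximum iff y[i] is strictly greater
# than both neighbors, a minimum iff strictly smaller.
brute_extrema <- function(y) {
  m <- length(y)
  minima <- integer(0); maxima <- integer(0)
  for (i in 2:(m - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) maxima <- c(maxima, i)
    if (y[i] < y[i - 1] && y[i] < y[i + 1]) minima <- c(minima, i)
  }
  list(minima = minima, maxima = maxima)
}

# Brute-force matcher oracle: per-truth and per-prediction double loop.
brute_match <- function(truth, pred, tol) {
  tp <- 0L
  for (t in truth) {
    ok <- FALSE
    for (p in pred) if (abs(p - t) / t <= tol) { ok <- TRUE; break }
    if (ok) tp <- tp + 1L
  }
  fp <- 0L
  for (p in pred) {
    ok <- FALSE
    for (t in truth) if (abs(p - t) / t <= tol) { ok <- TRUE; break }
    if (!ok) fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = length(truth) - tp)
}

# Direct classical constant-variance term-by-term shrinkage (the
# homoscedastic special case), written against the low-level transform
# functions rather than shrink_spectrum.
classical_shrink <- function(x, c_var, basis = "sym8") {
  m <- length(x)
  stopifnot(bitwAnd(m, m - 1L) == 0L)
  d <- wavelet_design(basis)
  lev <- seldiprep:::resolve_levels(m, d)
  w <- seldiprep:::dwt_forward(x, basis, lev)
  h <- ifelse(w == 0, 0, pmax(w^2 - c_var, 0) / w^2)
  seldiprep:::idwt_forward(h * w, basis, lev)
}
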