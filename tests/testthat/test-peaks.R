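test_that("extrema scan matches a brute-force oracle and alternates", {
  set.seed(20)
  for (r in 1:20) {
    y <- rnorm(50)
    s <- spectrum(ugrid(1, 2, 50), y)
    got <- find_extrema(s)
    oracle <- brute_extrema(y)
    expect_identical(got$minima, oracle$minima)
    expect_identical(got$maxima, oracle$maxima)
    # alternation: merged sorted extrema strictly alternate in type
    typ <- c(rep("min", length(got$minima)), rep("max", length(got$maxima)))
    typ <- typ[order(c(got$minima, got$maxima))]
    if (length(typ) > 1)
      expect_true(all(typ[-1] != typ[-length(typ)]))
  }
})

test_that("extrema scan handles monotone signals, pulses and plateaus", {
  m <- 20
  mono <- spectrum(ugrid(1, 2, m), seq_len(m))
  ex <- find_extrema(mono)
  expect_length(ex$minima, 0)
  expect_length(ex$maxima, 0)
  # triangle pulse on flat zero: apex is the single maximum
  y <- c(rep(0, 5), 1, 2, 3, 2, 1, rep(0, 5))
  ex2 <- find_extrema(spectrum(ugrid(1, 2, length(y)), y))
  expect_identical(ex2$maxima, 8L)
  # a 3-wide plateau maximum reports its center index
  yp <- c(0, 1, 2, 2, 2, 1, 0, 1, 0)
  ex3 <- find_extrema(spectrum(ugrid(1, 2, 9), yp))
  expect_identical(ex3$maxima, c(4L, 8L))
  expect_identical(ex3$minima, 7L)
})

test_that("baseline interpolant hits every knot and stays in range", {
  set.seed(21)
  mz <- ugrid(3000, 30000, 200)
  y <- 50 * exp(-(mz - 3000) / 9000) + rnorm(200, 0, 2)
  s <- spectrum(mz, y)
  minima <- find_extrema(s)$minima
  bl <- estimate_baseline(s, minima)
  expect_equal(bl$values[minima], y[minima], tolerance = 1e-12)
  # monotone-preserving: between adjacent knots the curve stays within the
  # knot values' range (no overshoot)
  for (k in seq_len(length(minima) - 1)) {
    seg <- minima[k]:minima[k + 1]
    lo <- min(y[minima[k]], y[minima[k + 1]])
    hi <- max(y[minima[k]], y[minima[k + 1]])
    expect_true(all(bl$values[seg] >= lo - 1e-9 & bl$values[seg] <= hi + 1e-9))
  }
  # constant continuation beyond the terminal knots
  if (minima[1] > 1)
    expect_true(all(bl$values[seq_len(minima[1] - 1)] == y[minima[1]]))
  last <- minima[length(minima)]
  if (last < length(mz))
    expect_true(all(bl$values[(last + 1):length(mz)] == y[last]))
})

test_that("degenerate baselines fall back as documented", {
  mz <- ugrid(1, 2, 10)
  # strictly increasing: no interior minima -> constant min with warning
  s <- spectrum(mz, 1:10)
  expect_warning(bl <- estimate_baseline(s, integer(0)), "constant baseline")
  expect_equal(bl$values, rep(1, 10))
  # knots all at zero give the zero baseline
  y <- c(0, 1, 0, 2, 0, 3, 0, 4, 0, 1)
  s2 <- spectrum(mz, y)
  mins <- find_extrema(s2)$minima
  bl2 <- estimate_baseline(s2, mins)
  expect_true(all(abs(bl2$values[min(mins):max(mins)]) < 1e-12))
  # two knots: single monotone Hermite segment through both, exactly
  bl3 <- estimate_baseline(s2, c(1L, 10L))
  expect_equal(bl3$values[c(1, 10)], y[c(1, 10)])
})

test_that("baseline on denoised protein-free spectra tracks the spectrum", {
  # zero protein signal: after denoising, mu_tilde is baseline + residual
  # wiggle, and the minima-interpolant should sit close to mu_tilde
  set.seed(22)
  spec <- dataset_spec(m = 512L, seed = 22L)
  grid <- tof_grid(spec)
  bm <- buffer_model(n_spectra = 30L)
  pool <- generate_buffer_pool(bm, grid, seed = 22)
  xbar <- mean_spectrum(restrict_window(pool, 3000, 30000))
  q <- fit_qvf(pointwise_moments(pool, window = c(3000, 30000)))
  mt <- shrink_spectrum(xbar, q, wavelet_design(), n = pool$n)
  bl <- estimate_baseline(mt, find_extrema(mt)$minima)
  rel <- abs(mt$intensity - bl$values) / mean(mt$intensity)
  expect_lt(stats::median(rel), 0.05)
})

test_that("a truncated Gaussian peak is located and quantified correctly", {
  # single kernel a*G(tj, sigma), truncated at 3*sigma, on a linear ramp;
  # the baseline model is anchored at the grid ends where the signal is
  # pure ramp
  m <- 600
  mz <- ugrid(8000, 12000, m)
  a <- 10; tj <- 10000
  sigma <- 40 * diff(mz[1:2]) / 3  # 3*sigma spans ~40 grid steps
  # ramp slope well below the bump's maximum slope a*exp(-1/2)/(sigma^2
  # sqrt(2*pi)) ~ 3e-4, so the apex survives the tilt
  ramp <- 5 + (mz - 8000) * 2e-5
  bump <- ifelse(abs(mz - tj) <= 3 * sigma, a * dnorm(mz, tj, sigma), 0)
  s <- spectrum(mz, ramp + bump)
  bl <- estimate_baseline(s, c(1L, as.integer(m)))
  pl <- detect_peaks(s, bl, find_extrema(s)$maxima)
  expect_equal(nrow(pl), 1)
  expect_lt(abs(pl$mz_apex - tj), 1.5 * diff(mz[1:2]))
  truth_area <- a * (pnorm(3) - pnorm(-3))
  expect_lt(abs(pl$area - truth_area) / truth_area, 0.10)
  expect_gt(pl$height, 0)
})

test_that("two separated Gaussians yield two peaks with areas ordered by abundance", {
  m <- 800
  mz <- ugrid(5000, 25000, m)
  sig <- 300
  k <- function(tj, a) ifelse(abs(mz - tj) <= 3 * sig,
                              a * dnorm(mz, tj, sig), 0)
  y <- k(9000, 20) + k(18000, 5)
  s <- spectrum(mz, y)
  # the flat stretch between the bumps yields a single plateau minimum, so
  # the baseline falls back to the constant 0 with its documented warning
  res <- suppressWarnings(call_peaks(s))
  pk <- res$peaks[res$peaks$area > 0, ]
  expect_equal(nrow(pk), 2)
  expect_gt(pk$area[1], pk$area[2])  # sorted by mz; first has a = 20
  expect_lt(abs(pk$mz_apex[1] - 9000), 2 * diff(mz[1:2]))
  expect_lt(abs(pk$mz_apex[2] - 18000), 2 * diff(mz[1:2]))
})

test_that("zero signal yields no effective peaks", {
  s <- spectrum(ugrid(1, 2, 50), rep(0, 50))
  res <- suppressWarnings(call_peaks(s))
  expect_true(nrow(res$peaks) == 0 || all(res$peaks$height == 0))
})

test_that("area thresholding is nested and monotone", {
  set.seed(23)
  y <- abs(rnorm(300, 2, 1)) + 3 * sin(seq(0, 20, length.out = 300))^2
  s <- spectrum(ugrid(3000, 30000, 300), y)
  res <- call_peaks(s)
  pl <- res$peaks
  expect_error(threshold_peaks(pl, -1), ">= 0")
  # threshold 0 keeps exactly the positive-area peaks
  expect_equal(nrow(threshold_peaks(pl, 0)), sum(pl$area > 0))
  # beyond the max area nothing survives
  expect_equal(nrow(threshold_peaks(pl, max(pl$area) + 1)), 0)
  # 20-threshold sweep: successive prediction sets are nested subsets
  ths <- seq(0, max(pl$area), length.out = 20)
  prev <- threshold_peaks(pl, ths[1])$mz_apex
  for (th in ths[-1]) {
    cur <- threshold_peaks(pl, th)$mz_apex
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("peak list CSV round trips", {
  set.seed(24)
  s <- spectrum(ugrid(3000, 30000, 200), abs(rnorm(200, 5, 2)))
  pl <- call_peaks(s)$peaks
  path <- tempfile(fileext = ".csv")
  write_peak_list(pl, path)
  r <- read_peak_list(path)
  expect_equal(as.data.frame(r), as.data.frame(pl), tolerance = 1e-12)
})
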