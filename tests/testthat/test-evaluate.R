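test_that("matching applies the relative tolerance with per-truth counting", {
  # boundary: 30/10000 is exactly 0.3%
  m1 <- match_predictions(10000, 10030, tol_rel = 0.003)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1L, 0L, 0L))
  # just outside
  m2 <- match_predictions(10000, 10031, tol_rel = 0.003)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))
  # empty predictions
  m3 <- match_predictions(c(5000, 9000), numeric(0))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0L, 0L, 2L))
  # one prediction can credit two nearby truths and is never an FP
  m4 <- match_predictions(c(10000, 10010), 10005, tol_rel = 0.003)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(2L, 0L, 0L))
  expect_error(match_predictions(numeric(0), 1), "empty truth")
  expect_error(match_predictions(10, 10, tol_rel = 0), "tol_rel")
})

test_that("matching agrees with a brute-force oracle on random instances", {
  set.seed(50)
  for (r in 1:200) {
    nt <- sample(1:12, 1)
    np <- sample(0:15, 1)
    truth <- sort(runif(nt, 3000, 30000))
    pred <- runif(np, 3000, 30000)
    tol <- runif(1, 1e-4, 0.02)
    got <- match_predictions(truth, pred, tol)
    want <- brute_match(truth, pred, tol)
    expect_equal(c(got$tp, got$fp, got$fn),
                 c(want$tp, want$fp, want$fn))
  }
})

test_that("matching is tolerance-monotone in tp", {
  set.seed(51)
  truth <- runif(20, 3000, 30000)
  pred <- runif(25, 3000, 30000)
  tols <- sort(runif(10, 1e-4, 0.05))
  tps <- vapply(tols, function(tl) match_predictions(truth, pred, tl)$tp,
                integer(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("rates implement FDR and TPR with the empty-prediction convention", {
  m <- structure(list(tp = 1L, fp = 1L, fn = 13L, tol_rel = 0.003),
                 class = "match_result")
  r <- oc_rates(m)
  expect_equal(r$fdr, 0.5)
  expect_equal(r$tpr, 1 / 14, tolerance = 1e-12)
  # fp = 0 with tp > 0 gives fdr 0
  m2 <- structure(list(tp = 5L, fp = 0L, fn = 2L, tol_rel = 0.003),
                  class = "match_result")
  expect_equal(oc_rates(m2)$fdr, 0)
  # perfect sensitivity
  m3 <- structure(list(tp = 150L, fp = 3L, fn = 0L, tol_rel = 0.003),
                  class = "match_result")
  expect_equal(oc_rates(m3)$tpr, 1)
  # no predictions at all anchors at the origin
  m4 <- structure(list(tp = 0L, fp = 0L, fn = 9L, tol_rel = 0.003),
                  class = "match_result")
  expect_equal(oc_rates(m4)$fdr, 0)
  # empty truth is a configuration bug
  m5 <- structure(list(tp = 0L, fp = 2L, fn = 0L, tol_rel = 0.003),
                  class = "match_result")
  expect_error(oc_rates(m5), "truth")
})

test_that("threshold sweeps give anchored, nested operating points", {
  # perfect predictions at threshold 0
  mz <- ugrid(5000, 25000, 400)
  truth <- c(8000, 12000, 18000)
  y <- rowSums(sapply(truth, function(tj)
    ifelse(abs(mz - tj) <= 900, 20 * dnorm(mz, tj, 300), 0)))
  pl <- call_peaks(spectrum(mz, y))$peaks
  cv <- oc_sweep(pl, truth, thresholds = 0)
  expect_equal(nrow(cv$points), 1)
  expect_equal(cv$points$tpr, 1)
  expect_equal(cv$points$fdr, 0)
  # threshold beyond the max area: tp = 0, both rates 0 by policy
  cv2 <- oc_sweep(pl, truth, thresholds = max(pl$area) + 1)
  expect_equal(cv2$points$tpr, 0)
  expect_equal(cv2$points$fdr, 0)
  # on a noisy spectrum, tpr is non-increasing across the default sweep
  set.seed(52)
  yn <- y + abs(rnorm(length(y), 0, 0.5))
  pln <- call_peaks(spectrum(mz, yn))$peaks
  cvn <- oc_sweep(pln, truth)
  expect_true(all(diff(cvn$points$tpr) <= 1e-12))
  expect_error(oc_sweep(pl, truth, thresholds = c(2, 1)), "sorted")
})

test_that("loess smoothing reproduces simple curves and clips to [0,1]", {
  # points already on a line
  pts <- data.frame(fdr = seq(0, 1, by = 0.05),
                    tpr = 0.2 + 0.6 * seq(0, 1, by = 0.05))
  sm <- smooth_oc_curve(pts)
  expect_equal(sm$fdr, seq(0, 1, length.out = 101))
  expect_lt(max(abs(sm$tpr - (0.2 + 0.6 * sm$fdr))), 0.02)
  # constant tpr = 1 smooths to 1 everywhere
  pts1 <- data.frame(fdr = seq(0, 0.8, by = 0.1), tpr = 1)
  expect_equal(smooth_oc_curve(pts1)$tpr, rep(1, 101), tolerance = 1e-9)
  # fewer than 3 distinct points: step fallback with warning
  pts2 <- data.frame(fdr = c(0, 0.5), tpr = c(0, 1))
  expect_warning(sm2 <- smooth_oc_curve(pts2), "step interpolation")
  expect_true(all(sm2$tpr >= 0 & sm2$tpr <= 1))
  # noisy sigmoid recovered within a Monte-Carlo band
  set.seed(53)
  f <- function(x) 1 / (1 + exp(-10 * (x - 0.3)))
  x <- runif(60)
  pts3 <- data.frame(fdr = x,
                     tpr = pmin(pmax(f(x) + rnorm(60, 0, 0.05), 0), 1))
  sm3 <- smooth_oc_curve(pts3)
  inner <- sm3$fdr > 0.05 & sm3$fdr < 0.95
  expect_lt(max(abs(sm3$tpr[inner] - f(sm3$fdr[inner]))), 0.15)
})

test_that("curve aggregation is pointwise mean and quartiles", {
  g <- seq(0, 1, length.out = 101)
  mk <- function(y) data.frame(fdr = g, tpr = y)
  # single curve: mean and quantiles all equal it
  one <- aggregate_oc_curves(list(mk(g^2)))
  expect_equal(one$mean$tpr, g^2)
  expect_equal(one$q25$tpr, g^2)
  expect_equal(one$q75$tpr, g^2)
  # two constant curves
  two <- aggregate_oc_curves(list(mk(rep(0.4, 101)), mk(rep(0.6, 101))))
  expect_equal(two$mean$tpr, rep(0.5, 101))
  # 30 random curves vs brute-force pointwise statistics
  set.seed(54)
  ys <- replicate(30, pmin(pmax(cumsum(rnorm(101, 0.01, 0.02)), 0), 1))
  agg <- aggregate_oc_curves(apply(ys, 2, mk, simplify = FALSE))
  expect_equal(agg$mean$tpr, rowMeans(ys))
  expect_equal(agg$q25$tpr, apply(ys, 1, quantile, 0.25),
               ignore_attr = TRUE)
  expect_equal(agg$q75$tpr, apply(ys, 1, quantile, 0.75),
               ignore_attr = TRUE)
})

test_that("normalized partial AUC behaves like a score out of 100", {
  g <- seq(0, 1, length.out = 101)
  perfect <- data.frame(fdr = g, tpr = rep(1, 101))
  expect_equal(pauc(perfect, 0.25), 100)
  expect_equal(pauc(perfect, 0.5), 100)
  expect_equal(pauc(data.frame(fdr = g, tpr = rep(0, 101)), 0.25), 0)
  # identity curve: area .5*fdr_max^2 -> normalized 12.5 at fdr_max = .25
  expect_equal(pauc(data.frame(fdr = g, tpr = g), 0.25), 12.5)
  # monotone in the curve; always within [0, 100]
  set.seed(55)
  for (r in 1:20) {
    y <- pmin(pmax(cumsum(rnorm(101, 0.01, 0.03)), 0), 1)
    lift <- pmin(y + runif(1, 0, 0.2), 1)
    fm <- runif(1, 0.1, 1)
    p1 <- pauc(data.frame(fdr = g, tpr = y), fm)
    p2 <- pauc(data.frame(fdr = g, tpr = lift), fm)
    expect_gte(p2, p1 - 1e-12)
    expect_gte(p1, 0); expect_lte(p1, 100)
  }
  expect_error(pauc(perfect, 0), "fdr_max")
})
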