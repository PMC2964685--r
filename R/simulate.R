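# Synthetic test ecology: clean virtual-protein spectra, matrix-only
# buffer spectra with quadratic-variance detector noise, and hybrid
# spectra (clean + buffer). Hybrid data combine exact knowledge of the
# protein content with realistic noise/baseline behavior, which is what
# makes FDR/TPR operating characteristics computable at all.

# Evaluate-with-seed helper: runs expr with a locally seeded RNG and
# restores the caller's RNG state afterwards, so simulation functions are
# pure functions of their seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulation design for a collection of hybrid datasets
#'
#' Describes the size and physics of a simulated experiment: how many
#' datasets, how many spectra per dataset, how many virtual proteins per
#' dataset, the mass window and grid, and the priors from which protein
#' properties are drawn. Defaults mirror a repeated low-resolution
#' SELDI/MALDI experiment: 30 datasets of 50 spectra, 150 virtual proteins
#' per dataset, analyzed in the 3--30 kDa mass-focused window on a grid
#' uniform in sqrt(m/z) (time-of-flight is proportional to sqrt(mass)).
#'
#' Protein priors (all configurable): protein m/z is log-uniform on the
#' window; mean abundance is lognormal (`abundance_meanlog`,
#' `abundance_sdlog`); prevalence — the probability a given spectrum
#' contains the protein — is uniform on \[0.3, 1\]; per-spectrum abundance
#' fluctuates with coefficient of variation `cv_abundance` and the apparent
#' m/z with relative jitter `cv_mz`. Peak width follows the instrument
#' resolution R = m/z over FWHM: sigma_j = mz / (2.355 R).
#'
#' @param n_proteins virtual proteins per dataset (default 150).
#' @param n_spectra_per_dataset spectra per dataset (default 50).
#' @param n_datasets number of datasets (default 30).
#' @param mz_window analysis window in Da (default `c(3000, 30000)`).
#' @param grid_lo,grid_hi full grid range in Da (default 2000--32000; the
#'   grid extends past the window so windowing never truncates a peak
#'   kernel mid-flank).
#' @param m grid length (default 8192).
#' @param resolution instrument resolution R (default 150, low-resolution
#'   TOF regime).
#' @param prevalence_range range of the prevalence prior (default
#'   `c(0.3, 1)`).
#' @param abundance_meanlog,abundance_sdlog lognormal abundance prior
#'   (defaults `log(3000)` and 0.7).
#' @param cv_abundance per-spectrum abundance CV (default 0.2).
#' @param cv_mz per-spectrum relative m/z jitter (default 0.001).
#' @param seed integer seed making the whole collection reproducible.
#' @return An object of class `"dataset_spec"`.
#' @export
dataset_spec <- function(n_proteins = 150L, n_spectra_per_dataset = 50L,
                         n_datasets = 30L, mz_window = c(3000, 30000),
                         grid_lo = 2000, grid_hi = 32000, m = 8192L,
                         resolution = 150, prevalence_range = c(0.3, 1),
                         abundance_meanlog = log(3000),
                         abundance_sdlog = 0.7,
                         cv_abundance = 0.2, cv_mz = 0.001, seed = 1L) {
  stopifnot(n_proteins >= 1L, n_spectra_per_dataset >= 1L, n_datasets >= 1L,
            m >= 4L, grid_lo < grid_hi,
            mz_window[1] >= grid_lo, mz_window[2] <= grid_hi,
            resolution > 0, cv_abundance >= 0, cv_mz >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_spectra_per_dataset = as.integer(n_spectra_per_dataset),
                 n_datasets = as.integer(n_datasets),
                 mz_window = mz_window, grid_lo = grid_lo,
                 grid_hi = grid_hi, m = as.integer(m),
                 resolution = resolution,
                 prevalence_range = prevalence_range,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 cv_abundance = cv_abundance, cv_mz = cv_mz,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Time-of-flight style mass grid
#'
#' Grid uniform in sqrt(m/z): flight time scales as sqrt(mass), so equal
#' sampling in time gives this spacing in mass.
#'
#' @param spec a [dataset_spec()].
#' @return Numeric vector of m strictly increasing m/z values.
#' @export
tof_grid <- function(spec) {
  s <- seq(sqrt(spec$grid_lo), sqrt(spec$grid_hi), length.out = spec$m)
  s^2
}

#' Matrix/buffer noise model
#'
#' Describes the protein-free component of a spectrum: a smooth decaying
#' baseline b0(mz) (matrix-ion contribution, maximal at the low-mass edge)
#' plus pointwise detector noise with variance V(b0(mz)) from a quadratic
#' variance function. Two noise families are provided: `"symmetric"`
#' (Gaussian) and `"skewed"` (shifted gamma, right-skewed, moment-matched
#' to the same mean and variance), mirroring the contrast between machine
#' settings that produce symmetric versus heavily right-skewed intensity
#' distributions.
#'
#' @param qvf a [qvf_params()] for the detector noise.
#' @param baseline_max baseline value at the low-mass grid edge (default
#'   100 intensity units).
#' @param baseline_decay exponential decay length in Da (default 8000).
#' @param family `"symmetric"` or `"skewed"`.
#' @param skewness target skewness of the skewed family (default 1.5).
#' @param n_spectra buffer pool size (default 183).
#' @param seed integer seed for standalone pool generation.
#' @return An object of class `"buffer_model"` (contains `baseline_fn`,
#'   a function of m/z).
#' @export
buffer_model <- function(qvf = qvf_params(4, 0.5, 0.01),
                         baseline_max = 100, baseline_decay = 8000,
                         family = c("symmetric", "skewed"),
                         skewness = 1.5, n_spectra = 183L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(inherits(qvf, "qvf_params"), baseline_max > 0,
            baseline_decay > 0, skewness > 0, n_spectra >= 1L)
  # b0 is anchored at the low edge of whatever grid it is evaluated on,
  # so the baseline maximum always sits at the low-mass end.
  structure(list(qvf = qvf, baseline_max = baseline_max,
                 baseline_decay = baseline_decay, family = family,
                 skewness = skewness, n_spectra = as.integer(n_spectra),
                 seed = as.integer(seed),
                 baseline_fn = function(mz, mz0 = min(mz))
                   baseline_max * exp(-(mz - mz0) / baseline_decay)),
            class = "buffer_model")
}

#' Draw the virtual-protein truth list for one dataset
#'
#' Each protein gets an m/z (log-uniform on the window), a mean abundance
#' (lognormal), a prevalence (uniform on the configured range) and the
#' spec's fluctuation CVs. The returned data.frame is the ground truth a
#' peak caller is scored against.
#'
#' @param spec a [dataset_spec()].
#' @param seed optional seed; `NULL` (default) consumes the current RNG
#'   stream (used when a caller manages reproducibility at a higher level).
#' @return data.frame with columns `protein_id`, `mz`, `mean_abundance`,
#'   `prevalence`, `cv_abundance`, `cv_mz`, sorted by `mz`.
#' @export
sample_virtual_proteins <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  with_seed(seed, {
    k <- spec$n_proteins
    mz <- exp(stats::runif(k, log(spec$mz_window[1]), log(spec$mz_window[2])))
    ab <- stats::rlnorm(k, spec$abundance_meanlog, spec$abundance_sdlog)
    pv <- stats::runif(k, spec$prevalence_range[1], spec$prevalence_range[2])
    df <- data.frame(protein_id = seq_len(k), mz = mz, mean_abundance = ab,
                     prevalence = pv, cv_abundance = spec$cv_abundance,
                     cv_mz = spec$cv_mz)
    df <- df[order(df$mz), , drop = FALSE]
    df$protein_id <- seq_len(k)
    rownames(df) <- NULL
    df
  })
}

# Truncated Gaussian kernel: abundance * N(tj, sigma) density, set to zero
# outside [tj - 3 sigma, tj + 3 sigma].
add_protein_kernel <- function(intensity, mz, tj, sigma, abundance) {
  lo <- tj - 3 * sigma
  hi <- tj + 3 * sigma
  sel <- which(mz >= lo & mz <= hi)
  if (length(sel) > 0L)
    intensity[sel] <- intensity[sel] +
      abundance * stats::dnorm(mz[sel], mean = tj, sd = sigma)
  intensity
}

#' Simulate one clean (noise- and matrix-free) spectrum
#'
#' Each virtual protein is included independently with probability equal
#' to its prevalence. An included protein contributes a truncated Gaussian
#' kernel a_j * G(t_j, sigma_j), zero outside t_j +/- 3 sigma_j, with the
#' per-spectrum abundance a_j lognormal around the protein's mean (CV
#' `cv_abundance`) and the apparent position t_j jittered with relative
#' standard deviation `cv_mz`. Peak width sigma_j follows the resolution
#' rule of the [dataset_spec()].
#'
#' @param proteins truth data.frame from [sample_virtual_proteins()].
#' @param spec a [dataset_spec()].
#' @param grid optional precomputed grid (default [tof_grid()]).
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return List with `spectrum` (a [spectrum()], elementwise >= 0) and
#'   `included` (protein ids present in this spectrum).
#' @export
clean_spectrum <- function(proteins, spec, grid = tof_grid(spec),
                           seed = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  with_seed(seed, {
    y <- numeric(length(grid))
    included <- integer(0)
    for (r in seq_len(nrow(proteins))) {
      if (stats::runif(1) > proteins$prevalence[r]) next
      included <- c(included, proteins$protein_id[r])
      cv <- proteins$cv_abundance[r]
      a <- if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        stats::rlnorm(1, log(proteins$mean_abundance[r]) - sdl^2 / 2, sdl)
      } else proteins$mean_abundance[r]
      tj <- proteins$mz[r]
      if (proteins$cv_mz[r] > 0)
        tj <- stats::rnorm(1, tj, proteins$cv_mz[r] * tj)
      sigma <- tj / (2.355 * spec$resolution)
      y <- add_protein_kernel(y, grid, tj, sigma, a)
    }
    list(spectrum = spectrum(grid, y, meta = list(kind = "clean")),
         included = included)
  })
}

#' Simulate one matrix-only (buffer) spectrum
#'
#' Intensities are drawn independently per grid point with mean b0(mz) and
#' variance V(b0(mz)) from the buffer model's quadratic variance function.
#' The `"symmetric"` family draws Gaussian; the `"skewed"` family draws a
#' shifted gamma moment-matched to the same mean and variance with the
#' model's target skewness.
#'
#' @param bm a [buffer_model()].
#' @param grid numeric m/z grid.
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return A [spectrum()].
#' @export
buffer_spectrum <- function(bm, grid, seed = NULL) {
  stopifnot(inherits(bm, "buffer_model"))
  with_seed(seed, {
    b0 <- bm$baseline_max * exp(-(grid - grid[1]) / bm$baseline_decay)
    v <- variance_at(bm$qvf, b0)
    if (any(v < 0))
      stop("buffer model yields negative variance on the grid",
           call. = FALSE)
    y <- if (bm$family == "symmetric") {
      stats::rnorm(length(grid), mean = b0, sd = sqrt(v))
    } else {
      if (any(v <= 0))
        stop("skewed noise family requires strictly positive variance",
             call. = FALSE)
      shape <- (2 / bm$skewness)^2
      scale <- sqrt(v / shape)
      shift <- b0 - shape * scale
      shift + stats::rgamma(length(grid), shape = shape, scale = scale)
    }
    spectrum(grid, y, meta = list(kind = "buffer", family = bm$family))
  })
}

#' Generate a pool of buffer spectra
#'
#' @param bm a [buffer_model()].
#' @param grid numeric m/z grid.
#' @param seed seed (default `bm$seed`).
#' @return A [spectrum_set()] of `bm$n_spectra` buffer spectra.
#' @export
generate_buffer_pool <- function(bm, grid, seed = bm$seed) {
  with_seed(seed, {
    mat <- vapply(seq_len(bm$n_spectra),
                  function(i) buffer_spectrum(bm, grid)$intensity,
                  numeric(length(grid)))
    spectrum_set(grid, mat, condition_label = sprintf("buffer-%s", bm$family))
  })
}

#' Sum a clean and a buffer spectrum into a hybrid spectrum
#'
#' @param clean,buffer [spectrum()] objects on identical grids.
#' @return A [spectrum()]; `meta` records both parents' kinds.
#' @export
hybrid_spectrum <- function(clean, buffer) {
  stopifnot(inherits(clean, "spectrum"), inherits(buffer, "spectrum"))
  if (length(clean$mz) != length(buffer$mz) || any(clean$mz != buffer$mz))
    stop("hybrid_spectrum requires identical grids", call. = FALSE)
  spectrum(clean$mz, clean$intensity + buffer$intensity,
           meta = list(kind = "hybrid",
                       parents = c(clean$meta$kind, buffer$meta$kind)))
}

#' Generate a full hybrid test collection
#'
#' Produces `n_datasets` datasets, each with its own freshly drawn
#' virtual-protein truth list and `n_spectra_per_dataset` hybrid spectra.
#' Buffer spectra are sampled with replacement from one finite simulated
#' pool (size `bm$n_spectra`) shared by the whole collection — emulating
#' the practical situation where far fewer matrix-only acquisitions exist
#' than test spectra are needed, and reuse-by-sampling introduces the
#' noise variation between datasets. The entire collection is a pure
#' function of `(spec, bm, spec$seed)`.
#'
#' @param spec a [dataset_spec()].
#' @param bm a [buffer_model()].
#' @return An object of class `"hybrid_collection"`: list with `datasets`
#'   (each a list of `spectra` — a hybrid [spectrum_set()] — and `truth`),
#'   `buffer_pool` (a [spectrum_set()]), `grid`, `spec`, `bm`.
#' @export
generate_collection <- function(spec, bm) {
  stopifnot(inherits(spec, "dataset_spec"), inherits(bm, "buffer_model"))
  with_seed(spec$seed, {
    grid <- tof_grid(spec)
    pool <- generate_buffer_pool(bm, grid, seed = NULL)
    datasets <- vector("list", spec$n_datasets)
    for (dset in seq_len(spec$n_datasets)) {
      truth <- sample_virtual_proteins(spec)
      mat <- matrix(NA_real_, nrow = length(grid),
                    ncol = spec$n_spectra_per_dataset)
      for (k in seq_len(spec$n_spectra_per_dataset)) {
        cl <- clean_spectrum(truth, spec, grid = grid)
        buf <- set_member(pool, sample.int(pool$n, 1L))
        mat[, k] <- cl$spectrum$intensity + buf$intensity
      }
      datasets[[dset]] <- list(
        spectra = spectrum_set(grid, mat,
                               condition_label = sprintf("hybrid-%d", dset)),
        truth = truth)
    }
    structure(list(datasets = datasets, buffer_pool = pool, grid = grid,
                   spec = spec, bm = bm),
              class = "hybrid_collection")
  })
}

#' Write / read a truth list as CSV
#'
#' @param truth data.frame from [sample_virtual_proteins()].
#' @param path file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` a
#'   data.frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth[, c("protein_id", "mz", "mean_abundance",
                             "prevalence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("protein_id", "mz") %in% names(df)))
    stop("truth CSV must have protein_id and mz columns", call. = FALSE)
  df
}
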