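# Laser-shot-resolved spectrum simulation.
#
# An acquisition with n shots is the mean of n independent single-shot
# spectra. Each single shot draws (i) a global intensity gain (unit-mean
# lognormal, CV = gain_cv) shared by every peak, the baseline and the
# chemical noise - the laser-fluence / spot-heterogeneity component - and
# (ii) an independent per-peak ionization factor (unit mean, CV = shot_cv
# x the feature's ionization multiplier), plus additive Gaussian detector
# noise. Averaging n shots leaves the expectation unchanged and scales
# every variance by 1/n, the statistical backbone of the low-shot vs
# high-shot contrast. The gain component is in principle recoverable from
# the spectrum itself (everything brightens together); the per-peak
# component is not.

#' Acquisition configuration for the spectrum simulator
#'
#' @param mz_min,mz_max m/z range of the profile grid (Da).
#' @param n_points number of grid points. The default 9001 gives a 0.1 Da
#'   spacing, a desk-scale stand-in for the ~80,000-point instrument grids;
#'   raise it for full-resolution runs.
#' @param peak_sigma Gaussian peak width (standard deviation, Da).
#' @param baseline_level flat baseline intensity.
#' @param chemical_noise_density expected nuisance peaks per Da (Poisson).
#'   Nuisance peaks are re-drawn for every acquisition at heights below the
#'   planted-feature regime, giving the S/N and presence filters true
#'   negatives to remove.
#' @param chemical_log2_range log2 height range of chemical-noise peaks.
#' @param shot_cv per-shot multiplicative CV of each peak's individual
#'   ionization factor.
#' @param gain_cv per-shot CV of the global intensity gain shared by all
#'   peaks, the baseline and the chemical noise within a shot. Together the
#'   defaults give a 1000-shot replicate apex CV of about 11%, the
#'   noisy-native-replicate regime.
#' @param detector_sd per-shot additive detector noise standard deviation.
#' @param adduct_offsets,adduct_height optional satellite (cation adduct)
#'   peaks at fixed Da offsets with the given relative height; disabled by
#'   default (`adduct_height = 0`).
#' @return an object of class `smp_acq` (a validated list).
#' @examples
#' acq <- acquisition_config(n_points = 2001, mz_max = 300)
#' @export
acquisition_config <- function(mz_min = 100, mz_max = 1000, n_points = 9001,
                               peak_sigma = 0.2, baseline_level = 5,
                               chemical_noise_density = 0.05,
                               chemical_log2_range = c(2, 4.5),
                               shot_cv = 0.25, gain_cv = 3.3, detector_sd = 8,
                               adduct_offsets = c(21.98, 37.96),
                               adduct_height = 0) {
  if (!(mz_min < mz_max)) stop_invalid("mz_min must be < mz_max")
  if (n_points < 2) stop_invalid("n_points must be >= 2")
  if (peak_sigma <= 0) stop_invalid("peak_sigma must be > 0")
  if (shot_cv < 0) stop_invalid("shot_cv must be >= 0")
  if (gain_cv < 0) stop_invalid("gain_cv must be >= 0")
  if (detector_sd < 0) stop_invalid("detector_sd must be >= 0")
  if (chemical_noise_density < 0) stop_invalid("chemical_noise_density must be >= 0")
  structure(
    list(mz_min = mz_min, mz_max = mz_max, n_points = as.integer(n_points),
         peak_sigma = peak_sigma, baseline_level = baseline_level,
         chemical_noise_density = chemical_noise_density,
         chemical_log2_range = chemical_log2_range,
         shot_cv = shot_cv, gain_cv = gain_cv, detector_sd = detector_sd,
         adduct_offsets = adduct_offsets, adduct_height = adduct_height),
    class = "smp_acq"
  )
}

acq_grid <- function(acq) seq(acq$mz_min, acq$mz_max, length.out = acq$n_points)

#' Construct a spectrum object
#'
#' Validates and wraps a profile spectrum: strictly increasing m/z grid,
#' nonnegative intensities, plus acquisition metadata.
#'
#' @param mz strictly increasing m/z vector (Da).
#' @param intensity nonnegative intensities, same length as `mz`.
#' @param sample_id,replicate_id,n_shots acquisition metadata.
#' @return an object of class `smp_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, sample_id = NA_character_,
                         replicate_id = NA_integer_, n_shots = NA_integer_) {
  if (length(mz) != length(intensity)) {
    stop_invalid("mz and intensity must have equal length")
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop_invalid("mz must be strictly increasing")
  }
  if (any(intensity < 0)) stop_invalid("intensities must be >= 0")
  structure(
    list(mz = as.numeric(mz), intensity = as.numeric(intensity),
         sample_id = sample_id, replicate_id = replicate_id,
         n_shots = n_shots),
    class = "smp_spectrum"
  )
}

#' @export
print.smp_spectrum <- function(x, ...) {
  cat(sprintf("LDI-MS spectrum: %d points, m/z [%.2f, %.2f]%s%s\n",
              length(x$mz), min(x$mz), max(x$mz),
              if (is.na(x$sample_id)) "" else paste0(", sample ", x$sample_id),
              if (is.na(x$n_shots)) "" else sprintf(", %d shots", x$n_shots)))
  invisible(x)
}

#' @export
plot.smp_spectrum <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "l", xlab = "m/z (Da)",
                 ylab = "intensity", ...)
  invisible(x)
}

# peak centers/heights for a sample, including optional adduct satellites
.panel_peaks <- function(log2_abund, panel, acq) {
  mz <- panel$features$mz
  h <- 2^log2_abund
  ion <- panel$features$ionization_cv
  if (acq$adduct_height > 0) {
    for (off in acq$adduct_offsets) {
      keep <- (mz + off) <= acq$mz_max
      mz <- c(mz, mz[seq_along(log2_abund)][keep] + off)
      h <- c(h, h[seq_along(log2_abund)][keep] * acq$adduct_height)
      ion <- c(ion, ion[seq_along(log2_abund)][keep])
    }
  }
  list(mz = mz, height = h, ion = ion)
}

# add Gaussian peaks onto an intensity vector (windowed at +/- 6 sigma)
.add_peaks <- function(intensity, grid, centers, heights, sigma) {
  dx <- grid[2] - grid[1]
  hw <- ceiling(6 * sigma / dx)
  n <- length(grid)
  for (i in seq_along(centers)) {
    j <- round((centers[i] - grid[1]) / dx) + 1
    idx <- max(1, j - hw):min(n, j + hw)
    intensity[idx] <- intensity[idx] +
      heights[i] * exp(-(grid[idx] - centers[i])^2 / (2 * sigma^2))
  }
  intensity
}

#' Analytic noise-free spectrum
#'
#' The exact expectation of [simulate_spectrum()] with chemical noise off:
#' Gaussian peaks at the panel centers with heights `2^log2_abund`, plus the
#' flat baseline. Used as the unbiasedness oracle in tests.
#'
#' @param log2_abund vector of true log2 abundances (one per panel feature).
#' @param panel,acq panel and acquisition configuration.
#' @return an `smp_spectrum`.
#' @export
analytic_spectrum <- function(log2_abund, panel, acq) {
  stopifnot(inherits(panel, "smp_panel"), inherits(acq, "smp_acq"))
  grid <- acq_grid(acq)
  pk <- .panel_peaks(log2_abund, panel, acq)
  y <- .add_peaks(rep(acq$baseline_level, length(grid)), grid, pk$mz, pk$height,
                  acq$peak_sigma)
  new_spectrum(grid, y, n_shots = NA_integer_)
}

#' Simulate one acquisition (mean of n laser shots)
#'
#' Draws one profile spectrum for a subject. Per shot, a global unit-mean
#' lognormal gain (CV `gain_cv`) multiplies the baseline and every peak,
#' and each peak additionally draws an independent unit-mean lognormal
#' ionization factor (per-shot CV `shot_cv` scaled by the feature's
#' ionization multiplier); Poisson-placed chemical-noise peaks behave the
#' same way, and additive detector noise enters with standard deviation
#' `detector_sd / sqrt(n_shots)` -- the exact distribution of the mean of
#' `n_shots` single-shot detector-noise draws. The expectation is thus
#' independent of `n_shots` and every peak-apex variance scales as
#' `1/n_shots`. Intensities are truncated at zero.
#'
#' @param log2_abund true log2 abundances for the subject (panel order), or
#'   an `smp_cohort` row passed as `cohort$log2_abund[i, ]`.
#' @param panel an [make_panel()] object.
#' @param acq an [acquisition_config()] object.
#' @param n_shots number of averaged laser shots (>= 1).
#' @param seed integer seed.
#' @param sample_id,replicate_id metadata carried on the spectrum.
#' @return an `smp_spectrum`.
#' @examples
#' pan <- make_panel(5, 0, 0, 0, seed = 1, mz_range = c(100, 300))
#' acq <- acquisition_config(mz_max = 300, n_points = 2001)
#' sp <- simulate_spectrum(pan$features$base_log2, pan, acq, 1000, seed = 7)
#' @export
simulate_spectrum <- function(log2_abund, panel, acq, n_shots, seed = 1,
                              sample_id = NA_character_,
                              replicate_id = NA_integer_) {
  stopifnot(inherits(panel, "smp_panel"), inherits(acq, "smp_acq"))
  if (n_shots < 1) stop_invalid("n_shots must be >= 1")
  n_shots <- as.integer(n_shots)
  if (length(log2_abund) != panel$n_features) {
    stop_invalid("log2_abund must have one entry per panel feature")
  }
  grid <- acq_grid(acq)
  pk <- .panel_peaks(log2_abund, panel, acq)
  y <- local_seed(seed, {
    # per-shot global gain shared across the whole transient
    G <- .unit_lognormal(n_shots, acq$gain_cv)
    # mean over shots of (gain x per-peak ionization factor) per planted peak
    cvs <- acq$shot_cv * pk$ion
    fac <- .mean_gain_lognormal(G, cvs)
    out <- rep(acq$baseline_level * mean(G), length(grid))
    out <- .add_peaks(out, grid, pk$mz, pk$height * fac, acq$peak_sigma)
    # chemical noise: Poisson placement, same per-shot noise structure
    lam <- acq$chemical_noise_density * (acq$mz_max - acq$mz_min)
    n_chem <- stats::rpois(1, lam)
    if (n_chem > 0) {
      cmz <- stats::runif(n_chem, acq$mz_min, acq$mz_max)
      ch <- 2^stats::runif(n_chem, acq$chemical_log2_range[1],
                           acq$chemical_log2_range[2])
      cfac <- .mean_gain_lognormal(G, rep(acq$shot_cv, n_chem))
      out <- .add_peaks(out, grid, cmz, ch * cfac, acq$peak_sigma)
    }
    if (acq$detector_sd > 0) {
      out <- out + stats::rnorm(length(grid), 0, acq$detector_sd / sqrt(n_shots))
    }
    pmax(out, 0)
  })
  new_spectrum(grid, y, sample_id = sample_id, replicate_id = replicate_id,
               n_shots = n_shots)
}

# n iid unit-mean lognormal draws with the given CV
.unit_lognormal <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -0.5 * sdl^2, sdlog = sdl)
}

# mean over shots of shared gain x per-peak factor, for each CV in `cvs`
.mean_gain_lognormal <- function(G, cvs) {
  n <- length(G)
  vapply(seq_along(cvs), function(i) {
    mean(G * .unit_lognormal(n, cvs[i]))
  }, numeric(1))
}

#' Generate aligned low-shot / high-shot acquisition pairs
#'
#' Training material for the deep stabilizer: `n_pairs` pairs of spectra from
#' the same subject truth, the first member acquired with `low_shots` (the
#' noisy "native" regime) and the second with `high_shots` (the near-reference
#' regime).
#'
#' @param log2_abund subject truth (panel order).
#' @param panel,acq panel and acquisition configuration.
#' @param low_shots,high_shots shot counts; `low_shots < high_shots`.
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @return list of `n_pairs` lists with elements `low` and `high`
#'   (both `smp_spectrum`).
#' @export
paired_acquisition <- function(log2_abund, panel, acq, low_shots, high_shots,
                               n_pairs, seed = 1) {
  if (low_shots >= high_shots) {
    stop_invalid("low_shots (%d) must be < high_shots (%d)", low_shots, high_shots)
  }
  if (n_pairs < 1) stop_invalid("n_pairs must be >= 1")
  lapply(seq_len(n_pairs), function(i) {
    list(
      low = simulate_spectrum(log2_abund, panel, acq, low_shots,
                              seed = stage_seed(seed, "acquisition") + 2L * i,
                              replicate_id = i),
      high = simulate_spectrum(log2_abund, panel, acq, high_shots,
                               seed = stage_seed(seed, "acquisition") + 2L * i + 1L,
                               replicate_id = i)
    )
  })
}
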