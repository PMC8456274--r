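# SMP extraction: local-maximum detection, S/N estimation and filtering,
# m/z alignment.

test_that("local-maximum detection matches the exhaustive window-scan oracle", {
  set.seed(101)
  for (rep in 1:10) {
    n <- 300
    y <- abs(rnorm(n, 10, 4)) + ifelse(runif(n) < 0.03, runif(n, 30, 80), 0)
    sp <- new_spectrum(seq(100, 200, length.out = n), y)
    for (w in c(3, 5, 7)) {
      pk <- detect_peaks(sp, w)
      expect_identical(attr(pk, "peak_index"), oracle_peaks(y, w))
    }
  }
})

test_that("detection handles degenerate spectra and bad windows", {
  sp <- new_spectrum(1:50, rep(3, 50))
  expect_equal(nrow(detect_peaks(sp, 5)), 0)           # no strict maxima
  expect_error(detect_peaks(sp, 4), "odd")
  expect_error(detect_peaks(sp, 51), "larger than spectrum")
  # noise-free planted peaks are recovered at their centers
  pan <- fix_panel()
  sp2 <- analytic_spectrum(pan$features$base_log2, pan, fix_acq_clean())
  pk <- detect_peaks(sp2, 5)
  expect_equal(nrow(pk), 35)
  dx <- 400 / 1023
  expect_true(all(abs(pk$mz - pan$features$mz) <= dx + 1e-9))
})

test_that("S/N follows its defining arithmetic", {
  # constructed spectrum: three-level free region (median 30, robust scale
  # 1.4826 * MAD = 30) with a single apex at 120
  n <- 201
  a <- 30 / 1.4826
  y <- rep(c(30 - a, 30, 30 + a), length.out = n)
  j <- 101
  y[j] <- 120
  sp <- new_spectrum(1:n, y)
  pk <- detect_peaks(sp, 3)
  pk <- pk[pk$intensity == 120, , drop = FALSE]
  attr(pk, "peak_index") <- j
  pk <- estimate_snr(sp, pk, exclude_halfwidth = 1, local_halfwidth = 50)
  expect_equal(pk$snr, (120 - 30) / 30, tolerance = 0.02)
})

test_that("S/N of a planted peak sits near height/noise and caps when noise-free", {
  pan1 <- make_panel(1, 0, 0, 0, seed = 3, mz_range = c(100, 140), min_spacing = 2)
  sigma <- 4
  acq <- acquisition_config(mz_min = 100, mz_max = 140, n_points = 401,
                            peak_sigma = 0.8, detector_sd = sigma,
                            baseline_level = 10, chemical_noise_density = 0,
                            shot_cv = 0, gain_cv = 0)
  stopifnot(acq$gain_cv == 0)
  snrs <- vapply(1:100, function(r) {
    sp <- simulate_spectrum(log2(50 * sigma), pan1, acq, 1, seed = r)
    pk <- detect_peaks(sp, 5)
    # single-shot spectra are maximum-density in noise maxima, so the
    # global-scale fallback is the expected path here
    pk <- suppressWarnings(estimate_snr(sp, pk))
    pk$snr[which.max(pk$intensity)]
  }, numeric(1))
  expect_gt(median(snrs), 35)
  expect_lt(median(snrs), 65)
  # zero-noise spectrum reports the capped sentinel
  sp0 <- analytic_spectrum(log2(50 * sigma), pan1,
                           acquisition_config(mz_min = 100, mz_max = 140,
                                              n_points = 401, peak_sigma = 0.8))
  pk0 <- estimate_snr(sp0, detect_peaks(sp0, 5))
  expect_equal(max(pk0$snr), 1e6)
})

test_that("the S/N filter excludes the boundary and is monotone in the threshold", {
  pk <- fix_peaklist(c(150, 200, 250), snr = c(2.9, 3.0, 3.1))
  kept <- filter_by_snr(pk, 3)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$mz, 250)
  expect_equal(nrow(filter_by_snr(fix_peaklist(numeric(0), numeric(0),
                                               numeric(0)), 3)), 0)
  # constructed snr values: exactly the > 3 ones survive
  set.seed(77)
  snr <- c(runif(40, 3.01, 40), runif(55, 0, 3))
  pk2 <- fix_peaklist(sort(runif(95, 100, 900)), snr = snr)
  expect_equal(nrow(filter_by_snr(pk2, 3)), 40)
  # monotonicity
  counts <- vapply(seq(0, 10, by = 0.5),
                   function(th) nrow(filter_by_snr(pk2, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("alignment merges within tolerance and splits outside it", {
  p1 <- fix_peaklist(204.10, 50, sample_id = "a")
  p2 <- fix_peaklist(204.12, 70, sample_id = "b")
  fm <- align_features(list(p1, p2), mz_tolerance = 0.1)
  expect_equal(ncol(fm$values), 1)
  expect_equal(dim(fm$values), c(2, 1))
  expect_equal(fm$feature_mz, weighted.mean(c(204.10, 204.12), c(50, 70)))
  fm2 <- align_features(list(p1, p2), mz_tolerance = 0.01)
  expect_equal(ncol(fm2$values), 2)
  # absent cells imputed as zero
  expect_equal(fm2$values[1, ], c(50, 0))
  expect_equal(fm2$values[2, ], c(0, 70))
  expect_error(align_features(list(p1), mz_tolerance = 0), "tolerance")
})

test_that("jittered replicates of a 35-peak panel align onto the true centers", {
  pan <- fix_panel()
  centers <- pan$features$mz
  set.seed(5)
  pls <- lapply(1:20, function(r) {
    fix_peaklist(centers + rnorm(35, 0, 0.02 / 3), runif(35, 40, 200),
                 sample_id = sprintf("s%02d", r))
  })
  fm <- align_features(pls, mz_tolerance = 0.1, min_fraction = 0.5)
  expect_equal(ncol(fm$values), 35)
  expect_true(all(fm$values > 0))                  # present in every spectrum
  expect_true(all(abs(fm$feature_mz - centers) < 0.05))
})

test_that("alignment is invariant to the order of the input spectra", {
  pan <- fix_panel()
  set.seed(6)
  pls <- lapply(1:8, function(r) {
    keep <- runif(35) < 0.8
    fix_peaklist(pan$features$mz[keep] + rnorm(sum(keep), 0, 0.01),
                 runif(sum(keep), 30, 100), sample_id = sprintf("s%d", r))
  })
  fm1 <- align_features(pls, 0.1, min_fraction = 0.4)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  fm2 <- align_features(pls[perm], 0.1, min_fraction = 0.4)
  expect_equal(fm1$feature_mz, fm2$feature_mz)
  expect_equal(fm1$values[perm, ], fm2$values)
})

test_that("end-to-end extraction recovers the planted panel from noisy replicates", {
  pan <- fix_panel(seed = 9)
  acq <- fix_acq()
  coh <- sample_cohort(pan, 2, 2, 0.4, seed = 10)
  spectra <- list()
  for (i in 1:4) for (r in 1:3) {
    spectra[[length(spectra) + 1L]] <-
      simulate_spectrum(coh$log2_abund[i, ], pan, acq, 1000,
                        seed = 100 * i + r,
                        sample_id = coh$samples$sample_id[i], replicate_id = r)
  }
  fm <- extract_smp(spectra, window_points = 5, snr_threshold = 3,
                    mz_tolerance = 0.8, min_fraction = 0.5,
                    snr_exclude = 4, snr_local = 80,
                    labels = rep(coh$samples$label, each = 3))
  near <- vapply(pan$features$mz,
                 function(m) min(abs(fm$feature_mz - m)), numeric(1))
  expect_equal(sum(near < 0.8), 35)
})
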