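# Shared fixtures. Everything is generated in code at test time; the heavier
# objects (replicate pair sets, one trained tiny stabilizer) are memoized in
# an environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small panel/acquisition used throughout: 35 features on 100-500 Da,
# 1024-point profile grid
fix_panel <- function(seed = 1, effect = 0.6) {
  make_panel(35, 6, effect, 5, seed = seed, mz_range = c(100, 500),
             min_spacing = 6)
}

fix_acq <- function(...) {
  acquisition_config(mz_min = 100, mz_max = 500, n_points = 1024,
                     peak_sigma = 1.2, detector_sd = 8, ...)
}

# noise-free acquisition (all stochastic terms off)
fix_acq_clean <- function() {
  acquisition_config(mz_min = 100, mz_max = 500, n_points = 1024,
                     peak_sigma = 1.2, shot_cv = 0, gain_cv = 0,
                     detector_sd = 0, chemical_noise_density = 0)
}

# replicate matrices: one binned matrix (replicates x bins) per sample,
# plus the per-sample reference (mean over replicates)
fix_replicates <- function(panel, acq, cohort, n_rep = 10, n_shots = 1000,
                           bins = 512, seed = 1) {
  n <- nrow(cohort$log2_abund)
  reps <- vector("list", n)
  refs <- vector("list", n)
  for (i in seq_len(n)) {
    R <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
      as.numeric(bin_spectrum(
        simulate_spectrum(cohort$log2_abund[i, ], panel, acq, n_shots,
                          seed = seed * 100000L + 1000L * i + r), bins))
    }))
    reps[[i]] <- R
    refs[[i]] <- colMeans(R)
  }
  list(reps = reps, refs = refs)
}

# (low, high) training pairs: low = one replicate, high = replicate mean
fix_pairs <- function(rr) {
  pairs <- list()
  for (i in seq_along(rr$reps)) {
    for (r in seq_len(nrow(rr$reps[[i]]))) {
      pairs[[length(pairs) + 1L]] <- list(low = rr$reps[[i]][r, ],
                                          high = rr$refs[[i]])
    }
  }
  pairs
}

# one trained tiny stabilizer shared across test files (512 bins, 2 dense
# blocks) together with held-out replicate matrices
fix_trained_stabilizer <- function() {
  memo("stab512", {
    pan <- fix_panel(seed = 3)
    coh <- sample_cohort(pan, 12, 12, 0.4, seed = 4)
    rr <- fix_replicates(pan, fix_acq(), coh, n_rep = 8, seed = 5)
    pairs <- fix_pairs(list(reps = rr$reps[1:20], refs = rr$refs[1:20]))
    cfg <- stabilizer_config(512, n_dense_blocks = 2, layers_per_block = 2,
                             growth_channels = 6, kernel_size = 9,
                             epochs = 6, batch_size = 16,
                             learning_rate = 1e-2, seed = 11)
    list(model = train_stabilizer(pairs, cfg),
         hold_reps = rr$reps[21:24], hold_refs = rr$refs[21:24])
  })
}

# forge a peak list (the alignment stage only needs mz/intensity plus the
# source metadata attributes)
fix_peaklist <- function(mz, intensity = rep(100, length(mz)),
                         snr = rep(10, length(mz)), sample_id = "s1",
                         replicate_id = 1L) {
  structure(data.frame(mz = mz, intensity = intensity, snr = snr),
            class = c("smp_peaks", "data.frame"),
            sample_id = sample_id, replicate_id = replicate_id,
            peak_index = seq_along(mz), n_grid = length(mz),
            baseline = 0)
}

# independent linear-interpolation percentile (oracle for quantile type 7)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  if (length(x) == 1L) return(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# brute-force MK surface: an independent re-derivation used as the oracle
oracle_surface <- function(ctrl, pat, cv_mode = "sensitivity") {
  M <- ncol(ctrl)
  out <- data.frame()
  for (n in 1:100) {
    thr <- numeric(M); sens <- numeric(M); spec <- numeric(M)
    labm <- matrix(0, nrow(pat), M)
    for (m in 1:M) {
      thr[m] <- oracle_percentile(ctrl[, m], n / 100)
      labm[, m] <- as.numeric(pat[, m] > thr[m])
      sens[m] <- sum(labm[, m]) / nrow(pat)
      spec[m] <- sum(ctrl[, m] <= thr[m]) / nrow(ctrl)
    }
    cv <- if (cv_mode == "labels") {
      mean(apply(labm, 1, function(v) {
        mu <- mean(v)
        if (mu == 0) 0 else stats::sd(v) / mu
      }))
    } else {
      mu <- mean(sens)
      if (mu == 0 && all(sens == 0)) 0 else stats::sd(sens) / mu
    }
    out <- rbind(out, data.frame(percentile = n, threshold = mean(thr),
                                 specificity = mean(spec),
                                 sensitivity = mean(sens), cv = cv))
  }
  out
}

oracle_vus <- function(rows) {
  o <- order(rows$specificity)
  s <- c(0, rows$specificity[o])
  f <- rows$cv[o] * rows$sensitivity[o]
  f <- c(f[1], f)
  tot <- 0
  for (i in 2:length(s)) tot <- tot + (s[i] - s[i - 1]) * (f[i] + f[i - 1]) / 2
  tot
}

# exhaustive local-maximum scan: oracle for detect_peaks
oracle_peaks <- function(y, w) {
  half <- (w - 1) %/% 2
  base <- stats::median(y)
  idx <- integer(0)
  for (i in seq_along(y)) {
    win <- y[max(1, i - half):min(length(y), i + half)]
    if (y[i] > base && sum(win == max(win)) == 1 && y[i] == max(win)) {
      idx <- c(idx, i)
    }
  }
  idx
}

# pairwise Mann-Whitney AUC with 0.5 tie credit: oracle for the trapezoidal AUC
oracle_auc <- function(probs, y) {
  pos <- probs[y == 1]; neg <- probs[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
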