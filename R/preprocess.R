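# Serum-metabolic-profile (SMP) extraction: local-maximum peak picking,
# robust signal-to-noise estimation, strict S/N filtering, and greedy m/z
# alignment of peak lists into a samples x features intensity matrix.

#' Detect peaks by the local-maximum method
#'
#' A grid point is a peak if it is the strict maximum of its centred window
#' of `window_points` points (truncated at the spectrum edges) and exceeds
#' the baseline estimate (the median intensity of the spectrum).
#'
#' @param spectrum an `smp_spectrum`.
#' @param window_points odd window width in grid points (>= 3).
#' @return an object of class `smp_peaks`: a data frame with columns `mz`,
#'   `intensity`, `snr` (`NA` until [estimate_snr()]), plus the source
#'   spectrum's metadata and peak grid indices as attributes.
#' @export
detect_peaks <- function(spectrum, window_points = 5) {
  stopifnot(inherits(spectrum, "smp_spectrum"))
  w <- as.integer(window_points)
  if (w < 3 || w %% 2 == 0) stop_invalid("window_points must be odd and >= 3")
  n <- length(spectrum$intensity)
  if (w > n) stop_invalid("window (%d) larger than spectrum (%d points)", w, n)
  y <- spectrum$intensity
  half <- (w - 1L) %/% 2L
  is_max <- rep(TRUE, n)
  for (d in seq_len(half)) {
    left <- c(rep(-Inf, d), y[seq_len(n - d)])
    right <- c(y[(d + 1L):n], rep(-Inf, d))
    is_max <- is_max & (y > left) & (y > right)
  }
  base <- stats::median(y)
  idx <- which(is_max & y > base)
  res <- data.frame(mz = spectrum$mz[idx], intensity = y[idx],
                    snr = rep(NA_real_, length(idx)))
  structure(res,
            class = c("smp_peaks", "data.frame"),
            sample_id = spectrum$sample_id,
            replicate_id = spectrum$replicate_id,
            peak_index = idx, n_grid = n, baseline = base)
}

#' @export
print.smp_peaks <- function(x, ...) {
  cat(sprintf("Peak list: %d peaks%s\n", nrow(x),
              if (all(is.na(x$snr))) " (S/N not yet estimated)" else ""))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Estimate peak signal-to-noise ratios
#'
#' S/N of a peak is `(apex - local baseline) / noise_sigma`, clamped at zero.
#' The local baseline is the median of peak-free intensities within
#' `local_halfwidth` grid points of the apex; `noise_sigma` is a robust
#' global scale (1.4826 x median absolute deviation) of the peak-free
#' region, where "peak-free" excludes `exclude_halfwidth` points around
#' every detected apex. With no measurable noise the S/N is reported as the
#' `snr_cap` sentinel.
#'
#' @param spectrum the spectrum the peaks came from.
#' @param peaks an `smp_peaks` object from [detect_peaks()].
#' @param exclude_halfwidth half-width (points) masked around each apex when
#'   building the peak-free region.
#' @param local_halfwidth half-width (points) of the local baseline window.
#' @param snr_cap value reported for peaks in a noise-free spectrum.
#' @return `peaks` with the `snr` column filled.
#' @export
estimate_snr <- function(spectrum, peaks, exclude_halfwidth = 10,
                         local_halfwidth = 150, snr_cap = 1e6) {
  stopifnot(inherits(spectrum, "smp_spectrum"), inherits(peaks, "smp_peaks"))
  y <- spectrum$intensity
  n <- length(y)
  idx <- attr(peaks, "peak_index")
  if (!is.null(idx) && length(idx) && (max(idx) > n || !all(y[idx] == peaks$intensity))) {
    stop_invalid("peaks were not detected from this spectrum")
  }
  free <- rep(TRUE, n)
  for (i in idx) {
    free[max(1, i - exclude_halfwidth):min(n, i + exclude_halfwidth)] <- FALSE
  }
  # a vanished (or near-vanished) peak-free region cannot support a robust
  # scale estimate; fall back to the whole spectrum, which the MAD keeps
  # robust to the peaks themselves. Only a truly empty region warrants a
  # warning - on dense spectra the fallback is routine.
  if (sum(free) < max(20, 0.05 * n)) {
    if (!any(free)) warning("no peak-free region; falling back to global robust scale")
    free <- rep(TRUE, n)
  }
  sigma <- stats::mad(y[free])
  global_base <- stats::median(y[free])
  snr <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    win <- max(1, i - local_halfwidth):min(n, i + local_halfwidth)
    loc <- win[free[win]]
    base <- if (length(loc)) stats::median(y[loc]) else global_base
    sig <- peaks$intensity[k] - base
    if (sig <= 0) return(0)
    if (sigma <= 0) return(snr_cap)
    min(sig / sigma, snr_cap)
  }, numeric(1))
  peaks$snr <- snr
  peaks
}

#' Filter peaks by signal-to-noise
#'
#' Retains peaks with `snr` strictly greater than the threshold, i.e.
#' excludes background peaks with S/N <= threshold (default 3).
#'
#' @param peaks an `smp_peaks` object with `snr` filled.
#' @param threshold S/N threshold; peaks at exactly the threshold are removed.
#' @return the filtered `smp_peaks`.
#' @export
filter_by_snr <- function(peaks, threshold = 3) {
  stopifnot(inherits(peaks, "smp_peaks"))
  if (nrow(peaks) == 0L) return(peaks)
  if (anyNA(peaks$snr)) stop_invalid("S/N not computed; run estimate_snr() first")
  keep <- peaks$snr > threshold
  out <- peaks[keep, , drop = FALSE]
  attr(out, "peak_index") <- attr(peaks, "peak_index")[keep]
  attr(out, "sample_id") <- attr(peaks, "sample_id")
  attr(out, "replicate_id") <- attr(peaks, "replicate_id")
  attr(out, "n_grid") <- attr(peaks, "n_grid")
  class(out) <- class(peaks)
  out
}

#' Align peak lists into a feature matrix
#'
#' Pools all peaks, sorts them by m/z, and greedily forms clusters whose
#' total m/z width does not exceed `mz_tolerance` (single-linkage along the
#' sorted axis). Each cluster becomes a candidate feature with consensus m/z
#' equal to the intensity-weighted mean of its members. A feature is kept
#' only if it is present in at least `min_fraction` of the input spectra;
#' absent cells are imputed as 0 (absence of a peak is informative for the
#' downstream sparse classifier). When one spectrum contributes several
#' peaks to a cluster the most intense is used.
#'
#' @param peaklists list of `smp_peaks` objects (one per spectrum).
#' @param mz_tolerance maximum cluster width in Da (> 0).
#' @param min_fraction minimum fraction of spectra in which a feature must
#'   be present.
#' @return an object of class `smp_features`: list with `values`
#'   (spectra x features matrix), `feature_mz`, `sample_id`, `replicate_id`,
#'   and `label` (filled by the pipeline when known).
#' @export
align_features <- function(peaklists, mz_tolerance = 0.1, min_fraction = 0.5) {
  if (!length(peaklists)) stop_invalid("need at least one peak list")
  if (mz_tolerance <= 0) stop_invalid("mz_tolerance must be > 0")
  stopifnot(all(vapply(peaklists, inherits, TRUE, "smp_peaks")))
  n_spec <- length(peaklists)
  pooled <- do.call(rbind, lapply(seq_len(n_spec), function(i) {
    p <- peaklists[[i]]
    if (!nrow(p)) return(NULL)
    data.frame(mz = p$mz, intensity = p$intensity, spec = i)
  }))
  sample_id <- vapply(peaklists, function(p) attr(p, "sample_id") %||% NA_character_,
                      character(1))
  replicate_id <- vapply(peaklists, function(p) {
    as.integer(attr(p, "replicate_id") %||% NA_integer_)
  }, integer(1))
  if (is.null(pooled) || !nrow(pooled)) {
    return(structure(list(values = matrix(0, n_spec, 0), feature_mz = numeric(0),
                          sample_id = sample_id, replicate_id = replicate_id,
                          label = NULL),
                     class = "smp_features"))
  }
  o <- order(pooled$mz)
  pooled <- pooled[o, ]
  # greedy width-bounded clustering along sorted m/z
  eps <- 1e-9
  cl <- integer(nrow(pooled))
  cur <- 1L
  start_mz <- pooled$mz[1]
  cl[1] <- 1L
  for (i in seq_len(nrow(pooled))[-1]) {
    if (pooled$mz[i] - start_mz > mz_tolerance + eps) {
      cur <- cur + 1L
      start_mz <- pooled$mz[i]
    }
    cl[i] <- cur
  }
  keep_mz <- numeric(0)
  cols <- list()
  for (k in seq_len(cur)) {
    rows <- which(cl == k)
    present <- unique(pooled$spec[rows])
    if (length(present) + eps < min_fraction * n_spec) next
    v <- numeric(n_spec)
    for (r in rows) {
      s <- pooled$spec[r]
      v[s] <- max(v[s], pooled$intensity[r])
    }
    keep_mz <- c(keep_mz, stats::weighted.mean(pooled$mz[rows], pooled$intensity[rows]))
    cols[[length(cols) + 1L]] <- v
  }
  values <- if (length(cols)) do.call(cbind, cols) else matrix(0, n_spec, 0)
  o2 <- order(keep_mz)
  structure(
    list(values = values[, o2, drop = FALSE], feature_mz = keep_mz[o2],
         sample_id = sample_id, replicate_id = replicate_id, label = NULL),
    class = "smp_features"
  )
}

#' @export
print.smp_features <- function(x, ...) {
  cat(sprintf("SMP feature matrix: %d spectra x %d m/z features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$label)) cat("labels:", paste(names(table(x$label)),
                                              table(x$label), collapse = ", "), "\n")
  invisible(x)
}

#' Extract SMPs from a set of spectra
#'
#' Convenience wrapper running [detect_peaks()], [estimate_snr()],
#' [filter_by_snr()] and [align_features()] over a list of spectra.
#'
#' @param spectra list of `smp_spectrum` objects.
#' @param window_points,snr_threshold,mz_tolerance,min_fraction see the
#'   stage functions.
#' @param snr_exclude,snr_local [estimate_snr()] window half-widths in grid
#'   points; scale them down for coarse (binned) grids.
#' @param labels optional per-spectrum class labels carried into the result.
#' @return an `smp_features` object.
#' @export
extract_smp <- function(spectra, window_points = 5, snr_threshold = 3,
                        mz_tolerance = 0.1, min_fraction = 0.5,
                        snr_exclude = 10, snr_local = 150,
                        labels = NULL) {
  pls <- lapply(spectra, function(sp) {
    pk <- detect_peaks(sp, window_points)
    pk <- estimate_snr(sp, pk, exclude_halfwidth = snr_exclude,
                       local_halfwidth = snr_local)
    filter_by_snr(pk, snr_threshold)
  })
  fm <- align_features(pls, mz_tolerance, min_fraction)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(spectra))
    fm$label <- labels
  }
  fm
}
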