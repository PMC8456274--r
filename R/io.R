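# Spectrum and feature-matrix I/O. CSV is the native interchange format;
# mzML is supported through the mzR Bioconductor backend when installed.

#' Read a spectrum from disk
#'
#' @param path file path.
#' @param format `"csv"` (two columns, `mz,intensity`) or `"mzml"`
#'   (MS level 1; requires the mzR package).
#' @param ... metadata passed to the spectrum constructor.
#' @return an `smp_spectrum`.
#' @export
read_spectrum <- function(path, format = c("csv", "mzml"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path),
                   error = function(e) stop_invalid("malformed CSV %s: %s",
                                                    path, conditionMessage(e)))
    if (!all(c("mz", "intensity") %in% names(df))) {
      stop_invalid("%s: expected columns 'mz' and 'intensity'", path)
    }
    if (anyNA(df$mz) || anyNA(df$intensity)) {
      stop_invalid("%s: missing values in mz/intensity", path)
    }
    new_spectrum(df$mz, df$intensity, ...)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop_invalid("mzML support requires the mzR package")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, 1)
    new_spectrum(pk[, 1], pk[, 2], ...)
  }
}

#' Write a spectrum to disk
#'
#' @param spectrum an `smp_spectrum`.
#' @param path destination path.
#' @param format `"csv"` or `"mzml"` (profile MS level 1 via mzR).
#' @return the path, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("csv", "mzml")) {
  format <- match.arg(format)
  stopifnot(inherits(spectrum, "smp_spectrum"))
  if (format == "csv") {
    utils::write.csv(data.frame(mz = spectrum$mz,
                                intensity = spectrum$intensity),
                     path, row.names = FALSE)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop_invalid("mzML support requires the mzR package")
    }
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
      peaksCount = length(spectrum$mz), totIonCurrent = sum(spectrum$intensity),
      retentionTime = 0, basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
      basePeakIntensity = max(spectrum$intensity), collisionEnergy = 0,
      ionisationEnergy = 0, lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
      centroided = FALSE, ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
      scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
    mzR::writeMSData(list(cbind(spectrum$mz, spectrum$intensity)), path,
                     header = hdr, outformat = "mzml")
  }
  invisible(path)
}

#' Write / read an SMP feature matrix as CSV
#'
#' The CSV carries one row per (sample, replicate) spectrum: `sample_id`,
#' `replicate_id`, `label`, then one column per consensus m/z feature.
#'
#' @param fm an `smp_features` object.
#' @param path destination path.
#' @return the path (write) or an `smp_features` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "smp_features"))
  df <- data.frame(sample_id = fm$sample_id, replicate_id = fm$replicate_id,
                   label = fm$label %||% NA_character_, check.names = FALSE)
  vals <- fm$values
  colnames(vals) <- sprintf("%.5f", fm$feature_mz)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("sample_id", "replicate_id", "label")
  if (!all(meta %in% names(df))) {
    stop_invalid("%s is not a feature-matrix CSV", path)
  }
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  structure(
    list(values = unname(vals),
         feature_mz = as.numeric(colnames(vals)),
         sample_id = df$sample_id, replicate_id = df$replicate_id,
         label = if (all(is.na(df$label))) NULL else df$label),
    class = "smp_features"
  )
}
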