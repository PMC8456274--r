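# Metabolite panels and cohorts: the ground truth behind every simulated
# spectrum. A panel fixes where features sit on the m/z axis and which of
# them carry a disease effect; a cohort draws per-subject abundances around
# the class means.

#' Define a synthetic metabolite panel
#'
#' Creates the ground-truth feature panel used by the spectrum simulator:
#' `n_features` metabolite species at strictly increasing m/z positions, of
#' which `n_biomarkers` are class-discriminating. `n_up` biomarkers are
#' up-regulated in cases (positive log2 fold change) and the rest are
#' down-regulated, matching the typical serum-metabolic finding of a small
#' directional biomarker set (e.g. five up, one down).
#'
#' Base abundances are drawn once per panel on a log2 scale spanning roughly
#' 45-250 raw intensity units, so that genuine features sit well above the
#' chemical-noise regime.
#'
#' @param n_features number of m/z features in the panel.
#' @param n_biomarkers number of features carrying a class effect.
#' @param effect_log2fc absolute log2 fold change (case vs control) of the
#'   biomarkers; scalar or length-`n_biomarkers` vector.
#' @param n_up how many biomarkers are up-regulated in cases; the remaining
#'   `n_biomarkers - n_up` are down-regulated.
#' @param seed integer seed; panels are deterministic given the seed.
#' @param mz_range numeric length 2, m/z interval holding the features (Da).
#' @param min_spacing minimum spacing between adjacent feature centers (Da).
#' @param base_log2_range range of base log2 abundances.
#' @param ionization_spread half-width of the per-feature relative ionization
#'   variability multiplier; each feature's per-shot CV is the acquisition
#'   `shot_cv` times a factor drawn uniformly in
#'   `1 +/- ionization_spread`. Set 0 for homogeneous ionization.
#' @return an object of class `smp_panel`: a list with a `features` data frame
#'   (`mz`, `base_log2`, `ionization_cv`, `is_biomarker`, `effect_log2fc`,
#'   `direction`) and `n_features`.
#' @examples
#' pan <- make_panel(35, 6, 1.0, 5, seed = 1)
#' table(pan$features$direction)
#' @export
make_panel <- function(n_features = 35, n_biomarkers = 6, effect_log2fc = 1,
                       n_up = 5, seed = 1, mz_range = c(100, 1000),
                       min_spacing = 2, base_log2_range = c(5.5, 8),
                       ionization_spread = 0.1) {
  if (n_features < 1) stop_invalid("n_features must be >= 1")
  if (n_biomarkers > n_features) {
    stop_invalid("n_biomarkers (%d) must not exceed n_features (%d)",
                 n_biomarkers, n_features)
  }
  if (n_up > n_biomarkers) {
    stop_invalid("n_up (%d) must not exceed n_biomarkers (%d)", n_up, n_biomarkers)
  }
  if (n_biomarkers > 0 && any(effect_log2fc <= 0)) {
    stop_invalid("effect_log2fc must be positive (direction is set by n_up)")
  }
  stopifnot(length(mz_range) == 2L, mz_range[1] < mz_range[2])

  feats <- local_seed(seed, {
    # uniform order statistics shifted by the fixed minimum gaps: the exact
    # distribution of uniform points conditioned on all gaps >= min_spacing
    lo <- mz_range[1] + min_spacing
    hi <- mz_range[2] - min_spacing
    slack <- (hi - lo) - (n_features - 1) * min_spacing
    if (slack <= 0) {
      stop_invalid("m/z range too small for %d features at %g Da spacing",
                   n_features, min_spacing)
    }
    mz <- lo + sort(stats::runif(n_features)) * slack +
      (seq_len(n_features) - 1) * min_spacing
    base <- stats::runif(n_features, base_log2_range[1], base_log2_range[2])
    ion <- stats::runif(n_features, 1 - ionization_spread, 1 + ionization_spread)
    bio_idx <- if (n_biomarkers > 0) sort(sample.int(n_features, n_biomarkers)) else integer(0)
    eff <- numeric(n_features)
    dir <- rep(NA_character_, n_features)
    if (n_biomarkers > 0) {
      fc <- rep_len(abs(effect_log2fc), n_biomarkers)
      up <- rep(c(TRUE, FALSE), c(n_up, n_biomarkers - n_up))
      eff[bio_idx] <- ifelse(up, fc, -fc)
      dir[bio_idx] <- ifelse(up, "up", "down")
    }
    data.frame(
      mz = mz, base_log2 = base, ionization_cv = ion,
      is_biomarker = seq_len(n_features) %in% bio_idx,
      effect_log2fc = eff, direction = dir,
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(features = feats, n_features = n_features,
         n_biomarkers = n_biomarkers, mz_range = mz_range, seed = seed),
    class = "smp_panel"
  )
}

#' @export
print.smp_panel <- function(x, ...) {
  cat(sprintf("Metabolite panel: %d features in m/z [%g, %g], %d biomarkers (%d up / %d down)\n",
              x$n_features, x$mz_range[1], x$mz_range[2], x$n_biomarkers,
              sum(x$features$direction == "up", na.rm = TRUE),
              sum(x$features$direction == "down", na.rm = TRUE)))
  invisible(x)
}

#' Draw a synthetic cohort around a panel
#'
#' Samples per-subject true log2 abundances. Controls are centred on the
#' panel's base abundances; cases are shifted by each biomarker's signed log2
#' fold change. Between-subject biological spread is multiplicative lognormal
#' with the stated coefficient of variation on the raw-intensity scale.
#'
#' @param panel an [make_panel()] object.
#' @param n_control,n_case subject counts per class.
#' @param between_subject_cv between-subject CV of raw abundances (fraction).
#'   The default 0.4 is a typical serum-metabolite biological spread.
#' @param seed integer seed.
#' @param cohort_tag label carried in the result, e.g. `"discovery"`.
#' @return an object of class `smp_cohort`: list with `samples` data frame
#'   (`sample_id`, `label`), `log2_abund` matrix (subjects x features) and the
#'   generating panel.
#' @examples
#' pan <- make_panel(10, 2, 1, 1, seed = 1)
#' coh <- sample_cohort(pan, 5, 5, 0.2, seed = 2)
#' dim(coh$log2_abund)
#' @export
sample_cohort <- function(panel, n_control, n_case, between_subject_cv = 0.4,
                          seed = 1, cohort_tag = "discovery") {
  stopifnot(inherits(panel, "smp_panel"))
  if (n_control < 0 || n_case < 0) stop_invalid("subject counts must be >= 0")
  if (between_subject_cv < 0) stop_invalid("between_subject_cv must be >= 0")
  n <- n_control + n_case
  # lognormal CV on the linear scale -> sd on the log2 scale
  sd_log2 <- sqrt(log1p(between_subject_cv^2)) / log(2)
  f <- panel$features
  ctrl_mean <- f$base_log2
  case_mean <- f$base_log2 + f$effect_log2fc
  lab <- rep(c("control", "case"), c(n_control, n_case))
  ab <- local_seed(seed, {
    mu <- matrix(0, n, panel$n_features)
    if (n_control > 0) mu[seq_len(n_control), ] <- rep(ctrl_mean, each = n_control)
    if (n_case > 0) mu[n_control + seq_len(n_case), ] <- rep(case_mean, each = n_case)
    mu + matrix(stats::rnorm(n * panel$n_features, 0, sd_log2), n, panel$n_features)
  })
  ids <- sprintf("%s_%s%03d", substr(cohort_tag, 1, 1),
                 ifelse(lab == "case", "P", "C"),
                 c(seq_len(n_control), seq_len(n_case)))
  rownames(ab) <- ids
  structure(
    list(samples = data.frame(sample_id = ids, label = lab,
                              stringsAsFactors = FALSE),
         log2_abund = ab, panel = panel, cohort_tag = cohort_tag, seed = seed),
    class = "smp_cohort"
  )
}

#' @export
print.smp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort '%s': %d controls, %d cases, %d panel features\n",
              x$cohort_tag, sum(x$samples$label == "control"),
              sum(x$samples$label == "case"), ncol(x$log2_abund)))
  invisible(x)
}
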