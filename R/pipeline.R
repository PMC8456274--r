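# End-to-end orchestration: simulation -> binning -> (optional deep
# stabilization) -> SMP extraction -> diagnosis -> replicate ensemble ->
# MK surface, with a paired no-stabilization / deep-stabilized comparison.

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Defaults describe a desk-scale
#' study: a 35-feature panel with six biomarkers (five up, one down) on a
#' 100-500 Da window, cohorts of 30/30 training and 15/15 test subjects, 10
#' technical replicates per subject at 1000 laser shots, a 512-bin
#' stabilizer, and a 100-model replicate ensemble. Any section can be
#' overridden by passing a named list of replacements.
#'
#' @param seed global seed; per-stage seeds are derived from it by a fixed
#'   offset scheme recorded in the run manifest.
#' @param panel,cohort,acquisition,replicates,stabilizer,extraction,diagnosis
#'   named lists overriding individual defaults in each section.
#' @return object of class `smp_config`.
#' @export
pipeline_config <- function(seed = 1, panel = list(), cohort = list(),
                            acquisition = list(), replicates = list(),
                            stabilizer = list(), extraction = list(),
                            diagnosis = list()) {
  merge <- function(def, user) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop_invalid("unknown config field(s): %s",
                                  paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- list(
    seed = as.integer(seed),
    panel = merge(list(n_features = 35, n_biomarkers = 6, effect_log2fc = 0.6,
                       n_up = 5, mz_range = c(100, 500), min_spacing = 4,
                       base_log2_range = c(5.5, 8)), panel),
    cohort = merge(list(n_train_control = 30, n_train_case = 30,
                        n_test_control = 15, n_test_case = 15,
                        between_subject_cv = 0.4), cohort),
    acquisition = merge(list(n_points = 1024, peak_sigma = 1.2,
                             baseline_level = 5, chemical_noise_density = 0.05,
                             shot_cv = 0.25, gain_cv = 3.3, detector_sd = 8),
                        acquisition),
    replicates = merge(list(n_replicates = 10, n_shots = 1000), replicates),
    stabilizer = merge(list(input_length = 512, n_dense_blocks = 2,
                            layers_per_block = 2, growth_channels = 8,
                            kernel_size = 9, adversarial_weight = 0.01,
                            learning_rate = 1e-2, batch_size = 16,
                            epochs = 25, train_pairs = 160), stabilizer),
    extraction = merge(list(window_points = 3, snr_threshold = 3,
                            mz_tolerance = 1.6, min_fraction = 0.5,
                            snr_exclude = 3, snr_local = 60), extraction),
    diagnosis = merge(list(cv_folds = 5, n_models = 100, cv_max = 0.10),
                      diagnosis)
  )
  structure(cfg, class = "smp_config")
}

# simulate all replicate spectra for a cohort; returns binned matrix rows
# (sample x replicate) plus per-sample reference vectors (mean of replicates,
# the high-shot-equivalent aggregate)
.simulate_binned <- function(cohort, panel, acq, n_replicates, n_shots,
                             input_length, seed) {
  n <- nrow(cohort$log2_abund)
  rows <- vector("list", n * n_replicates)
  sample_id <- character(n * n_replicates)
  replicate_id <- integer(n * n_replicates)
  label <- character(n * n_replicates)
  bin_mz <- NULL
  k <- 0L
  refs <- vector("list", n)
  for (i in seq_len(n)) {
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      sp <- simulate_spectrum(cohort$log2_abund[i, ], panel, acq, n_shots,
                              seed = seed + 1000L * i + r,
                              sample_id = cohort$samples$sample_id[i],
                              replicate_id = r)
      bv <- bin_spectrum(sp, input_length)
      if (is.null(bin_mz)) bin_mz <- attr(bv, "bin_mz")
      reps[[r]] <- as.numeric(bv)
      k <- k + 1L
      rows[[k]] <- reps[[r]]
      sample_id[k] <- cohort$samples$sample_id[i]
      replicate_id[k] <- r
      label[k] <- cohort$samples$label[i]
    }
    refs[[i]] <- colMeans(do.call(rbind, reps))
  }
  list(binned = do.call(rbind, rows), sample_id = sample_id,
       replicate_id = replicate_id, label = label, refs = refs,
       ref_sample_id = cohort$samples$sample_id,
       ref_label = cohort$samples$label, bin_mz = bin_mz)
}

.extract_from_binned <- function(binned, bin_mz, sample_id, replicate_id,
                                 label, ext) {
  spectra <- lapply(seq_len(nrow(binned)), function(i) {
    new_spectrum(bin_mz, pmax(binned[i, ], 0), sample_id = sample_id[i],
                 replicate_id = replicate_id[i])
  })
  extract_smp(spectra, window_points = ext$window_points,
              snr_threshold = ext$snr_threshold,
              mz_tolerance = ext$mz_tolerance,
              min_fraction = ext$min_fraction,
              snr_exclude = ext$snr_exclude, snr_local = ext$snr_local,
              labels = label)
}

# analyse one mode end-to-end given binned spectra for train and test
.analyse_mode <- function(tr, te, cfg, seed) {
  ext <- cfg$extraction
  all_binned <- rbind(tr$binned, te$binned)
  fm <- .extract_from_binned(all_binned, tr$bin_mz,
                             c(tr$sample_id, te$sample_id),
                             c(tr$replicate_id, te$replicate_id),
                             c(tr$label, te$label), ext)
  ntr <- length(tr$sample_id)
  idx_tr <- seq_len(ntr)
  subset_fm <- function(idx) {
    structure(list(values = fm$values[idx, , drop = FALSE],
                   feature_mz = fm$feature_mz,
                   sample_id = fm$sample_id[idx],
                   replicate_id = fm$replicate_id[idx],
                   label = fm$label[idx]),
              class = "smp_features")
  }
  fm_tr <- subset_fm(idx_tr)
  fm_te <- subset_fm(setdiff(seq_len(nrow(fm$values)), idx_tr))

  # per-sample replicate means for cross-validation and the blind test
  tr_mean <- .pick_replicates(fm_tr, mean = TRUE)
  te_mean <- .pick_replicates(fm_te, mean = TRUE)
  cv_enet <- cross_validate(tr_mean$x, tr_mean$labels, k = cfg$diagnosis$cv_folds,
                            model = "enet", seed = seed)
  cv_opls <- cross_validate(tr_mean$x, tr_mean$labels, k = cfg$diagnosis$cv_folds,
                            model = "oplsda", seed = seed)
  blind_fit <- fit_elastic_net(tr_mean$x, tr_mean$labels, seed = seed)
  blind <- compute_metrics(predict(blind_fit, te_mean$x), te_mean$labels,
                           ci_bootstraps = 200, seed = seed)

  if (max(table(fm_tr$sample_id)) < 2) {
    stop_invalid("MK-surface stage needs >= 2 technical replicates per sample")
  }
  ens <- fit_replicate_models(fm_tr, n_models = cfg$diagnosis$n_models,
                              seed = seed)
  screen <- screen_biomarkers(tr_mean$x, tr_mean$labels, hits = ens$hits,
                              n_models = ens$n_models)
  screen$feature_mz <- fm$feature_mz
  probs <- predict_replicates(ens, fm_te, seed = seed)
  y_te <- .as_binary(te_mean$labels)
  per_model <- vapply(seq_len(cfg$diagnosis$n_models), function(m) {
    p <- c(probs$control_probs[, m], probs$patient_probs[, m])
    yy <- c(rep(0, nrow(probs$control_probs)), rep(1, nrow(probs$patient_probs)))
    mt <- compute_metrics(p, yy, ci_bootstraps = 0)
    c(auc = mt$auc, sensitivity = mt$sensitivity, specificity = mt$specificity)
  }, numeric(3))
  surface <- build_surface(probs)
  sel <- select_threshold(surface, cfg$diagnosis$cv_max)

  list(feature_matrix = fm, n_features = ncol(fm$values),
       cv_enet = cv_enet, cv_oplsda = cv_opls, blind = blind,
       ensemble = ens, screen = screen, probs = probs,
       metric_cv = apply(per_model, 1, cv_stat),
       metric_mean = rowMeans(per_model),
       surface = surface, vus = surface$vus, threshold = sel)
}

#' Run the full diagnostic pipeline
#'
#' Simulates discovery and validation cohorts with technical replicates,
#' optionally trains and applies the deep stabilizer, extracts SMPs, fits
#' and cross-validates the classifiers, screens biomarkers, builds the
#' replicate-model ensemble and the MK surface, and reports the
#' no-stabilization versus deep-stabilized comparison.
#'
#' @param config an [pipeline_config()] object.
#' @param mode `"both"` (default), `"no_stabilization"` or
#'   `"deep_stabilized"`.
#' @param output_dir optional directory for CSV artifacts and the run
#'   manifest.
#' @return object of class `smp_run`: per-mode results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("both", "no_stabilization", "deep_stabilized"),
                         output_dir = NULL) {
  stopifnot(inherits(config, "smp_config"))
  mode <- match.arg(mode)
  t0 <- Sys.time()
  if (config$replicates$n_replicates < 2) {
    stop_invalid("insufficient replicates: the MK-surface stage needs >= 2 technical replicates per sample")
  }
  pan <- do.call(make_panel, c(config$panel,
                               list(seed = stage_seed(config$seed, "panel"))))
  acq <- do.call(acquisition_config,
                 c(list(mz_min = config$panel$mz_range[1],
                        mz_max = config$panel$mz_range[2]),
                   config$acquisition))
  coh_tr <- sample_cohort(pan, config$cohort$n_train_control,
                          config$cohort$n_train_case,
                          config$cohort$between_subject_cv,
                          seed = stage_seed(config$seed, "cohort"),
                          cohort_tag = "discovery")
  coh_te <- sample_cohort(pan, config$cohort$n_test_control,
                          config$cohort$n_test_case,
                          config$cohort$between_subject_cv,
                          seed = stage_seed(config$seed, "cohort") + 1L,
                          cohort_tag = "validation")
  L <- config$stabilizer$input_length
  tr <- .simulate_binned(coh_tr, pan, acq, config$replicates$n_replicates,
                         config$replicates$n_shots, L,
                         stage_seed(config$seed, "acquisition"))
  te <- .simulate_binned(coh_te, pan, acq, config$replicates$n_replicates,
                         config$replicates$n_shots, L,
                         stage_seed(config$seed, "acquisition") + 500000L)

  modes <- if (mode == "both") c("no_stabilization", "deep_stabilized") else mode
  results <- list()
  stab_model <- NULL
  for (md in modes) {
    if (md == "no_stabilization") {
      results[[md]] <- .analyse_mode(tr, te, config,
                                     stage_seed(config$seed, "mk"))
    } else {
      if (is.null(stab_model)) {
        scfg <- stabilizer_config(
          input_length = L,
          n_dense_blocks = config$stabilizer$n_dense_blocks,
          layers_per_block = config$stabilizer$layers_per_block,
          growth_channels = config$stabilizer$growth_channels,
          kernel_size = config$stabilizer$kernel_size,
          adversarial_weight = config$stabilizer$adversarial_weight,
          learning_rate = config$stabilizer$learning_rate,
          batch_size = config$stabilizer$batch_size,
          epochs = config$stabilizer$epochs,
          seed = stage_seed(config$seed, "stabilizer"))
        ref_of <- match(tr$sample_id, tr$ref_sample_id)
        pair_idx <- local_seed(scfg$seed, {
          sample_exact(seq_len(nrow(tr$binned)),
                       min(config$stabilizer$train_pairs, nrow(tr$binned)))
        })
        pairs <- lapply(pair_idx, function(i) {
          list(low = tr$binned[i, ], high = tr$refs[[ref_of[i]]])
        })
        stab_model <- train_stabilizer(pairs, scfg)
      }
      tr_s <- tr; te_s <- te
      tr_s$binned <- stabilize(stab_model, tr$binned)
      te_s$binned <- stabilize(stab_model, te$binned)
      results[[md]] <- .analyse_mode(tr_s, te_s, config,
                                     stage_seed(config$seed, "mk"))
      results[[md]]$stabilizer <- stab_model
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("smpdx")),
    seed = config$seed,
    stage_seeds = vapply(names(.seed_offsets), function(s) {
      stage_seed(config$seed, s)
    }, integer(1)),
    config = unclass(config),
    modes = modes,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out <- structure(list(results = results, config = config,
                        manifest = manifest, panel = pan),
                   class = "smp_run")
  if (!is.null(output_dir)) .write_run_artifacts(out, output_dir)
  out
}

.write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (md in names(run$results)) {
    r <- run$results[[md]]
    write_feature_matrix(r$feature_matrix,
                         file.path(dir, paste0("features_", md, ".csv")))
    utils::write.csv(r$surface$rows,
                     file.path(dir, paste0("mk_surface_", md, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(r$screen),
                     file.path(dir, paste0("biomarkers_", md, ".csv")),
                     row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    dput(run$manifest, file.path(dir, "manifest.R"))
  }
  invisible(dir)
}

#' @export
print.smp_run <- function(x, ...) {
  cat("Serum-metabolic diagnosis pipeline run\n")
  cat(sprintf("seed %d; modes: %s\n\n", x$config$seed,
              paste(names(x$results), collapse = ", ")))
  tab <- do.call(rbind, lapply(names(x$results), function(md) {
    r <- x$results[[md]]
    data.frame(
      mode = if (md == "no_stabilization") "N" else "D",
      features = r$n_features,
      cv_auc = sprintf("%.0f%%/%.2f", 100 * r$metric_cv["auc"],
                       r$metric_mean["auc"]),
      cv_sens = sprintf("%.0f%%/%.2f", 100 * r$metric_cv["sensitivity"],
                        r$metric_mean["sensitivity"]),
      cv_spec = sprintf("%.0f%%/%.2f", 100 * r$metric_cv["specificity"],
                        r$metric_mean["specificity"]),
      vus = sprintf("%.3f", r$vus),
      threshold = if (r$threshold$qualified) {
        sprintf("%dth", r$threshold$percentile)
      } else "none",
      sens_at_cv10 = if (r$threshold$qualified) {
        sprintf("%.2f", r$threshold$sensitivity)
      } else "-",
      screened = sum(r$screen$passes_screen))
  }))
  names(tab) <- c("stabilizer", "features", "CV/AUC", "CV/sens", "CV/spec",
                  "VUS", "threshold", "sens@CV<10%", "biomarkers")
  print(tab, row.names = FALSE)
  invisible(x)
}
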