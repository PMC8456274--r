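# Replicate-model ensembles ("blinded inter-replication combinations"):
# each ensemble member is an elastic net trained on one random assignment
# of technical replicates to individuals. Their spread across members is
# the raw material of the MK surface and of the hit-frequency screen.

# collapse an smp_features object to one row per sample using one randomly
# chosen replicate per sample (or the replicate mean when mean = TRUE)
.pick_replicates <- function(fm, mean = FALSE) {
  ids <- unique(fm$sample_id)
  rows <- vapply(ids, function(s) {
    cand <- which(fm$sample_id == s)
    if (length(cand) == 1L || mean) cand[1] else sample_exact(cand, 1)
  }, integer(1))
  if (mean) {
    vals <- t(vapply(ids, function(s) {
      colMeans(fm$values[fm$sample_id == s, , drop = FALSE])
    }, numeric(ncol(fm$values))))
  } else {
    vals <- fm$values[rows, , drop = FALSE]
  }
  lab <- fm$label[rows]
  list(x = vals, labels = lab, sample_id = ids)
}

#' Fit an ensemble of replicate-combination models
#'
#' Fits `n_models` elastic nets, each trained on one random assignment of a
#' technical replicate to every training individual. Hyperparameters
#' (`alpha`, `lambda`) are selected once by inner cross-validation on the
#' replicate-mean matrix and then held fixed across the ensemble, so the
#' ensemble spread reflects acquisition variation, not tuning noise.
#'
#' @param fm an `smp_features` object whose rows are (sample, replicate)
#'   spectra, with `label` and `replicate_id` filled.
#' @param n_models ensemble size (default 100).
#' @param seed integer seed.
#' @return object of class `smp_ensemble`: the fitted `models`, per-feature
#'   `hits` (nonzero-coefficient counts), and the shared hyperparameters.
#' @export
fit_replicate_models <- function(fm, n_models = 100, seed = 1) {
  stopifnot(inherits(fm, "smp_features"))
  if (is.null(fm$label)) stop_invalid("feature matrix has no labels")
  base <- .pick_replicates(fm, mean = TRUE)
  ref <- fit_elastic_net(base$x, base$labels, seed = seed)
  models <- local_seed(stage_seed(seed, "ensemble"), {
    lapply(seq_len(n_models), function(m) {
      pk <- .pick_replicates(fm)
      fit_elastic_net(pk$x, pk$labels, alpha = ref$alpha, lambda = ref$lambda)
    })
  })
  nz <- lapply(models, function(m) which(m$coef[-1] != 0))
  structure(
    list(models = models, hits = tabulate(unlist(nz), nbins = ncol(fm$values)),
         alpha = ref$alpha, lambda = ref$lambda, n_models = n_models,
         reference_fit = ref, seed = seed),
    class = "smp_ensemble"
  )
}

#' @export
print.smp_ensemble <- function(x, ...) {
  cat(sprintf("Replicate-model ensemble: %d elastic nets (alpha %.2f, lambda %.4g)\n",
              x$n_models, x$alpha, x$lambda))
  cat(sprintf("features hit by > 60%% of models: %d\n",
              sum(x$hits > 0.6 * x$n_models)))
  invisible(x)
}

#' Predict test individuals under every ensemble member
#'
#' Each model predicts every test individual from one randomly drawn
#' technical replicate (drawn per model, mirroring blinded replicate
#' combinations at prediction time). Returns the replicate-probability
#' container consumed by [build_surface()].
#'
#' @param ensemble an `smp_ensemble`.
#' @param fm_test `smp_features` for the test individuals (rows =
#'   (sample, replicate) spectra, labels filled).
#' @param seed integer seed for the per-model replicate draws.
#' @return an [replicate_probabilities()] object.
#' @export
predict_replicates <- function(ensemble, fm_test, seed = 1) {
  stopifnot(inherits(ensemble, "smp_ensemble"), inherits(fm_test, "smp_features"))
  ids <- unique(fm_test$sample_id)
  lab <- vapply(ids, function(s) fm_test$label[match(s, fm_test$sample_id)],
                fm_test$label[1])
  y <- .as_binary(lab)
  P <- local_seed(stage_seed(seed, "ensemble") + 7L, {
    vapply(seq_along(ensemble$models), function(m) {
      pk <- .pick_replicates(fm_test)
      pr <- predict(ensemble$models[[m]], pk$x)
      pr[match(ids, pk$sample_id)]
    }, numeric(length(ids)))
  })
  replicate_probabilities(P[y == 0, , drop = FALSE],
                          P[y == 1, , drop = FALSE])
}
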