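# The diagnosis variation characteristic (DVC / MK) surface: percentile
# thresholds on healthy-control probabilities, per-threshold diagnostic
# performance and its coefficient of variation across replicate models, the
# 3D CV-over-(specificity, sensitivity) surface, its volume (VUS), and
# CV-constrained threshold selection.

#' Bundle replicate-model probabilities
#'
#' Container for the predicted disease probabilities of every individual
#' under each of an ensemble of replicate models (e.g. 100 elastic nets
#' trained on different technical-replicate assignments).
#'
#' @param control_probs controls x models matrix of probabilities.
#' @param patient_probs patients x models matrix.
#' @param model_ids optional model identifiers.
#' @return object of class `smp_replicate_probs`.
#' @export
replicate_probabilities <- function(control_probs, patient_probs,
                                    model_ids = NULL) {
  control_probs <- as.matrix(control_probs)
  patient_probs <- as.matrix(patient_probs)
  if (ncol(control_probs) != ncol(patient_probs)) {
    stop_invalid("control and patient matrices must have equal model counts")
  }
  if (ncol(control_probs) < 2) stop_invalid("need >= 2 replicate models")
  if (anyNA(control_probs) || anyNA(patient_probs)) {
    stop_invalid("probability matrices must be complete")
  }
  rng <- range(control_probs, patient_probs)
  if (rng[1] < 0 || rng[2] > 1) stop_invalid("probabilities must lie in [0, 1]")
  structure(
    list(control_probs = control_probs, patient_probs = patient_probs,
         model_ids = model_ids %||% paste0("m", seq_len(ncol(control_probs)))),
    class = "smp_replicate_probs"
  )
}

#' @export
print.smp_replicate_probs <- function(x, ...) {
  cat(sprintf("Replicate probabilities: %d controls, %d patients, %d models\n",
              nrow(x$control_probs), nrow(x$patient_probs),
              ncol(x$control_probs)))
  invisible(x)
}

#' Percentile threshold of control probabilities
#'
#' The empirical nth percentile (linear-interpolation convention, or the
#' exclusive-rank convention behind a flag) of the healthy-control predicted
#' probabilities; individuals strictly above it are called positive.
#'
#' @param control_probs numeric vector of control probabilities.
#' @param n percentile in 1..100.
#' @param convention `"linear"` (default) or `"exclusive"` (type-6 rank).
#' @return a single probability threshold.
#' @examples
#' percentile_threshold(seq(0.1, 1, by = 0.1), 50)  # 0.55
#' @export
percentile_threshold <- function(control_probs, n, convention = c("linear", "exclusive")) {
  convention <- match.arg(convention)
  if (!length(control_probs)) stop_invalid("control_probs is empty")
  if (n < 1 || n > 100) stop_invalid("percentile n must lie in 1..100")
  type <- if (convention == "linear") 7 else 6
  as.numeric(stats::quantile(control_probs, n / 100, type = type, names = FALSE))
}

#' Per-model labels and performance at one percentile
#'
#' For each replicate model, the threshold is that model's own nth control
#' percentile; patients strictly above it are labelled positive. Reports the
#' per-model sensitivity vector, the mean specificity across models, and the
#' patients x models binary label matrix.
#'
#' @param probs an [replicate_probabilities()] object.
#' @param n percentile in 1..100.
#' @param convention percentile convention, see [percentile_threshold()].
#' @return list with `sensitivity` (per model), `specificity` (scalar),
#'   `labels` (patients x models 0/1), `thresholds` (per model).
#' @export
labels_and_performance <- function(probs, n, convention = "linear") {
  stopifnot(inherits(probs, "smp_replicate_probs"))
  M <- ncol(probs$control_probs)
  thr <- vapply(seq_len(M), function(m) {
    percentile_threshold(probs$control_probs[, m], n, convention)
  }, numeric(1))
  lab <- sweep(probs$patient_probs, 2, thr, ">") * 1L
  sens <- colMeans(lab)
  spec <- mean(vapply(seq_len(M), function(m) {
    mean(probs$control_probs[, m] <= thr[m])
  }, numeric(1)))
  list(sensitivity = sens, specificity = spec, labels = lab, thresholds = thr)
}

#' Build the MK (diagnosis variation characteristic) surface
#'
#' Scans percentiles n = 1..100 of the control probabilities. At each
#' percentile the replicate models yield per-patient binary labels; the
#' surface records the threshold (mean across models), the specificity, the
#' mean sensitivity, and the diagnostic CV. By default the CV at a
#' percentile is the CV of the per-model sensitivities
#' (`cv_mode = "sensitivity"`, the clinical-assay convention; bounded for
#' any data). The alternative `"labels"` mode reports the mean over
#' patients of the CV of each patient's predicted labels across models;
#' note it grows without bound for patients whose positive rate approaches
#' zero, so surfaces from sparse positives are dominated by those
#' patients.
#'
#' @param probs an [replicate_probabilities()] object.
#' @param cv_mode `"sensitivity"` (default) or `"labels"`.
#' @param convention percentile convention, see [percentile_threshold()].
#' @return object of class `smp_mk_surface`: data frame `rows` (percentile,
#'   threshold, specificity, sensitivity, cv), the per-model sensitivity
#'   matrix, the scalar `vus`, and the settings used.
#' @export
build_surface <- function(probs, cv_mode = c("sensitivity", "labels"),
                          convention = "linear") {
  stopifnot(inherits(probs, "smp_replicate_probs"))
  cv_mode <- match.arg(cv_mode)
  rows <- vector("list", 100)
  sens_models <- matrix(NA_real_, 100, ncol(probs$control_probs))
  for (n in 1:100) {
    lp <- labels_and_performance(probs, n, convention)
    cv <- if (cv_mode == "labels") {
      mean(apply(lp$labels, 1, cv_stat))
    } else {
      cv_stat(lp$sensitivity)
    }
    sens_models[n, ] <- lp$sensitivity
    rows[[n]] <- data.frame(percentile = n,
                            threshold = mean(lp$thresholds),
                            specificity = lp$specificity,
                            sensitivity = mean(lp$sensitivity),
                            cv = cv)
  }
  rows <- do.call(rbind, rows)
  if (any(diff(rows$threshold) < -1e-12)) {
    stop_invalid("internal error: thresholds not non-decreasing in percentile")
  }
  out <- structure(
    list(rows = rows, sensitivity_per_model = sens_models,
         cv_mode = cv_mode, convention = convention, vus = NA_real_),
    class = "smp_mk_surface"
  )
  out$vus <- vus(out)
  out
}

#' Volume under the MK surface
#'
#' Trapezoidal integration of `cv(n) * sensitivity(n)` against the
#' specificity footprint, with the segment below the smallest observed
#' specificity closed off at the first row's integrand (so a constant-CV,
#' full-sensitivity surface over specificity spanning `[0, 1]` integrates to
#' exactly that constant). Lower is better: 0 means every percentile
#' threshold yields perfectly reproducible labels.
#'
#' @param surface an `smp_mk_surface`.
#' @return a single nonnegative volume.
#' @export
vus <- function(surface) {
  stopifnot(inherits(surface, "smp_mk_surface"))
  r <- surface$rows
  if (anyNA(r$specificity) || anyNA(r$cv)) {
    stop_invalid("surface rows incomplete")
  }
  o <- order(r$specificity)
  s <- r$specificity[o]
  f <- r$cv[o] * r$sensitivity[o]
  if (any(diff(s) < 0)) stop_invalid("specificity not sortable for integration")
  s <- c(0, s)
  f <- c(f[1], f)
  sum(diff(s) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' Select the CV-constrained diagnostic threshold
#'
#' The largest percentile whose diagnostic CV is strictly below `cv_max`
#' (default 10%, the reproducibility limit recommended for clinical
#' diagnostic assays), together with that row's threshold and mean
#' sensitivity.
#'
#' @param surface an `smp_mk_surface`.
#' @param cv_max CV ceiling (fraction).
#' @return list with `percentile`, `threshold`, `sensitivity`,
#'   `specificity` and `qualified`; when no percentile qualifies,
#'   `qualified` is `FALSE` and the other entries are `NA`.
#' @export
select_threshold <- function(surface, cv_max = 0.10) {
  stopifnot(inherits(surface, "smp_mk_surface"))
  ok <- which(surface$rows$cv < cv_max)
  if (!length(ok)) {
    return(list(percentile = NA_integer_, threshold = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                qualified = FALSE))
  }
  i <- max(ok)
  r <- surface$rows[i, ]
  list(percentile = r$percentile, threshold = r$threshold,
       sensitivity = r$sensitivity, specificity = r$specificity,
       qualified = TRUE)
}

#' @export
print.smp_mk_surface <- function(x, ...) {
  cat(sprintf("MK surface (%d models, cv mode '%s'): VUS = %.4g\n",
              ncol(x$sensitivity_per_model), x$cv_mode, x$vus))
  sel <- select_threshold(x)
  if (sel$qualified) {
    cat(sprintf("CV < 10%% threshold: %dth percentile, sensitivity %.3f\n",
                sel$percentile, sel$sensitivity))
  } else {
    cat("no percentile achieves CV < 10%\n")
  }
  invisible(x)
}

#' @export
plot.smp_mk_surface <- function(x, ...) {
  r <- x$rows
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(r$specificity, r$cv, type = "l", xlab = "specificity",
                 ylab = "diagnostic CV", ...)
  graphics::abline(h = 0.10, lty = 2)
  graphics::plot(r$specificity, r$sensitivity, type = "l",
                 xlab = "specificity", ylab = "mean sensitivity", ...)
  invisible(x)
}
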