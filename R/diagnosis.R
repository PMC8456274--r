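# Profile recognition and biomarker screening: sparse (elastic net)
# logistic classification, an OPLS-DA baseline, ROC/PRC metrics with
# bootstrap confidence intervals, stratified cross-validation, a label
# permutation test, and the multi-restriction biomarker screen.

.as_xy <- function(x, labels = NULL) {
  if (inherits(x, "smp_features")) {
    if (is.null(labels)) labels <- x$label
    fmz <- x$feature_mz
    x <- x$values
    colnames(x) <- sprintf("mz_%.4f", fmz %||% seq_len(ncol(x)))
  }
  x <- as.matrix(x)
  if (is.null(labels)) stop_invalid("class labels are required")
  y <- .as_binary(labels)
  if (nrow(x) != length(y)) stop_invalid("labels must match matrix rows")
  list(x = x, y = y)
}

# binary labels as 0/1 with "case" (or the second level) = 1
.as_binary <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  f <- as.factor(labels)
  lev <- levels(f)
  if (length(lev) > 2) stop_invalid("labels must be binary")
  if ("case" %in% lev) as.integer(f == "case") else as.integer(f) - 1L
}

.stratified_folds <- function(y, k, seed) {
  local_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample_exact(which(y == cls), sum(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit a sparse logistic (elastic net) classifier
#'
#' Logistic elastic net on an SMP feature matrix. The mixing parameter
#' `alpha` and penalty `lambda` are selected by inner cross-validation on
#' the training data, scoring every (alpha, lambda) pair by the pooled
#' out-of-fold AUC, unless both are supplied, in which case the fit is
#' direct -- the fast path used for the replicate-model ensembles.
#'
#' @param x feature matrix (samples x features) or an `smp_features` object.
#' @param labels binary class labels (`control`/`case`, a factor, or 0/1).
#' @param cv_folds inner cross-validation folds for hyperparameter choice.
#' @param alpha_grid candidate mixing parameters in (0, 1].
#' @param alpha,lambda optional fixed hyperparameters (both given = no
#'   inner CV).
#' @param nlambda length of the automatic penalty path.
#' @param seed integer seed (fold assignment).
#' @return object of class `smp_enet` with elements `fit` (the glmnet
#'   path), `alpha`, `lambda`, `coef` (named vector incl. intercept) and
#'   `nonzero` (names of active features).
#' @examples
#' \donttest{
#' x <- matrix(rnorm(200), 40); y <- rep(c(0, 1), each = 20)
#' x[, 1] <- x[, 1] + y * 2
#' m <- fit_elastic_net(x, y, seed = 1)
#' head(coef(m))
#' }
#' @export
fit_elastic_net <- function(x, labels = NULL, cv_folds = 5,
                            alpha_grid = seq(0.1, 1, by = 0.1),
                            alpha = NULL, lambda = NULL, nlambda = 100,
                            seed = 1) {
  d <- .as_xy(x, labels)
  if (min(table(d$y)) < 2) stop_invalid("need at least 2 samples per class")
  if (length(unique(d$y)) < 2) stop_invalid("labels are single-class")
  if (is.null(colnames(d$x))) colnames(d$x) <- paste0("f", seq_len(ncol(d$x)))

  if (!is.null(alpha) && !is.null(lambda)) {
    fit <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = alpha,
                          lambda = lambda)
    best <- list(alpha = alpha, lambda = lambda, fit = fit)
  } else {
    # manual inner CV: for each alpha, fit the full-data path, refit it on
    # each training fold, and score every lambda by the pooled out-of-fold
    # AUC (rank form of the Mann-Whitney statistic; fast and well defined
    # even for small folds)
    foldid <- .stratified_folds(d$y, cv_folds, seed)
    best <- list(score = -Inf)
    for (a in alpha_grid) {
      full <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = a,
                             nlambda = nlambda)
      lam <- full$lambda
      oof <- matrix(NA_real_, length(d$y), length(lam))
      for (f in seq_len(cv_folds)) {
        tr <- foldid != f
        # small training folds routinely trip glmnet's sample-size warning
        ff <- suppressWarnings(
          glmnet::glmnet(d$x[tr, , drop = FALSE], d$y[tr],
                         family = "binomial", alpha = a, lambda = lam))
        oof[!tr, ] <- stats::predict(ff, d$x[!tr, , drop = FALSE],
                                     s = lam, type = "response")
      }
      aucs <- apply(oof, 2, .fast_auc, y = d$y)
      j <- which.max(aucs)
      if (aucs[j] > best$score) {
        best <- list(alpha = a, lambda = lam[j], fit = full,
                     score = aucs[j], cv_auc = aucs)
      }
    }
  }
  cf <- as.numeric(stats::coef(best$fit, s = best$lambda))
  names(cf) <- c("(Intercept)", colnames(d$x))
  structure(
    list(fit = best$fit, alpha = best$alpha, lambda = best$lambda,
         coef = cf, nonzero = names(cf)[-1][cf[-1] != 0],
         feature_names = colnames(d$x), model_kind = "elastic_net",
         seed = seed),
    class = "smp_enet"
  )
}

#' @export
coef.smp_enet <- function(object, ...) object$coef

#' @export
predict.smp_enet <- function(object, newdata, ...) {
  if (inherits(newdata, "smp_features")) newdata <- newdata$values
  as.numeric(stats::predict(object$fit, as.matrix(newdata), s = object$lambda,
                            type = "response"))
}

#' @export
print.smp_enet <- function(x, ...) {
  cat(sprintf("Elastic-net SMP classifier: alpha = %.2f, lambda = %.4g, %d/%d nonzero features\n",
              x$alpha, x$lambda, length(x$nonzero), length(x$coef) - 1L))
  invisible(x)
}

#' Fit an OPLS-DA baseline classifier
#'
#' Orthogonal projections to latent structures discriminant analysis by the
#' NIPALS/OSC deflation scheme: `n_orthogonal` components of class-orthogonal
#' variation are removed, then a single predictive PLS component is fitted
#' and its score mapped to a probability through univariate logistic
#' regression. By construction the orthogonal score vectors have zero
#' training-set correlation with the class vector.
#'
#' @param x feature matrix or `smp_features` object.
#' @param labels binary class labels.
#' @param n_orthogonal number of orthogonal components (>= 0).
#' @param scale autoscale columns before fitting (default `TRUE`).
#' @param seed retained for interface symmetry; the fit is deterministic.
#' @return object of class `smp_oplsda` with loadings, weights, scores, and
#'   the logistic mapping.
#' @export
fit_oplsda <- function(x, labels = NULL, n_orthogonal = 1, scale = TRUE,
                       seed = 1) {
  d <- .as_xy(x, labels)
  if (length(unique(d$y)) < 2) stop_invalid("labels are single-class")
  if (min(table(d$y)) < 2) stop_invalid("need at least 2 samples per class")
  X <- as.matrix(d$x)
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1
  Xc <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  rk <- qr(Xc)$rank
  if (n_orthogonal >= rk) {
    stop_invalid("n_orthogonal (%d) must be below the rank of centred X (%d)",
                 n_orthogonal, rk)
  }
  yc <- d$y - mean(d$y)
  W_o <- P_o <- NULL
  T_o <- NULL
  for (i in seq_len(n_orthogonal)) {
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    p <- drop(crossprod(Xc, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    no <- sqrt(sum(wo^2))
    if (no < 1e-12) break
    wo <- wo / no
    to <- drop(Xc %*% wo)
    po <- drop(crossprod(Xc, to)) / sum(to^2)
    Xc <- Xc - tcrossprod(to, po)
    W_o <- cbind(W_o, wo); P_o <- cbind(P_o, po); T_o <- cbind(T_o, to)
  }
  w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
  t_pred <- drop(Xc %*% w)
  # perfect separation of the predictive score is legitimate here; the
  # resulting saturated probabilities are still valid ranking scores
  lg <- suppressWarnings(stats::glm(d$y ~ t_pred, family = stats::binomial()))
  structure(
    list(center = ctr, scale = scl, W_o = W_o, P_o = P_o, w_pred = w,
         scores_pred = t_pred, scores_orth = T_o,
         logistic = stats::coef(lg), n_orthogonal = n_orthogonal,
         model_kind = "oplsda", y = d$y),
    class = "smp_oplsda"
  )
}

#' @export
predict.smp_oplsda <- function(object, newdata, ...) {
  if (inherits(newdata, "smp_features")) newdata <- newdata$values
  Xc <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  if (!is.null(object$W_o)) {
    for (i in seq_len(ncol(object$W_o))) {
      to <- drop(Xc %*% object$W_o[, i])
      Xc <- Xc - tcrossprod(to, object$P_o[, i])
    }
  }
  t_pred <- drop(Xc %*% object$w_pred)
  as.numeric(stats::plogis(object$logistic[1] + object$logistic[2] * t_pred))
}

#' @export
print.smp_oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA classifier: 1 predictive + %d orthogonal component(s), %d features\n",
              x$n_orthogonal, length(x$w_pred)))
  invisible(x)
}

# rank-form Mann-Whitney AUC (average ranks handle ties); equals the
# trapezoidal ROC area
.fast_auc <- function(p, y) {
  n1 <- sum(y == 1)
  n0 <- length(y) - n1
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points at every distinct threshold, descending; positives called at
# prob >= threshold. Returns data.frame with threshold, tp, fp, tpr, fpr.
.roc_points <- function(probs, y) {
  o <- order(probs, decreasing = TRUE)
  p <- probs[o]; yy <- y[o]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  idx <- cumsum(rle(p)$lengths)        # block ends (distinct thresholds)
  tp <- cumsum(yy)[idx]
  fp <- (idx - cumsum(yy)[idx])
  data.frame(threshold = p[idx], tp = tp, fp = fp,
             tpr = tp / n1, fpr = fp / n0)
}

#' Diagnostic metrics from predicted probabilities
#'
#' Trapezoidal ROC AUC, step-integrated area under the precision-recall
#' curve, and the operating point nearest the upper-left ROC corner (or the
#' Youden-J optimum), with stratified-bootstrap percentile confidence
#' intervals for the AUC.
#'
#' @param probs predicted disease probabilities in `[0, 1]`.
#' @param labels binary labels; both classes must be present.
#' @param ci_bootstraps bootstrap resamples for the 95% AUC CI (0 skips it).
#' @param seed bootstrap seed.
#' @param operating `"upper_left"` (minimum Euclidean distance to (0,1)) or
#'   `"youden"` (maximum sensitivity + specificity - 1).
#' @return object of class `smp_metrics`: `auc`, `auc_ci`, `auprc`,
#'   `sensitivity`, `specificity`, `threshold` (positives are `prob >=
#'   threshold`).
#' @examples
#' compute_metrics(c(.9, .8, .7, .4, .3, .2), c(1, 1, 1, 0, 0, 0),
#'                 ci_bootstraps = 0)
#' @export
compute_metrics <- function(probs, labels, ci_bootstraps = 2000, seed = 1,
                            operating = c("upper_left", "youden")) {
  operating <- match.arg(operating)
  y <- .as_binary(labels)
  if (any(probs < 0 | probs > 1)) stop_invalid("probs must lie in [0, 1]")
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")
  rp <- .roc_points(probs, y)
  fpr <- c(0, rp$fpr); tpr <- c(0, rp$tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # PRC step integration: sum over recall increments of precision there
  prec <- rp$tp / (rp$tp + rp$fp)
  rec <- c(0, rp$tpr)
  auprc <- sum(diff(rec) * prec)
  dist <- switch(operating,
                 upper_left = sqrt(rp$fpr^2 + (1 - rp$tpr)^2),
                 youden = -(rp$tpr - rp$fpr))
  i <- which.min(dist)
  ci <- c(NA_real_, NA_real_)
  if (ci_bootstraps > 0) {
    i1 <- which(y == 1); i0 <- which(y == 0)
    boots <- local_seed(seed, {
      vapply(seq_len(ci_bootstraps), function(b) {
        bi <- c(sample_exact(i1, length(i1), replace = TRUE),
                sample_exact(i0, length(i0), replace = TRUE))
        rpb <- .roc_points(probs[bi], y[bi])
        f <- c(0, rpb$fpr); t <- c(0, rpb$tpr)
        sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
      }, numeric(1))
    })
    ci <- as.numeric(stats::quantile(boots, c(0.025, 0.975)))
  }
  structure(
    list(auc = auc, auc_ci = ci, auprc = auprc,
         sensitivity = rp$tpr[i], specificity = 1 - rp$fpr[i],
         threshold = rp$threshold[i], operating = operating,
         n_case = sum(y == 1), n_control = sum(y == 0)),
    class = "smp_metrics"
  )
}

#' @export
print.smp_metrics <- function(x, ...) {
  ci <- if (all(is.finite(x$auc_ci))) {
    sprintf(" (95%% CI %.3f-%.3f)", x$auc_ci[1], x$auc_ci[2])
  } else ""
  cat(sprintf("AUC %.3f%s, AUPRC %.3f; sens %.3f / spec %.3f at threshold %.3f (%s)\n",
              x$auc, ci, x$auprc, x$sensitivity, x$specificity, x$threshold,
              x$operating))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds; each fold's model is fitted on the remaining folds
#' (with hyperparameter selection nested inside the training folds for the
#' elastic net) and evaluated on the held-out fold. Reports per-fold and
#' pooled out-of-fold metrics.
#'
#' @param x feature matrix or `smp_features`.
#' @param labels binary labels.
#' @param k number of folds (must not exceed the minority class count).
#' @param model `"enet"` or `"oplsda"`.
#' @param seed integer seed.
#' @param ci_bootstraps bootstrap count for per-fold/pooled CIs.
#' @param ... passed to the fitting function.
#' @return object of class `smp_cv`: `folds` data frame, `pooled` metrics,
#'   out-of-fold probabilities and fold assignment.
#' @export
cross_validate <- function(x, labels = NULL, k = 5,
                           model = c("enet", "oplsda"), seed = 1,
                           ci_bootstraps = 200, ...) {
  model <- match.arg(model)
  d <- .as_xy(x, labels)
  if (k > min(table(d$y))) {
    stop_invalid("k = %d exceeds the minority class count (%d)",
                 k, min(table(d$y)))
  }
  fold <- .stratified_folds(d$y, k, seed)
  oof <- numeric(length(d$y))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fitter <- if (model == "enet") {
      function() fit_elastic_net(d$x[tr, , drop = FALSE], d$y[tr],
                                 seed = seed + f, ...)
    } else {
      function() fit_oplsda(d$x[tr, , drop = FALSE], d$y[tr], ...)
    }
    m <- fitter()
    oof[!tr] <- predict(m, d$x[!tr, , drop = FALSE])
    mt <- compute_metrics(oof[!tr], d$y[!tr], ci_bootstraps = 0)
    rows[[f]] <- data.frame(fold = f, n_test = sum(!tr), auc = mt$auc,
                            sensitivity = mt$sensitivity,
                            specificity = mt$specificity)
  }
  pooled <- compute_metrics(oof, d$y, ci_bootstraps = ci_bootstraps,
                            seed = seed)
  structure(
    list(folds = do.call(rbind, rows), pooled = pooled, oof_probs = oof,
         fold_id = fold, model = model, k = k, seed = seed),
    class = "smp_cv"
  )
}

#' @export
print.smp_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (%s)\n", x$k, x$model))
  print(x$folds, row.names = FALSE)
  cat("pooled out-of-fold: ")
  print(x$pooled)
  invisible(x)
}

#' Label permutation test for classifier validity
#'
#' Re-runs the full cross-validated fitting pipeline on `n_perm` random
#' label permutations and compares the observed pooled out-of-fold AUC with
#' the null distribution. The p-value uses the add-one permutation formula
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param x feature matrix or `smp_features`.
#' @param labels binary labels.
#' @param n_perm number of permutations (>= 19).
#' @param k folds used for each pipeline run.
#' @param model `"enet"` or `"oplsda"`.
#' @param seed integer seed.
#' @param ... passed to [cross_validate()].
#' @return object of class `smp_perm`: `p_value`, `observed_auc`,
#'   `null_auc` vector.
#' @export
permutation_test <- function(x, labels = NULL, n_perm = 99, k = 5,
                             model = "enet", seed = 1, ...) {
  if (n_perm < 19) stop_invalid("n_perm must be >= 19")
  d <- .as_xy(x, labels)
  obs <- cross_validate(d$x, d$y, k = k, model = model, seed = seed,
                        ci_bootstraps = 0, ...)$pooled$auc
  null_auc <- local_seed(seed, {
    perms <- replicate(n_perm, sample_exact(d$y, length(d$y)),
                       simplify = FALSE)
    vapply(seq_len(n_perm), function(i) {
      cross_validate(d$x, perms[[i]], k = k, model = model,
                     seed = seed + i, ci_bootstraps = 0, ...)$pooled$auc
    }, numeric(1))
  })
  p <- (1 + sum(null_auc >= obs)) / (n_perm + 1)
  structure(list(p_value = p, observed_auc = obs, null_auc = null_auc,
                 n_perm = n_perm),
            class = "smp_perm")
}

#' @export
print.smp_perm <- function(x, ...) {
  cat(sprintf("Permutation test: observed AUC %.3f vs %d null fits (median %.3f); p = %.4f\n",
              x$observed_auc, x$n_perm, stats::median(x$null_auc), x$p_value))
  invisible(x)
}

#' Screen biomarkers under multiple restrictions
#'
#' Applies the three-way screen to every feature: independent-samples t-test
#' p-value below `p_threshold`, mean raw intensity in the enriched class
#' above `intensity_threshold`, and a hit frequency (number of replicate
#' elastic-net fits with a nonzero coefficient for the feature) strictly
#' above `hit_threshold`. All three inequalities are strict.
#'
#' @param x feature matrix or `smp_features` (per-sample intensities).
#' @param labels binary labels.
#' @param hits integer vector of per-feature hit counts, or a list of
#'   `smp_enet` fits from which hit counts are derived.
#' @param n_models ensemble size behind `hits` (denominator, default 100).
#' @param p_threshold,intensity_threshold,hit_threshold screen limits.
#' @param welch use Welch's t-test (default); otherwise pooled variance.
#' @return data frame of class `smp_biomarkers` with one row per feature:
#'   `feature_mz`, `p_value`, `mean_case`, `mean_control`, `hit_frequency`,
#'   `direction`, `flagged` (zero-variance fallback) and `passes_screen`.
#' @export
screen_biomarkers <- function(x, labels = NULL, hits, n_models = 100,
                              p_threshold = 0.001, intensity_threshold = 25,
                              hit_threshold = 60, welch = TRUE) {
  fm_mz <- if (inherits(x, "smp_features")) x$feature_mz else NULL
  d <- .as_xy(x, labels)
  if (is.list(hits) && all(vapply(hits, inherits, TRUE, "smp_enet"))) {
    n_models <- length(hits)
    nz <- lapply(hits, function(m) which(m$coef[-1] != 0))
    hits <- tabulate(unlist(nz), nbins = ncol(d$x))
  }
  stopifnot(length(hits) == ncol(d$x))
  case <- d$x[d$y == 1, , drop = FALSE]
  ctrl <- d$x[d$y == 0, , drop = FALSE]
  res <- lapply(seq_len(ncol(d$x)), function(j) {
    a <- case[, j]; b <- ctrl[, j]
    flagged <- FALSE
    p <- tryCatch(
      stats::t.test(a, b, var.equal = !welch)$p.value,
      error = function(e) NA_real_)
    if (is.na(p)) {
      # zero-variance fallback: pooled variance with a floor
      flagged <- TRUE
      sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
      if (!is.finite(sp) || sp == 0) sp <- 1e-12
      tt <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
      p <- 2 * stats::pt(-abs(tt), df = length(a) + length(b) - 2)
    }
    data.frame(p_value = p, mean_case = mean(a), mean_control = mean(b),
               flagged = flagged)
  })
  res <- do.call(rbind, res)
  res$feature_mz <- fm_mz %||% as.numeric(seq_len(ncol(d$x)))
  res$hit_frequency <- as.integer(hits)
  res$direction <- ifelse(res$mean_case > res$mean_control, "up", "down")
  enriched <- pmax(res$mean_case, res$mean_control)
  res$passes_screen <- (res$p_value < p_threshold) &
    (enriched > intensity_threshold) &
    (res$hit_frequency > hit_threshold)
  res <- res[, c("feature_mz", "p_value", "mean_case", "mean_control",
                 "hit_frequency", "direction", "flagged", "passes_screen")]
  structure(res, class = c("smp_biomarkers", "data.frame"),
            n_models = n_models,
            thresholds = c(p = p_threshold, intensity = intensity_threshold,
                           hits = hit_threshold))
}

#' @export
print.smp_biomarkers <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("Biomarker screen (p < %g, enriched mean > %g, hits > %g of %d models): %d/%d pass\n",
              th["p"], th["intensity"], th["hits"], attr(x, "n_models"),
              sum(x$passes_screen), nrow(x)))
  print.data.frame(x[x$passes_screen, , drop = FALSE], row.names = FALSE,
                   digits = 4)
  invisible(x)
}
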