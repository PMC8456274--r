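# Classifiers, metrics, cross-validation, permutation testing and the
# multi-restriction biomarker screen.

# feature matrices built directly from cohort truth plus acquisition-style
# multiplicative noise: fast stand-in for full spectrum simulation
noisy_matrix <- function(cohort, gain_cv = 0.1, peak_cv = 0.03, seed = 1) {
  ab <- cohort$log2_abund
  set.seed(seed)
  g <- exp(rnorm(nrow(ab), 0, gain_cv))
  2^ab * g * matrix(exp(rnorm(length(ab), 0, peak_cv)), nrow(ab))
}

test_that("trapezoidal AUC and the operating point behave on hand cases", {
  m <- compute_metrics(c(.9, .8, .7, .4, .3, .2), c(1, 1, 1, 0, 0, 0),
                       ci_bootstraps = 0)
  expect_equal(m$auc, 1.0)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 1.0)
  m2 <- compute_metrics(c(.9, .8, .7, .4, .3, .2), c(1, 1, 0, 1, 0, 0),
                        ci_bootstraps = 0)
  expect_equal(m2$auc, 8 / 9)
  # perfect classifier: AUPRC 1; constant classifier: AUPRC = prevalence
  expect_equal(m$auprc, 1.0)
  mc <- compute_metrics(rep(0.4, 10), c(rep(1, 3), rep(0, 7)), ci_bootstraps = 0)
  expect_equal(mc$auprc, 0.3)
  expect_error(compute_metrics(c(.2, 1.4), c(0, 1)), "\\[0, 1\\]")
  expect_error(compute_metrics(c(.2, .4), c(1, 1)), "both classes")
})

test_that("AUC agrees with the exhaustive Mann-Whitney oracle, ties included", {
  set.seed(31)
  for (r in 1:25) {
    n <- sample(4:9, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), 1)          # coarse grid forces ties
    m <- compute_metrics(p, y, ci_bootstraps = 0)
    expect_equal(m$auc, oracle_auc(p, y), tolerance = 1e-12)
  }
})

test_that("AUC cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  y <- sample(0:1, 60, replace = TRUE, prob = c(.6, .4))
  y[1:2] <- 0:1
  p <- plogis(rnorm(60) + y)
  m <- compute_metrics(p, y, ci_bootstraps = 0)
  expect_equal(m$auc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("bootstrap CI brackets the point AUC", {
  set.seed(33)
  y <- rep(c(0, 1), each = 25)
  p <- plogis(rnorm(50) + 1.5 * y)
  m <- compute_metrics(p, y, ci_bootstraps = 300, seed = 2)
  expect_true(m$auc_ci[1] <= m$auc && m$auc <= m$auc_ci[2])
  expect_true(m$auc_ci[2] - m$auc_ci[1] < 0.5)
})

test_that("elastic net recovers planted biomarkers and flags degenerate input", {
  pan <- make_panel(35, 6, 1.0, 5, seed = 41)
  coh <- sample_cohort(pan, 50, 50, 0.4, seed = 42)
  x <- noisy_matrix(coh, seed = 43)
  y <- coh$samples$label
  fit <- fit_elastic_net(x, y, seed = 44)
  hit <- which(fit$coef[-1] != 0)
  expect_gte(length(intersect(hit, which(pan$features$is_biomarker))), 5)
  expect_error(fit_elastic_net(x, rep("case", 100), seed = 1), "single-class")
  # one perfectly separating feature dominates the coefficients
  set.seed(45)
  x2 <- matrix(rnorm(40 * 5), 40)
  y2 <- rep(c(0, 1), each = 20)
  x2[, 3] <- y2 * 4 + rnorm(40, 0, 0.05)
  f2 <- fit_elastic_net(x2, y2, seed = 46)
  expect_equal(unname(which.max(abs(f2$coef[-1]))), 3L)
})

test_that("permuted labels drive the cross-validated AUC to chance", {
  pan <- make_panel(35, 6, 1.0, 5, seed = 51)
  coh <- sample_cohort(pan, 30, 30, 0.4, seed = 52)
  x <- noisy_matrix(coh, seed = 53)
  set.seed(54)
  y <- sample(coh$samples$label)
  cv <- cross_validate(x, y, k = 5, seed = 55, alpha_grid = c(0.5, 1))
  expect_gt(cv$pooled$auc, 0.30)
  expect_lt(cv$pooled$auc, 0.70)
})

test_that("OPLS-DA deflation is orthogonal to the class and reduces to PLS", {
  pan <- make_panel(20, 4, 0.8, 3, seed = 61)
  coh <- sample_cohort(pan, 25, 25, 0.4, seed = 62)
  x <- noisy_matrix(coh, seed = 63)
  y <- as.integer(coh$samples$label == "case")
  fit <- fit_oplsda(x, y, n_orthogonal = 2)
  for (i in 1:2) {
    expect_lt(abs(cor(fit$scores_orth[, i], y)), 1e-6)
  }
  # n_orthogonal = 0: predictive scores proportional to Xc w, w ~ X'y
  f0 <- fit_oplsda(x, y, n_orthogonal = 0, scale = FALSE)
  Xc <- scale(x, scale = FALSE)
  w <- drop(crossprod(Xc, y - mean(y)))
  w <- w / sqrt(sum(w^2))
  expect_equal(abs(cor(f0$scores_pred, drop(Xc %*% w))), 1, tolerance = 1e-10)
  expect_error(fit_oplsda(x[c(1:3, 26:28), 1:3], y[c(1:3, 26:28)],
               n_orthogonal = 5), "rank")
  pr <- predict(fit, x)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("stratified cross-validation partitions and pools correctly", {
  pan <- make_panel(10, 2, 1.0, 2, seed = 71)
  coh <- sample_cohort(pan, 80, 80, 0.4, seed = 72)
  x <- noisy_matrix(coh, seed = 73)
  y <- coh$samples$label
  cv <- cross_validate(x, y, k = 5, seed = 74, alpha_grid = 0.5,
                       ci_bootstraps = 0)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(abs(cv$folds$n_test - 32) <= 1))
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  mix <- c(1:4, 81:84)
  expect_error(cross_validate(x[mix, ], y[mix], k = 5, seed = 1), "minority")
  # duplicating every row leaves the pooled AUC essentially unchanged
  cv2 <- cross_validate(rbind(x, x), c(y, y), k = 5, seed = 74,
                        alpha_grid = 0.5, ci_bootstraps = 0)
  expect_lt(abs(cv2$pooled$auc - cv$pooled$auc), 0.05)
})

test_that("permutation test p-values follow the add-one formula", {
  pan <- make_panel(8, 2, 1.2, 2, seed = 81)
  coh <- sample_cohort(pan, 16, 16, 0.4, seed = 82)
  x <- noisy_matrix(coh, seed = 83)
  y <- coh$samples$label
  pt <- permutation_test(x, y, n_perm = 19, k = 4, seed = 84,
                         alpha_grid = 0.5)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_auc >= pt$observed_auc)) / 20)
  expect_length(pt$null_auc, 19)
  expect_lte(pt$p_value, 0.05)       # informative cohort: observed beats null
  expect_error(permutation_test(x, y, n_perm = 5, seed = 1), "19")
})

test_that("the biomarker screen applies its three strict restrictions", {
  # constructed feature matrix: per-feature behaviour is forced
  set.seed(91)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(
    a = c(rnorm(n / 2, 30, 2), rnorm(n / 2, 45, 2)),   # passes everything
    b = c(rnorm(n / 2, 30, 2), rnorm(n / 2, 45, 2)),   # fails hit frequency
    c = c(rnorm(n / 2, 10, 1), rnorm(n / 2, 15, 1)),   # fails intensity > 25
    d = rnorm(n, 40, 3),                               # fails p < 0.001
    e = rep(5, n)                                      # zero variance: flagged
  )
  rep_hits <- c(75, 60, 80, 90, 0)
  sc <- screen_biomarkers(x, y, hits = rep_hits, n_models = 100)
  expect_equal(sc$passes_screen, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(sc$flagged[5])
  expect_equal(sc$direction[1], "up")
  expect_equal(sc$hit_frequency, as.integer(rep_hits))
  # boundary: hits exactly 60 of 100 fails the strict inequality
  expect_false(sc$passes_screen[2])
})

test_that("hit counts can be derived from a list of elastic-net fits", {
  set.seed(92)
  x <- matrix(rnorm(40 * 6), 40)
  y <- rep(c(0, 1), each = 20)
  x[, 2] <- x[, 2] + 3 * y
  fits <- lapply(1:5, function(i) {
    fit_elastic_net(x, y, alpha = 0.5, lambda = 0.05)
  })
  sc <- screen_biomarkers(x, y, hits = fits)
  expect_equal(attr(sc, "n_models"), 5)
  expect_equal(sc$hit_frequency[2], 5L)
})
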