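# The MK / diagnosis-variation-characteristic surface and its volume.

test_that("percentile thresholds follow the linear-interpolation convention", {
  x <- seq(0.1, 1.0, by = 0.1)
  expect_equal(percentile_threshold(x, 50), 0.55)
  expect_equal(percentile_threshold(x, 100), max(x))
  for (n in c(1, 17, 50, 83, 100)) {
    expect_equal(percentile_threshold(x, n), oracle_percentile(x, n / 100))
    expect_equal(percentile_threshold(rep(0.4, 7), n), 0.4)
  }
  expect_error(percentile_threshold(x, 0), "1..100")
  expect_error(percentile_threshold(numeric(0), 50), "empty")
})

test_that("cv_stat covers its arithmetic and conventions", {
  expect_equal(cv_stat(c(1, 1, 1, 1)), 0)
  expect_equal(cv_stat(c(8, 12)), sd(c(8, 12)) / 10)
  expect_equal(cv_stat(c(8, 12)), 0.2828427, tolerance = 1e-6)
  expect_equal(cv_stat(c(0, 0, 0)), 0)
  expect_error(cv_stat(c(-1, 1)), "undefined")
  expect_error(cv_stat(numeric(0)), "nonempty")
})

test_that("per-percentile labels and performance match hand enumeration", {
  # separable case
  rp <- replicate_probabilities(matrix(0, 5, 3), matrix(1, 4, 3))
  lp <- labels_and_performance(rp, 50)
  expect_equal(lp$sensitivity, rep(1, 3))
  expect_equal(lp$specificity, 1)
  # identical model columns give a constant sensitivity vector
  set.seed(7)
  cp <- matrix(runif(6), 6, 3)
  pp <- matrix(runif(5), 5, 3)
  lp2 <- labels_and_performance(replicate_probabilities(cp, pp), 30)
  expect_equal(var(lp2$sensitivity), 0)
  # tiny 5 controls x 4 patients x 3 models instance vs brute force
  set.seed(8)
  cp3 <- matrix(runif(15), 5, 3)
  pp3 <- matrix(runif(12), 4, 3)
  rp3 <- replicate_probabilities(cp3, pp3)
  for (n in c(10, 40, 75, 100)) {
    lp3 <- labels_and_performance(rp3, n)
    thr <- vapply(1:3, function(m) oracle_percentile(cp3[, m], n / 100), numeric(1))
    labm <- matrix(0, 4, 3)
    for (m in 1:3) labm[, m] <- as.numeric(pp3[, m] > thr[m])
    expect_equal(unname(lp3$labels), labm)
    expect_equal(lp3$sensitivity, colMeans(labm))
  }
})

test_that("surface and VUS equal brute-force enumeration on small instances", {
  set.seed(9)
  for (r in 1:8) {
    nc <- sample(3:6, 1); np <- sample(2:5, 1); nm <- sample(2:4, 1)
    cp <- matrix(runif(nc * nm), nc, nm)
    pp <- matrix(runif(np * nm), np, nm)
    rp <- replicate_probabilities(cp, pp)
    for (mode in c("sensitivity", "labels")) {
      surf <- build_surface(rp, cv_mode = mode)
      orac <- oracle_surface(cp, pp, cv_mode = mode)
      expect_equal(surf$rows$threshold, orac$threshold, tolerance = 1e-12)
      expect_equal(surf$rows$specificity, orac$specificity, tolerance = 1e-12)
      expect_equal(surf$rows$sensitivity, orac$sensitivity, tolerance = 1e-12)
      expect_equal(surf$rows$cv, orac$cv, tolerance = 1e-12)
      expect_equal(surf$vus, oracle_vus(orac), tolerance = 1e-12)
    }
  }
})

test_that("surface invariants: monotone thresholds, permutation invariance, zero variance", {
  set.seed(10)
  cp <- matrix(runif(40), 10, 4)
  pp <- matrix(runif(32), 8, 4)
  surf <- build_surface(replicate_probabilities(cp, pp))
  expect_true(all(diff(surf$rows$threshold) >= -1e-12))
  expect_true(all(diff(surf$rows$specificity) >= -1e-12))
  # VUS invariant to patient order and model-column permutation
  s2 <- build_surface(replicate_probabilities(cp[, c(3, 1, 4, 2)],
                                              pp[sample(8), c(3, 1, 4, 2)]))
  expect_equal(surf$vus, s2$vus, tolerance = 1e-12)
  # identical columns: deterministic classifier, cv == 0 everywhere, vus 0
  s0 <- build_surface(replicate_probabilities(cp[, c(1, 1, 1)], pp[, c(1, 1, 1)]))
  expect_true(all(s0$rows$cv == 0))
  expect_identical(s0$vus, 0)
})

test_that("uniform patient probabilities give sensitivity about 1 - n/100", {
  set.seed(11)
  cp <- matrix(runif(200 * 4), 200, 4)
  pp <- matrix(runif(400 * 4), 400, 4)
  surf <- build_surface(replicate_probabilities(cp, pp))
  dev <- abs(surf$rows$sensitivity - (1 - surf$rows$percentile / 100))
  expect_lt(max(dev), 0.08)
  expect_lt(mean(dev), 0.03)
})

test_that("VUS closed forms and the CV-constrained threshold selection", {
  forge <- function(spec, sens, cv) {
    structure(list(rows = data.frame(percentile = seq_along(spec),
                                     threshold = seq_along(spec) / 100,
                                     specificity = spec, sensitivity = sens,
                                     cv = cv),
                   sensitivity_per_model = matrix(sens, length(spec), 2),
                   cv_mode = "sensitivity", convention = "linear",
                   vus = NA_real_),
              class = "smp_mk_surface")
  }
  # constant cv, full sensitivity, specificity sweeping [0, 1] -> vus = cv
  s <- forge((1:100) / 100, rep(1, 100), rep(0.37, 100))
  expect_equal(vus(s), 0.37, tolerance = 1e-12)
  s0 <- forge((1:100) / 100, runif(100), rep(0, 100))
  expect_identical(vus(s0), 0)
  # cv(n) = n/100: the largest percentile below a 10% CV is the 9th
  s1 <- forge((1:100) / 100, rep(1, 100), (1:100) / 100)
  sel <- select_threshold(s1, 0.10)
  expect_equal(sel$percentile, 9)
  expect_true(sel$qualified)
  # cv == 0 selects the 100th percentile
  sel0 <- select_threshold(s0)
  expect_equal(sel0$percentile, 100)
  # nothing qualifies
  s2 <- forge((1:100) / 100, rep(1, 100), rep(0.5, 100))
  expect_false(select_threshold(s2, 0.10)$qualified)
})

test_that("replicate-probability containers validate their invariants", {
  expect_error(replicate_probabilities(matrix(0.5, 3, 2), matrix(0.5, 2, 3)),
               "equal model counts")
  expect_error(replicate_probabilities(matrix(0.5, 3, 1), matrix(0.5, 2, 1)),
               ">= 2")
  expect_error(replicate_probabilities(matrix(1.5, 3, 2), matrix(0.5, 2, 2)),
               "\\[0, 1\\]")
  expect_error(replicate_probabilities(matrix(NA_real_, 3, 2), matrix(0.5, 2, 2)),
               "complete")
})
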