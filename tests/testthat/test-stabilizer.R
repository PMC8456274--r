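# The deep stabilizer: binning, fusion arithmetic, training behaviour,
# inference invariants, and replicate-CV evaluation.

test_that("binning identity, constant pooling and apex-bin arithmetic", {
  n <- 500
  sp <- new_spectrum(seq(100, 200, length.out = n), runif(n, 0, 50))
  expect_equal(as.numeric(bin_spectrum(sp, n)), sp$intensity)
  spc <- new_spectrum(seq(100, 200, length.out = n), rep(7.5, n))
  expect_equal(as.numeric(bin_spectrum(spc, 40)), rep(7.5, 40))
  # single planted peak lands in the arithmetically predicted bin
  pan <- make_panel(1, 0, 0, 0, seed = 1, mz_range = c(100, 200), min_spacing = 2)
  acq <- acquisition_config(mz_min = 100, mz_max = 200, n_points = 1001,
                            peak_sigma = 0.6)
  sp1 <- analytic_spectrum(10, pan, acq)
  b <- bin_spectrum(sp1, 50)
  expect_equal(which.max(b),
               floor((pan$features$mz - 100) / (100 / 50)) + 1)
  expect_error(bin_spectrum(sp1, 2000), "exceeds")
  # unbinning restores a spectrum on the bin-centre grid
  sp2 <- unbin_spectrum(b)
  expect_equal(sp2$mz, as.numeric(attr(b, "bin_mz")))
})

test_that("stabilizer config validates its invariants", {
  expect_error(stabilizer_config(input_length = 8), "input_length")
  expect_error(stabilizer_config(kernel_size = 8), "odd")
  expect_error(stabilizer_config(reconstruction_weight = 0), "reconstruction_weight")
  expect_error(stabilizer_config(adversarial_weight = -1), "adversarial_weight")
})

test_that("fusion arithmetic: zero refinement collapses onto the coarse branch", {
  fx <- fix_trained_stabilizer()
  m <- fx$model
  x <- fx$hold_reps[[1]][1, ]
  # zero the refinement head: output must equal the coarse branch exactly
  m0 <- m
  m0$gen$refine_head$W[] <- 0
  m0$gen$refine_head$b[] <- 0
  parts <- stabilize(m0, x, parts = TRUE)
  expect_equal(parts$output, pmax(parts$coarse, 0), tolerance = 1e-12)
  # mask forced to saturation: output = coarse + refinement (log domain)
  m1 <- m
  m1$gen$mask_head$W[] <- 0
  m1$gen$mask_head$b[] <- 50          # sigmoid -> 1
  p1 <- stabilize(m1, x, parts = TRUE)
  u <- function(v) log1p(v / m$log_base) / m$scale
  sel <- p1$coarse > 0 & p1$output > 0
  expect_equal(u(p1$output)[sel],
               (u(p1$coarse) + p1$refinement / m$scale)[sel],
               tolerance = 1e-8)
})

test_that("attention mask is bounded and outputs are nonnegative on random inputs", {
  fx <- fix_trained_stabilizer()
  set.seed(8)
  X <- matrix(abs(rnorm(5 * 512, 20, 30)), 5)
  parts <- stabilize(fx$model, X, parts = TRUE)
  expect_true(all(parts$mask >= 0 & parts$mask <= 1))
  expect_true(all(parts$output >= 0))
  expect_error(stabilize(fx$model, X[, 1:100]), "input length")
})

test_that("training is reproducible and rejects malformed pairs", {
  pairs <- lapply(1:10, function(i) {
    list(low = abs(rnorm(64, 10, 3)), high = abs(rnorm(64, 10, 1)))
  })
  cfg <- stabilizer_config(64, 1, 1, 4, 5, epochs = 2, batch_size = 4, seed = 3)
  m1 <- train_stabilizer(pairs, cfg)
  m2 <- train_stabilizer(pairs, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(stabilize(m1, pairs[[1]]$low), stabilize(m2, pairs[[1]]$low))
  expect_equal(nrow(m1$history), 2)
  bad <- c(pairs, list(list(low = rnorm(32), high = rnorm(64))))
  expect_error(train_stabilizer(bad, cfg), "length")
  expect_error(train_stabilizer(pairs[1], cfg), "2 training pairs")
})

test_that("pure regression training (no adversary) shows a non-increasing loss trend", {
  set.seed(21)
  base <- abs(rnorm(64, 15, 5))
  pairs <- lapply(1:40, function(i) {
    list(low = base * exp(rnorm(1, 0, 0.2)) + abs(rnorm(64, 0, 1)), high = base)
  })
  cfg <- stabilizer_config(64, 1, 2, 4, 5, epochs = 12, batch_size = 8,
                           adversarial_weight = 0, learning_rate = 5e-3,
                           seed = 4)
  m <- train_stabilizer(pairs, cfg, holdout_fraction = 0)
  h <- m$history$loss_rec
  expect_true(all(is.na(m$history$loss_d)))
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
})

test_that("identical low/high pairs are mapped with near-zero error", {
  set.seed(22)
  vecs <- lapply(1:30, function(i) abs(rnorm(64, 20, 8)))
  pairs <- lapply(vecs, function(v) list(low = v, high = v))
  cfg <- stabilizer_config(64, 1, 1, 4, 5, epochs = 10, batch_size = 8,
                           adversarial_weight = 0, learning_rate = 5e-3,
                           seed = 5)
  m <- train_stabilizer(pairs, cfg)
  expect_equal(m$identity_error, 0)
  expect_lt(m$holdout_error, 0.05 * mean(unlist(vecs)))
})

test_that("the trained stabilizer beats the identity baseline on held-out pairs", {
  fx <- fix_trained_stabilizer()
  expect_lt(fx$model$holdout_error, fx$model$identity_error)
})

test_that("stabilization reduces replicate variability of feature intensities", {
  fx <- fix_trained_stabilizer()
  ev <- evaluate_stabilization(fx$model, fx$hold_reps, fx$hold_refs)
  expect_lt(median(ev$median_cv_after), median(ev$median_cv_before))
  expect_lt(ev$reconstruction_error, ev$identity_error)
  # zero-variance replicates: CV identically zero before and after
  Z <- fx$hold_reps[[1]][c(1, 1), ]
  ev0 <- evaluate_stabilization(fx$model, list(Z), feature_bins = c(10, 50, 400))
  expect_equal(as.numeric(ev0$cv_before), c(0, 0, 0))
  expect_equal(as.numeric(ev0$cv_after), c(0, 0, 0))
  expect_error(evaluate_stabilization(fx$model, list(Z[1, , drop = FALSE])),
               "replicates")
})

test_that("an untrained model still yields a structurally complete report", {
  cfg <- stabilizer_config(128, 1, 1, 4, 5, epochs = 1, batch_size = 4, seed = 6)
  pairs <- lapply(1:6, function(i) list(low = abs(rnorm(128, 10, 2)),
                                        high = abs(rnorm(128, 10, 2))))
  m <- train_stabilizer(pairs, cfg, holdout_fraction = 0)
  reps <- lapply(1:3, function(i) matrix(abs(rnorm(4 * 128, 10, 2)), 4))
  ev <- evaluate_stabilization(m, reps)
  expect_s3_class(ev, "smp_stab_report")
  expect_equal(dim(ev$cv_before), dim(ev$cv_after))
})
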