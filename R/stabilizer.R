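# The deep stabilizer: a conditional-GAN-style generator that maps binned
# low-shot spectra to high-shot-equivalent spectra. The generator has a
# stabilization-oriented coarse reconstruction branch and an
# attention-guided peak-refinement branch fused by element-wise product and
# addition; the discriminator scores whether a spectrum looks like a
# high-shot reference.

#' Deep stabilizer configuration
#'
#' Architecture and training hyperparameters. The topology (two dense-block
#' branches, sigmoid attention mask, product-plus-addition fusion, real/fake
#' discriminator) is fixed; sizes and loss weights are tunable. Defaults are
#' desk-scale: a 512-bin input with two dense blocks trains on a single CPU
#' in seconds per epoch.
#'
#' @param input_length length of the binned spectrum the network consumes.
#' @param n_dense_blocks dense blocks per branch.
#' @param layers_per_block convolutional layers inside each dense block.
#' @param growth_channels channels added by each dense-block layer (also the
#'   trunk width).
#' @param kernel_size odd convolution kernel width (grid bins).
#' @param disc_channels discriminator channel width.
#' @param adversarial_weight weight of the non-saturating adversarial term
#'   in the generator loss; 0 reduces training to pure paired regression.
#' @param reconstruction_weight weight of the mean-absolute reconstruction
#'   term (must be > 0).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed seed controlling initialization and batch shuffling.
#' @return an object of class `smp_stab_config`.
#' @export
stabilizer_config <- function(input_length = 512, n_dense_blocks = 2,
                              layers_per_block = 2, growth_channels = 8,
                              kernel_size = 9, disc_channels = 8,
                              adversarial_weight = 0.01,
                              reconstruction_weight = 1,
                              learning_rate = 2e-3, batch_size = 32,
                              epochs = 30, seed = 1) {
  if (input_length < 16) stop_invalid("input_length must be >= 16")
  if (kernel_size %% 2 == 0) stop_invalid("kernel_size must be odd")
  if (adversarial_weight < 0) stop_invalid("adversarial_weight must be >= 0")
  if (reconstruction_weight <= 0) stop_invalid("reconstruction_weight must be > 0")
  structure(
    list(input_length = as.integer(input_length),
         n_dense_blocks = as.integer(n_dense_blocks),
         layers_per_block = as.integer(layers_per_block),
         growth_channels = as.integer(growth_channels),
         kernel_size = as.integer(kernel_size),
         disc_channels = as.integer(disc_channels),
         adversarial_weight = adversarial_weight,
         reconstruction_weight = reconstruction_weight,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "smp_stab_config"
  )
}

#' Mean-pool a spectrum into fixed-length bins
#'
#' Pools intensities into `input_length` equal-width m/z bins spanning the
#' spectrum's range, the fixed-length representation the stabilizer network
#' consumes. Bin-centre m/z values are attached so stabilized vectors can be
#' re-expanded to (m/z, intensity) spectra with [unbin_spectrum()].
#'
#' @param spectrum an `smp_spectrum`.
#' @param input_length number of bins; must not exceed the grid length.
#' @return numeric vector of length `input_length` with attributes `bin_mz`
#'   (bin centres) and `mz_range`.
#' @export
bin_spectrum <- function(spectrum, input_length) {
  stopifnot(inherits(spectrum, "smp_spectrum"))
  n <- length(spectrum$mz)
  L <- as.integer(input_length)
  if (L < 1) stop_invalid("input_length must be >= 1")
  if (L > n) stop_invalid("input_length (%d) exceeds grid length (%d)", L, n)
  lo <- spectrum$mz[1]
  hi <- spectrum$mz[n]
  bw <- (hi - lo) / L
  bin <- pmin(L, floor((spectrum$mz - lo) / bw) + 1L)
  v <- as.numeric(tapply(spectrum$intensity, factor(bin, levels = seq_len(L)),
                         mean, default = 0))
  v[is.na(v)] <- 0
  structure(v, bin_mz = lo + (seq_len(L) - 0.5) * bw, mz_range = c(lo, hi))
}

#' Re-expand a binned vector to a spectrum
#'
#' @param x a vector carrying the `bin_mz` attribute from [bin_spectrum()],
#'   or a plain vector plus an explicit `bin_mz`.
#' @param bin_mz bin-centre m/z values (taken from `x` when absent).
#' @param ... metadata passed to the spectrum constructor.
#' @return an `smp_spectrum` on the bin-centre grid.
#' @export
unbin_spectrum <- function(x, bin_mz = attr(x, "bin_mz"), ...) {
  if (is.null(bin_mz)) stop_invalid("bin_mz metadata missing")
  new_spectrum(bin_mz, pmax(as.numeric(x), 0), ...)
}

# Background-level context channel fed to the generator alongside the
# spectrum itself: the per-spectrum lower-decile intensity, a robust
# estimate of the baseline level. Chemical noise and analyte peaks only
# ever add intensity, so a low quantile tracks the per-acquisition global
# gain while staying blind to peak content; it is broadcast to a constant
# channel.
.background_channel <- function(M, prob = 0.1) {
  q <- apply(M, 1, stats::quantile, probs = prob, names = FALSE)
  matrix(q, nrow(M), ncol(M))
}

.pairs_to_matrices <- function(pairs, input_length) {
  getv <- function(p, nm) {
    v <- p[[nm]]
    if (inherits(v, "smp_spectrum")) v <- bin_spectrum(v, input_length)
    as.numeric(v)
  }
  lows <- lapply(pairs, getv, "low")
  highs <- lapply(pairs, getv, "high")
  len <- vapply(c(lows, highs), length, integer(1))
  if (any(len != input_length)) {
    stop_invalid("pair vectors must have length input_length = %d (found %s)",
                 input_length, paste(unique(len[len != input_length]),
                                     collapse = ", "))
  }
  list(X = do.call(rbind, lows), Y = do.call(rbind, highs))
}

#' Train the deep stabilizer
#'
#' Alternating adversarial training on aligned (low-shot, high-shot) spectrum
#' pairs. The generator loss is
#' `reconstruction_weight * mean |G(x) - y| + adversarial_weight * softplus(-D(G(x)))`
#' (non-saturating adversarial term); the discriminator minimizes the
#' standard real/fake binary objective on reference versus stabilized
#' vectors. With `adversarial_weight = 0` the discriminator is skipped and
#' training reduces to pure paired regression. Inputs are internally scaled
#' by the 99th percentile of the reference intensities.
#'
#' @param pairs list of pairs; each element has `low` and `high`, either
#'   binned numeric vectors of length `input_length` or `smp_spectrum`
#'   objects (binned automatically).
#' @param config an [stabilizer_config()].
#' @param holdout_fraction fraction of pairs held out for the reported
#'   held-out reconstruction error (0 to use all pairs for training).
#' @return an object of class `smp_stabilizer` with the trained generator
#'   and discriminator, per-epoch `history`, the config snapshot, and
#'   held-out errors (`holdout_error`, `identity_error`).
#' @seealso [stabilize()], [evaluate_stabilization()]
#' @export
train_stabilizer <- function(pairs, config = stabilizer_config(),
                             holdout_fraction = 0.2) {
  stopifnot(inherits(config, "smp_stab_config"))
  if (length(pairs) < 2) stop_invalid("need at least 2 training pairs")
  mats <- .pairs_to_matrices(pairs, config$input_length)
  n <- nrow(mats$X)
  # the network operates on log intensities: u = log1p(x / c). This
  # compresses the dynamic range and turns the dominant multiplicative
  # (per-shot gain) noise into an additive offset the convolutions can see
  # at the same scale as the peaks.
  log_base <- as.numeric(stats::median(mats$Y))
  if (log_base <= 0) log_base <- 1
  scale <- as.numeric(stats::quantile(log1p(mats$Y / log_base), 0.99))
  if (scale <= 0) scale <- 1
  X <- log1p(mats$X / log_base) / scale
  Y <- log1p(mats$Y / log_base) / scale
  Xbg <- .background_channel(X)
  L <- config$input_length

  local_seed(config$seed, {
    hold <- if (holdout_fraction > 0 && n >= 5) {
      sample.int(n, max(1L, round(holdout_fraction * n)))
    } else integer(0)
    tr <- setdiff(seq_len(n), hold)
    gen <- nn_gen_build(config)
    # reference background level for the normalization term
    gen$m0 <- stats::median(.background_channel(Y)[, 1])
    use_disc <- config$adversarial_weight > 0
    disc <- if (use_disc) nn_disc_build(config) else NULL
    g_layers <- nn_gen_layers(gen)
    g_state <- adam_init(g_layers)
    if (use_disc) {
      d_layers <- list(disc$conv1, disc$conv2,
                       list(W = matrix(disc$w, 1), b = disc$b))
      d_state <- adam_init(d_layers)
    }
    t_g <- 0L; t_d <- 0L
    hist <- data.frame(epoch = integer(0), loss_g = numeric(0),
                       loss_rec = numeric(0), loss_adv = numeric(0),
                       loss_d = numeric(0))
    to_arr <- function(M, idx) {
      array(t(M[idx, , drop = FALSE]), c(1L, L, length(idx)))
    }
    to_arr2 <- function(idx) {
      a <- array(0, c(2L, L, length(idx)))
      a[1L, , ] <- t(X[idx, , drop = FALSE])
      a[2L, , ] <- t(Xbg[idx, , drop = FALSE])
      a
    }
    for (ep in seq_len(config$epochs)) {
      ord <- sample_exact(tr, length(tr))
      splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_rec <- ep_adv <- ep_d <- 0
      for (bi in splits) {
        B <- length(bi)
        x <- to_arr2(bi); y <- to_arr(Y, bi)
        fw <- nn_gen_fwd(gen, x)
        # --- discriminator step (uses the same generated batch) ---
        if (use_disc) {
          fw_r <- nn_disc_fwd(disc, y)
          fw_f <- nn_disc_fwd(disc, fw$out)
          loss_d <- mean(nn_softplus(-fw_r$logits)) +
            mean(nn_softplus(fw_f$logits))
          dz_r <- -nn_sigmoid(-fw_r$logits) / B
          dz_f <- nn_sigmoid(fw_f$logits) / B
          br <- nn_disc_bwd(disc, fw_r, dz_r, need_dx = FALSE)
          bf <- nn_disc_bwd(disc, fw_f, dz_f, need_dx = FALSE)
          dg <- list(list(dW = br$grads$conv1$dW + bf$grads$conv1$dW,
                          db = br$grads$conv1$db + bf$grads$conv1$db),
                     list(dW = br$grads$conv2$dW + bf$grads$conv2$dW,
                          db = br$grads$conv2$db + bf$grads$conv2$db),
                     list(dW = matrix(br$dw + bf$dw, 1), db = br$db + bf$db))
          t_d <- t_d + 1L
          upd <- adam_update(d_layers, dg, d_state, config$learning_rate, t_d)
          d_layers <- upd$layers; d_state <- upd$state
          disc$conv1 <- d_layers[[1]]; disc$conv2 <- d_layers[[2]]
          disc$w <- as.numeric(d_layers[[3]]$W); disc$b <- d_layers[[3]]$b
          ep_d <- ep_d + loss_d * B
        }
        # --- generator step ---
        diff <- fw$out - y
        loss_rec <- mean(abs(diff))
        dout <- config$reconstruction_weight * sign(diff) / length(diff)
        loss_adv <- 0
        if (use_disc) {
          fw_f <- nn_disc_fwd(disc, fw$out)
          loss_adv <- mean(nn_softplus(-fw_f$logits))
          dzf <- -nn_sigmoid(-fw_f$logits) / B
          bi_d <- nn_disc_bwd(disc, fw_f, dzf, need_dx = TRUE)
          dout <- dout + config$adversarial_weight * bi_d$dx
        }
        if (!is.finite(loss_rec) || !is.finite(loss_adv)) {
          stop_invalid("stabilizer training diverged at epoch %d", ep)
        }
        gg <- nn_gen_bwd(gen, fw, dout)
        t_g <- t_g + 1L
        upd <- adam_update(g_layers, nn_gen_flat_grads(gg), g_state,
                           config$learning_rate, t_g)
        g_layers <- upd$layers; g_state <- upd$state
        gen <- nn_gen_set_layers(gen, g_layers)
        ep_rec <- ep_rec + loss_rec * B
        ep_adv <- ep_adv + loss_adv * B
      }
      nt <- length(tr)
      hist <- rbind(hist, data.frame(
        epoch = ep,
        loss_g = config$reconstruction_weight * ep_rec / nt +
          config$adversarial_weight * ep_adv / nt,
        loss_rec = ep_rec / nt, loss_adv = ep_adv / nt,
        loss_d = if (use_disc) ep_d / nt else NA_real_))
    }
    model <- structure(
      list(gen = gen, disc = disc, config = config, scale = scale,
           log_base = log_base, history = hist,
           bin_mz = attr(pairs[[1]]$low, "bin_mz")),
      class = "smp_stabilizer")
    if (length(hold)) {
      stab <- stabilize(model, mats$X[hold, , drop = FALSE])
      model$holdout_error <- mean(abs(stab - mats$Y[hold, , drop = FALSE]))
      model$identity_error <- mean(abs(mats$X[hold, , drop = FALSE] -
                                         mats$Y[hold, , drop = FALSE]))
      model$holdout_idx <- hold
    }
    model
  })
}

#' Apply the deep stabilizer
#'
#' Deterministic inference. The binned spectrum is mapped to the network's
#' log-intensity representation, fused as
#' `out = coarse(u) + mask(u) * refinement(u)` (truncated at zero), and
#' transformed back to raw intensities. Accepts a single binned vector or a
#' matrix with one spectrum per row.
#'
#' @param model a trained `smp_stabilizer`.
#' @param x numeric vector of length `input_length`, or a matrix with that
#'   many columns.
#' @param parts if `TRUE`, also return the coarse output, refinement signal
#'   and attention mask.
#' @return stabilized vector/matrix, or a list when `parts = TRUE`.
#' @export
stabilize <- function(model, x, parts = FALSE) {
  stopifnot(inherits(model, "smp_stabilizer"))
  L <- model$config$input_length
  one <- is.null(dim(x))
  M <- if (one) matrix(as.numeric(x), 1) else as.matrix(x)
  if (ncol(M) != L) {
    stop_invalid("input length %d does not match model input_length %d",
                 ncol(M), L)
  }
  U <- log1p(M / model$log_base) / model$scale
  xin <- array(0, c(2L, L, nrow(M)))
  xin[1L, , ] <- t(U)
  xin[2L, , ] <- t(.background_channel(U))
  fw <- nn_gen_fwd(model$gen, xin)
  shape <- function(a) {
    out <- t(matrix(a, L, nrow(M)))
    if (one) as.numeric(out) else out
  }
  from_log <- function(u) model$log_base * expm1(pmax(u, 0) * model$scale)
  out <- from_log(shape(fw$out))
  if (!parts) return(out)
  list(output = out, coarse = from_log(shape(fw$coarse)),
       refinement = shape(fw$refine) * model$scale, mask = shape(fw$mask))
}

#' @export
predict.smp_stabilizer <- function(object, newdata, ...) stabilize(object, newdata)

#' @export
print.smp_stabilizer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Deep stabilizer: input %d bins, %d dense block(s) x %d ",
                     "layer(s), growth %d, kernel %d\n"),
              cfg$input_length, cfg$n_dense_blocks, cfg$layers_per_block,
              cfg$growth_channels, cfg$kernel_size))
  cat(sprintf("trained %d epochs; final reconstruction loss %.4g\n",
              nrow(x$history), utils::tail(x$history$loss_rec, 1)))
  if (!is.null(x$holdout_error)) {
    cat(sprintf("held-out mean abs error %.4g (identity baseline %.4g)\n",
                x$holdout_error, x$identity_error))
  }
  invisible(x)
}

#' @export
plot.smp_stabilizer <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss_rec, h$loss_d), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss",
                    col = c("black", "red"), ...)
  graphics::legend("topright", c("reconstruction", "discriminator"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Evaluate stabilization on replicated acquisitions
#'
#' Computes per-feature coefficients of variation across technical
#' replicates before and after stabilization, the reconstruction error
#' against a reference, and a paired one-sided test that stabilization
#' reduces each sample's median per-feature CV.
#'
#' @param model a trained `smp_stabilizer`.
#' @param replicates list with one element per sample: a matrix of binned
#'   replicate spectra (replicates x bins). At least 2 replicates each.
#' @param references optional list/matrix of per-sample reference vectors.
#' @param feature_bins indices of the bins treated as features; defaults to
#'   the strongest local maxima of the mean reference (or mean replicate)
#'   vector.
#' @param n_feature_bins number of feature bins auto-selected when
#'   `feature_bins` is `NULL`.
#' @return an object of class `smp_stab_report`: per-sample/per-feature CV
#'   matrices before and after, their medians, the paired one-sided p-value,
#'   and reconstruction/identity errors when references are given.
#' @export
evaluate_stabilization <- function(model, replicates, references = NULL,
                                   feature_bins = NULL, n_feature_bins = 20) {
  stopifnot(inherits(model, "smp_stabilizer"))
  if (any(vapply(replicates, nrow, 1L) < 2)) {
    stop_invalid("need >= 2 replicates per sample")
  }
  n_samp <- length(replicates)
  mean_ref <- if (!is.null(references)) {
    colMeans(do.call(rbind, lapply(references, as.numeric)))
  } else {
    colMeans(do.call(rbind, lapply(replicates, colMeans)))
  }
  if (is.null(feature_bins)) {
    L <- length(mean_ref)
    loc <- which(mean_ref > c(-Inf, mean_ref[-L]) &
                   mean_ref >= c(mean_ref[-1], -Inf))
    loc <- loc[order(mean_ref[loc], decreasing = TRUE)]
    feature_bins <- sort(utils::head(loc, n_feature_bins))
  }
  cv_mat <- function(M) apply(M[, feature_bins, drop = FALSE], 2, cv_stat)
  cv_before <- t(vapply(replicates, cv_mat, numeric(length(feature_bins))))
  stabbed <- lapply(replicates, function(M) stabilize(model, M))
  cv_after <- t(vapply(stabbed, cv_mat, numeric(length(feature_bins))))
  med_b <- apply(cv_before, 1, stats::median)
  med_a <- apply(cv_after, 1, stats::median)
  p <- if (n_samp >= 3 && stats::sd(med_b - med_a) > 0) {
    stats::t.test(med_b, med_a, paired = TRUE,
                  alternative = "greater")$p.value
  } else NA_real_
  recon <- identity_err <- NA_real_
  if (!is.null(references)) {
    re <- ie <- 0
    for (i in seq_len(n_samp)) {
      ref <- matrix(as.numeric(references[[i]]), nrow(replicates[[i]]),
                    length(mean_ref), byrow = TRUE)
      re <- re + mean(abs(stabbed[[i]] - ref))
      ie <- ie + mean(abs(replicates[[i]] - ref))
    }
    recon <- re / n_samp
    identity_err <- ie / n_samp
  }
  structure(
    list(cv_before = cv_before, cv_after = cv_after,
         median_cv_before = med_b, median_cv_after = med_a,
         p_value = p, feature_bins = feature_bins,
         reconstruction_error = recon, identity_error = identity_err),
    class = "smp_stab_report"
  )
}

#' @export
print.smp_stab_report <- function(x, ...) {
  cat(sprintf("Stabilization report over %d samples, %d feature bins\n",
              nrow(x$cv_before), length(x$feature_bins)))
  cat(sprintf("median per-feature CV: %.3f before -> %.3f after (paired one-sided p = %.3g)\n",
              stats::median(x$median_cv_before), stats::median(x$median_cv_after),
              x$p_value))
  if (is.finite(x$reconstruction_error)) {
    cat(sprintf("reconstruction error %.4g vs identity %.4g\n",
                x$reconstruction_error, x$identity_error))
  }
  invisible(x)
}
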