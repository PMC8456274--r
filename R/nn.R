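# Minimal 1-D convolutional network machinery for the deep stabilizer.
#
# Feature maps are arrays of dim (channels, length, batch). Convolutions use
# "same" zero padding and are computed as a single BLAS matrix product on an
# im2col patch matrix; backward passes rebuild the patch matrix instead of
# caching it to keep memory flat. Everything here is internal; the public
# surface lives in stabilizer.R.

nn_conv_init <- function(c_in, c_out, k, scale = 1) {
  list(W = matrix(stats::rnorm(c_out * c_in * k,
                               sd = scale * sqrt(2 / (c_in * k))),
                  nrow = c_out),
       b = numeric(c_out), c_in = c_in, c_out = c_out, k = as.integer(k))
}

.patch_cols <- function(L, B, p) {
  # column index into the padded (C x (L+2p)*B) matrix for kernel offset 0
  rep.int((0:(B - 1L)) * (L + 2L * p), rep.int(L, B)) + rep.int(seq_len(L), B)
}

# padded input flattened to a (C x (L+2p)*B) matrix
.pad_mat <- function(x, p) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  if (p == 0L) return(matrix(x, nrow = C))
  xp <- array(0, c(C, L + 2L * p, B))
  xp[, (p + 1L):(p + L), ] <- x
  matrix(xp, nrow = C)
}

# Convolution as a sum over kernel offsets of one stacked BLAS product:
# y[, i] = sum_j W_j %*% xpad[, i + j], avoiding im2col patch matrices.
nn_conv_fwd <- function(x, ly, want_cache = FALSE) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  k <- ly$k; p <- (k - 1L) %/% 2L
  M <- .pad_mat(x, p)
  co <- ly$c_out
  Wstack <- matrix(0, k * co, C)
  for (j in 0:(k - 1L)) {
    Wstack[(j * co + 1L):((j + 1L) * co), ] <- ly$W[, (j * C + 1L):((j + 1L) * C)]
  }
  A <- Wstack %*% M
  cols0 <- .patch_cols(L, B, p)
  ym <- matrix(ly$b, co, L * B)
  for (j in 0:(k - 1L)) {
    ym <- ym + A[(j * co + 1L):((j + 1L) * co), cols0 + j, drop = FALSE]
  }
  y <- array(ym, c(co, L, B))
  if (want_cache) attr(y, "padded") <- M
  y
}

# dy: (c_out, L, B); x: the layer input (used only when no cached padded
# matrix is supplied). Returns dx and parameter grads.
nn_conv_bwd <- function(x, ly, dy, need_dx = TRUE, padded = NULL) {
  k <- ly$k; p <- (k - 1L) %/% 2L
  if (is.null(padded)) padded <- .pad_mat(x, p)
  C <- nrow(padded)
  d <- dim(dy); co <- d[1]; L <- d[2]; B <- d[3]
  cols0 <- .patch_cols(L, B, p)
  dym <- matrix(dy, nrow = co)
  dW <- matrix(0, co, C * k)
  for (j in 0:(k - 1L)) {
    dW[, (j * C + 1L):((j + 1L) * C)] <-
      tcrossprod(dym, padded[, cols0 + j, drop = FALSE])
  }
  db <- rowSums(dym)
  dx <- NULL
  if (need_dx) {
    dM <- matrix(0, C, (L + 2L * p) * B)
    for (j in 0:(k - 1L)) {
      Wj <- ly$W[, (j * C + 1L):((j + 1L) * C), drop = FALSE]
      cj <- cols0 + j
      dM[, cj] <- dM[, cj] + crossprod(Wj, dym)
    }
    dxp <- array(dM, c(C, L + 2L * p, B))
    dx <- dxp[, (p + 1L):(p + L), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

nn_lrelu <- function(x, a = 0.2) x * (x > 0) + (a * x) * (x <= 0)
nn_lrelu_bwd <- function(x, dy, a = 0.2) dy * ((x > 0) + a * (x <= 0))

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

.concat_ch <- function(tens) {
  if (length(tens) == 1L) return(tens[[1]])
  d <- dim(tens[[1]])
  Cs <- vapply(tens, function(t) dim(t)[1], integer(1))
  out <- array(0, c(sum(Cs), d[2], d[3]))
  at <- 0L
  for (t in tens) {
    C <- dim(t)[1]
    out[(at + 1L):(at + C), , ] <- t
    at <- at + C
  }
  out
}

# ---- trunk: input conv + dense blocks ---------------------------------------
#
# A trunk plan is a list of ops; each op convolves the channel-concatenation
# of earlier tensor slots into a new slot (DenseNet-style connectivity inside
# each block, with a 1x1 transition conv compressing back to `width` channels
# between blocks).

nn_trunk_build <- function(in_ch, width, n_blocks, layers_per_block, growth, k) {
  plan <- list()
  layers <- list()
  add <- function(from, c_in, c_out, kk, act) {
    layers[[length(layers) + 1L]] <<- nn_conv_init(c_in, c_out, kk)
    plan[[length(plan) + 1L]] <<- list(from = from, act = act,
                                       to = length(plan) + 2L)
  }
  add(1L, in_ch, width, k, TRUE)          # slot 2: stem
  base <- 2L
  for (b in seq_len(n_blocks)) {
    slots <- base
    for (l in seq_len(layers_per_block)) {
      c_in <- width + (l - 1L) * growth
      add(slots, c_in, growth, k, TRUE)
      slots <- c(slots, length(plan) + 1L)
    }
    # transition back to `width` channels
    add(slots, width + layers_per_block * growth, width, 1L, TRUE)
    base <- length(plan) + 1L
  }
  list(plan = plan, layers = layers, out_slot = base)
}

nn_trunk_fwd <- function(trunk, x) {
  tens <- vector("list", length(trunk$plan) + 1L)
  pad_cache <- vector("list", length(trunk$plan))
  pre_cache <- vector("list", length(trunk$plan))
  tens[[1]] <- x
  for (i in seq_along(trunk$plan)) {
    op <- trunk$plan[[i]]
    xin <- .concat_ch(tens[op$from])
    pre <- nn_conv_fwd(xin, trunk$layers[[i]], want_cache = TRUE)
    pad_cache[[i]] <- attr(pre, "padded")
    attr(pre, "padded") <- NULL
    tens[[op$to]] <- if (op$act) nn_lrelu(pre) else pre
    pre_cache[[i]] <- pre
  }
  list(out = tens[[trunk$out_slot]], tens = tens,
       padded = pad_cache, pre = pre_cache)
}

nn_trunk_bwd <- function(trunk, cache, dout, need_dx = FALSE) {
  n_ops <- length(trunk$plan)
  dtens <- vector("list", n_ops + 1L)
  dtens[[trunk$out_slot]] <- dout
  grads <- vector("list", n_ops)
  for (i in rev(seq_len(n_ops))) {
    op <- trunk$plan[[i]]
    dt <- dtens[[op$to]]
    if (is.null(dt)) {  # slot never used downstream
      ly <- trunk$layers[[i]]
      grads[[i]] <- list(dW = matrix(0, nrow(ly$W), ncol(ly$W)),
                         db = numeric(length(ly$b)))
      next
    }
    dpre <- if (op$act) nn_lrelu_bwd(cache$pre[[i]], dt) else dt
    want_dx <- need_dx || any(op$from != 1L)
    bw <- nn_conv_bwd(NULL, trunk$layers[[i]], dpre,
                      need_dx = want_dx, padded = cache$padded[[i]])
    grads[[i]] <- list(dW = bw$dW, db = bw$db)
    if (want_dx) {
      at <- 0L
      for (s in op$from) {
        C <- dim(cache$tens[[s]])[1]
        piece <- bw$dx[(at + 1L):(at + C), , , drop = FALSE]
        dtens[[s]] <- if (is.null(dtens[[s]])) piece else dtens[[s]] + piece
        at <- at + C
      }
    }
  }
  list(grads = grads, dx = dtens[[1]])
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

# ---- generator --------------------------------------------------------------
#
# Two trunks. The coarse branch reconstructs the stabilized (log-domain)
# spectrum as
#   coarse = u - gamma * (med(u) - m0) + c(trunk(u)),
# an additive residual plus an explicit background-normalization term: in
# log space the dominant multiplicative per-shot gain becomes an additive
# offset visible in the running-median context channel, so subtracting the
# channel's excursion from the reference background level m0 (gamma is a
# learnable gain, initialized at 1) performs approximate gain correction
# from the very first step, and the convolutional residual only has to
# learn refinements. The attention branch feeds a linear refinement head
# and a sigmoid mask head.
# Fusion:  out = relu( coarse + mask * refinement ).

nn_gen_build <- function(cfg) {
  g <- cfg$growth_channels
  in_ch <- cfg$input_channels %||% 2L
  list(
    coarse = nn_trunk_build(in_ch, g, cfg$n_dense_blocks, cfg$layers_per_block,
                            g, cfg$kernel_size),
    att = nn_trunk_build(in_ch, g, cfg$n_dense_blocks, cfg$layers_per_block,
                         g, cfg$kernel_size),
    coarse_head = nn_conv_init(g, 1L, cfg$kernel_size, scale = 0.1),
    refine_head = nn_conv_init(g, 1L, cfg$kernel_size, scale = 0.1),
    mask_head = nn_conv_init(g, 1L, cfg$kernel_size, scale = 0.1),
    # learnable background-normalization gain (1x1 pseudo-conv for Adam)
    gain = list(W = matrix(1, 1, 1), b = 0, c_in = 1L, c_out = 1L, k = 1L),
    m0 = 0
  )
}

# x: (channels, L, B); channel 1 is the spectrum itself (the residual
# base), further channels are context (local running median background).
nn_gen_fwd <- function(gen, x) {
  x1 <- x[1L, , , drop = FALSE]
  bg <- if (dim(x)[1] >= 2L) x[2L, , , drop = FALSE] - gen$m0 else x1 * 0
  ct <- nn_trunk_fwd(gen$coarse, x)
  coarse <- x1 - gen$gain$W[1, 1] * bg + nn_conv_fwd(ct$out, gen$coarse_head)
  at <- nn_trunk_fwd(gen$att, x)
  refine <- nn_conv_fwd(at$out, gen$refine_head)
  mlogit <- nn_conv_fwd(at$out, gen$mask_head)
  mask <- nn_sigmoid(mlogit)
  pre <- coarse + mask * refine
  out <- pre * (pre > 0)
  list(out = out, pre = pre, coarse = coarse, refine = refine, mask = mask,
       ct = ct, at = at, x = x, bg = bg)
}

nn_gen_bwd <- function(gen, fw, dout) {
  dpre <- dout * (fw$pre > 0)
  dcres <- dpre
  dmask <- dpre * fw$refine
  drefine <- dpre * fw$mask
  dmlogit <- dmask * fw$mask * (1 - fw$mask)

  ch <- nn_conv_bwd(fw$ct$out, gen$coarse_head, dcres)
  rh <- nn_conv_bwd(fw$at$out, gen$refine_head, drefine)
  mh <- nn_conv_bwd(fw$at$out, gen$mask_head, dmlogit)
  cb <- nn_trunk_bwd(gen$coarse, fw$ct, ch$dx)
  ab <- nn_trunk_bwd(gen$att, fw$at, rh$dx + mh$dx)
  list(coarse = cb$grads, att = ab$grads,
       coarse_head = list(dW = ch$dW, db = ch$db),
       refine_head = list(dW = rh$dW, db = rh$db),
       mask_head = list(dW = mh$dW, db = mh$db),
       gain = list(dW = matrix(-sum(dcres * fw$bg), 1, 1), db = 0))
}

nn_gen_layers <- function(gen) {
  c(gen$coarse$layers, gen$att$layers,
    list(gen$coarse_head, gen$refine_head, gen$mask_head, gen$gain))
}

nn_gen_set_layers <- function(gen, layers) {
  nc <- length(gen$coarse$layers)
  na <- length(gen$att$layers)
  gen$coarse$layers <- layers[seq_len(nc)]
  gen$att$layers <- layers[nc + seq_len(na)]
  gen$coarse_head <- layers[[nc + na + 1L]]
  gen$refine_head <- layers[[nc + na + 2L]]
  gen$mask_head <- layers[[nc + na + 3L]]
  gen$gain <- layers[[nc + na + 4L]]
  gen
}

nn_gen_flat_grads <- function(gg) {
  c(gg$coarse, gg$att,
    list(gg$coarse_head, gg$refine_head, gg$mask_head, gg$gain))
}

# ---- discriminator ----------------------------------------------------------
#
# conv -> lrelu -> conv -> lrelu -> global mean pool -> affine logit.

nn_disc_build <- function(cfg) {
  c <- cfg$disc_channels
  list(conv1 = nn_conv_init(1L, c, cfg$kernel_size),
       conv2 = nn_conv_init(c, c, cfg$kernel_size),
       w = stats::rnorm(c, sd = 1 / sqrt(c)), b = 0)
}

nn_disc_fwd <- function(disc, x) {
  p1 <- nn_conv_fwd(x, disc$conv1); a1 <- nn_lrelu(p1)
  p2 <- nn_conv_fwd(a1, disc$conv2); a2 <- nn_lrelu(p2)
  d <- dim(a2)
  pool <- apply(a2, c(1, 3), mean)            # (C, B)
  logits <- as.numeric(crossprod(pool, disc$w)) + disc$b
  list(logits = logits, x = x, p1 = p1, a1 = a1, p2 = p2, a2 = a2, pool = pool)
}

# dlogits: length-B vector. Returns input grad and parameter grads.
nn_disc_bwd <- function(disc, fw, dlogits, need_dx = TRUE) {
  d <- dim(fw$a2); C <- d[1]; L <- d[2]; B <- d[3]
  dw <- as.numeric(fw$pool %*% dlogits)
  db <- sum(dlogits)
  dpool <- outer(disc$w, dlogits)             # (C, B)
  da2 <- aperm(array(dpool, c(C, B, L)), c(1, 3, 2)) / L
  dp2 <- nn_lrelu_bwd(fw$p2, da2)
  b2 <- nn_conv_bwd(fw$a1, disc$conv2, dp2)
  dp1 <- nn_lrelu_bwd(fw$p1, b2$dx)
  b1 <- nn_conv_bwd(fw$x, disc$conv1, dp1, need_dx = need_dx)
  list(dx = b1$dx,
       grads = list(conv1 = list(dW = b1$dW, db = b1$db),
                    conv2 = list(dW = b2$dW, db = b2$db)),
       dw = dw, db = db)
}
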