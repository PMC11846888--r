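# Differentiable tensor operations used by the teacher and student networks.
# Tensors are H x W x C x N arrays throughout (see src/nn_kernels.cpp).

# per-channel sum of a (H, W, C, N) array -> length-C vector
ch_sum <- function(x) {
  d <- dim(x)
  m <- colSums(array(x, c(d[1] * d[2], d[3] * d[4])))
  if (d[4] == 1L) m else rowSums(matrix(m, d[3], d[4]))
}

# expand a length-C vector to (H, W, C, N)
ch_expand <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

op_const <- function(value) ad_leaf(value)

op_conv2d <- function(tape, x, w, b) {
  out <- conv2d_forward_cpp(x$value, w$value, b$value)
  xv <- x$value
  wv <- w$value
  ad_node(tape, out, list(x, w, b), function(g) {
    gr <- conv2d_backward_cpp(xv, wv, g)
    list(gr$gx, gr$gw, gr$gb)
  })
}

op_relu <- function(tape, x) {
  mask <- x$value > 0
  out <- x$value * mask
  ad_node(tape, out, list(x), function(g) list(g * mask))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

op_maxpool <- function(tape, x, k) {
  fw <- maxpool_forward_cpp(x$value, as.integer(k))
  xd <- dim(x$value)
  ad_node(tape, fw$out, list(x), function(g) {
    list(maxpool_backward_cpp(fw$idx, g, as.integer(xd)))
  })
}

op_upsample <- function(tape, x, f) {
  d <- dim(x$value)
  out <- x$value[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , ,
                 drop = FALSE]
  ad_node(tape, out, list(x), function(g) {
    # sum gradients over each f x f block
    dim(g) <- c(f, d[1], f * d[2] * d[3] * d[4])
    g <- colSums(g)                       # (d1, f*d2*d3*d4)
    dim(g) <- c(d[1], f, d[2] * d[3] * d[4])
    g <- aperm(g, c(2L, 1L, 3L))
    dim(g) <- c(f, d[1] * d[2] * d[3] * d[4])
    g <- colSums(g)
    dim(g) <- d
    list(g)
  })
}

# Batch normalization over (H, W, N) per channel. `bn_env` holds the running
# mean/var buffers; they are updated only in training mode.
op_batchnorm <- function(tape, x, gamma, beta, bn_env, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- ch_sum(x$value) / m
    xc <- x$value - ch_expand(mu, d)
    va <- ch_sum(xc * xc) / m
    bn_env$running_mean <- (1 - momentum) * bn_env$running_mean + momentum * mu
    bn_env$running_var <- (1 - momentum) * bn_env$running_var + momentum * va
  } else {
    mu <- bn_env$running_mean
    va <- bn_env$running_var
    xc <- x$value - ch_expand(mu, d)
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * ch_expand(inv_sd, d)
  out <- xhat * ch_expand(gamma$value, d) + ch_expand(beta$value, d)
  gv <- gamma$value
  ad_node(tape, out, list(x, gamma, beta), function(g) {
    dgamma <- ch_sum(g * xhat)
    dbeta <- ch_sum(g)
    if (training) {
      gx <- ch_expand(gv * inv_sd, d) *
        (g - ch_expand(dbeta / m, d) - xhat * ch_expand(dgamma / m, d))
    } else {
      gx <- g * ch_expand(gv * inv_sd, d)
    }
    list(gx, dgamma, dbeta)
  })
}

# Inverted dropout; draws its mask from the current R RNG stream so that a
# seeded training loop is fully reproducible.
op_dropout <- function(tape, x, rate, active) {
  if (!active || rate <= 0) return(x)
  keep <- 1 - rate
  mask <- array((stats::runif(length(x$value)) >= rate) / keep, dim(x$value))
  ad_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

# channel-wise concatenation: out channels = C_a + C_b
op_concat_ch <- function(tape, a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  if (!all(da[c(1, 2, 4)] == db[c(1, 2, 4)])) {
    stop("spatial/batch dimensions must match for channel concatenation")
  }
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a$value
  out[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_node(tape, out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# broadcast-multiply a single-channel gate S (H, W, 1, N) over F (H, W, C, N)
op_gate_mul <- function(tape, s, f) {
  df <- dim(f$value)
  srep <- f$value
  srep[] <- s$value[, , rep(1L, df[3]), , drop = FALSE]
  fv <- f$value
  ad_node(tape, fv * srep, list(s, f), function(g) {
    gs <- g * fv
    d <- dim(gs)
    gs <- rowSums(array(aperm(gs, c(1L, 2L, 4L, 3L)), c(d[1] * d[2] * d[4], d[3])))
    dim(gs) <- c(d[1], d[2], 1L, d[4])
    list(gs, g * srep)
  })
}

# softmax over the channel dimension
op_softmax_ch <- function(tape, x) {
  d <- dim(x$value)
  mx <- x$value[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, x$value[, , c, , drop = FALSE])
  e <- exp(x$value - mx[, , rep(1L, d[3]), , drop = FALSE])
  tot <- e[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) tot <- tot + e[, , c, , drop = FALSE]
  s <- e / tot[, , rep(1L, d[3]), , drop = FALSE]
  ad_node(tape, s, list(x), function(g) {
    dot <- (g * s)[, , 1, , drop = FALSE]
    for (c in seq_len(d[3])[-1]) dot <- dot + (g * s)[, , c, , drop = FALSE]
    list(s * (g - dot[, , rep(1L, d[3]), , drop = FALSE]))
  })
}

# Binary cross-entropy of the foreground-probability channel against a
# binary mask, averaged over all pixels of all samples. `weights` (0/1 per
# pixel) optionally restricts which pixels contribute; the mean is then
# taken over the selected pixels.
op_bce <- function(tape, probs, y, weights = NULL, eps = 1e-7) {
  p <- probs$value[, , 2, , drop = TRUE]
  yv <- as.numeric(y)
  pc <- pmin(pmax(p, eps), 1 - eps)
  ll <- yv * log(pc) + (1 - yv) * log(1 - pc)
  if (is.null(weights)) {
    denom <- length(ll)
    val <- -sum(ll) / denom
  } else {
    denom <- sum(weights)
    if (denom == 0) denom <- 1
    val <- -sum(ll * weights) / denom
  }
  d <- dim(probs$value)
  ad_node(tape, val, list(probs), function(g) {
    dp <- -(yv / pc - (1 - yv) / (1 - pc)) / denom
    if (!is.null(weights)) dp <- dp * weights
    gp <- array(0, d)
    gp[, , 2, ] <- dp
    list(g * gp)
  })
}

# Mean over samples of the squared Euclidean distance between prediction
# maps, with the per-sample distance averaged over pixels (summed over the
# class channels). `target` is a plain array treated as a constant.
op_pred_sqdist <- function(tape, probs, target) {
  d <- dim(probs$value)
  diff <- probs$value - target
  val <- sum(diff * diff) / (d[1] * d[2] * d[4])
  ad_node(tape, val, list(probs), function(g) {
    list(g * 2 * diff / (d[1] * d[2] * d[4]))
  })
}

# sum of scalar loss nodes
op_add_scalars <- function(tape, nodes) {
  val <- sum(vapply(nodes, function(nd) nd$value, numeric(1)))
  ad_node(tape, val, nodes, function(g) rep(list(g), length(nodes)))
}
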