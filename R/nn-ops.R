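# Primitive differentiable operations for the decoder network.
#
# Activations are R arrays dim c(C, X, Y, Z, N) (channel-fastest); most ops
# view them as a C x (S*N) matrix on the same memory. The 3x3x3 convolutions
# are delegated to the compiled im2col/GEMM kernels; everything else is plain
# vectorized R on BLAS.

conv_out_extent <- function(n, k = 3L, stride = 1L, pad = 1L) {
  as.integer((n + 2L * pad - k) %/% stride + 1L)
}

as_chan_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

# --- 3x3x3 convolution -------------------------------------------------------

conv3_fwd <- function(x, w, stride) {
  d <- dim(x)
  r <- .conv3d_fwd(x, as.integer(d), w, dim(w)[1], NULL, 3L, as.integer(stride), 1L)
  r$out
}

conv3_bwd <- function(x, w, gout, stride, need_gx = TRUE) {
  d <- dim(x)
  .conv3d_bwd(x, as.integer(d), w, dim(w)[1], gout, FALSE, 3L,
              as.integer(stride), 1L, need_gx)
}

# --- channel-wise dense (1x1x1 convolution) ---------------------------------

dense_chan_fwd <- function(x, w) {
  d <- dim(x)
  y <- w %*% as_chan_mat(x)
  dim(y) <- c(nrow(w), d[-1])
  y
}

dense_chan_bwd <- function(x, w, gout, need_gx = TRUE) {
  d <- dim(x)
  gm <- as_chan_mat(gout)
  xm <- as_chan_mat(x)
  gw <- gm %*% t(xm)
  gx <- NULL
  if (need_gx) {
    gx <- crossprod(w, gm)
    dim(gx) <- d
  }
  list(gw = gw, gx = gx)
}

# --- batch normalization -----------------------------------------------------

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels),
       eps = 1e-5, momentum = 0.1)
}

bn_fwd <- function(x, bn, training) {
  d <- dim(x)
  xm <- as_chan_mat(x)
  nel <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + bn$eps)
    xhat <- xc * invstd
    y <- bn$gamma * xhat + bn$beta
    unbias <- if (nel > 1) nel / (nel - 1) else 1
    bn$running_mean <- (1 - bn$momentum) * bn$running_mean + bn$momentum * mu
    bn$running_var <- (1 - bn$momentum) * bn$running_var + bn$momentum * v * unbias
    dim(y) <- d
    list(y = y, bn = bn, cache = list(xhat = xhat, invstd = invstd))
  } else {
    invstd <- 1 / sqrt(bn$running_var + bn$eps)
    y <- bn$gamma * invstd * (xm - bn$running_mean) + bn$beta
    dim(y) <- d
    list(y = y, bn = bn, cache = list(invstd = invstd))
  }
}

bn_bwd <- function(gout, bn, cache, training, need_gx = TRUE) {
  d <- dim(gout)
  gm <- as_chan_mat(gout)
  if (training) {
    nel <- ncol(gm)
    xhat <- cache$xhat
    dbeta <- rowSums(gm)
    dgamma <- rowSums(gm * xhat)
    gx <- NULL
    if (need_gx) {
      gx <- (bn$gamma * cache$invstd) *
        (gm - dbeta / nel - xhat * (dgamma / nel))
      dim(gx) <- d
    }
    list(dgamma = dgamma, dbeta = dbeta, gx = gx)
  } else {
    gx <- NULL
    if (need_gx) {
      gx <- (bn$gamma * cache$invstd) * gm
      dim(gx) <- d
    }
    list(dgamma = NULL, dbeta = NULL, gx = gx)
  }
}

# --- ReLU --------------------------------------------------------------------

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

# Plain rule: pass gradient where the forward input was positive.
# Guided rule: additionally require the incoming gradient to be positive.
relu_bwd <- function(gout, x_pre, guided = FALSE) {
  g <- gout
  mask <- x_pre > 0
  if (guided) mask <- mask & (gout > 0)
  g[!mask] <- 0
  g
}

# --- parameter-free shortcut (identity, strided/padded) ----------------------

shortcut_fwd <- function(x, cout, stride) {
  d <- dim(x)
  cin <- d[1]
  if (stride > 1L) {
    x <- x[, seq(1, d[2], by = stride), seq(1, d[3], by = stride),
           seq(1, d[4], by = stride), , drop = FALSE]
  }
  d2 <- dim(x)
  if (cout == cin) return(x)
  out <- array(0, c(cout, d2[-1]))
  cc <- min(cin, cout)
  out[seq_len(cc), , , , ] <- x[seq_len(cc), , , , , drop = FALSE]
  out
}

shortcut_bwd <- function(gout, xdim, stride) {
  cout <- dim(gout)[1]
  cin <- xdim[1]
  gx <- array(0, xdim)
  cc <- min(cin, cout)
  ix <- seq(1, xdim[2], by = stride)
  iy <- seq(1, xdim[3], by = stride)
  iz <- seq(1, xdim[4], by = stride)
  gx[seq_len(cc), ix, iy, iz, ] <- gout[seq_len(cc), , , , , drop = FALSE]
  gx
}

# --- dense (fully connected / full convolution) ------------------------------

dense_fwd <- function(xmat, w, b) {
  y <- w %*% xmat
  if (!is.null(b)) y <- y + b
  y
}

dense_bwd <- function(xmat, w, gout, has_bias, need_gx = TRUE) {
  gw <- gout %*% t(xmat)
  gb <- if (has_bias) rowSums(gout) else NULL
  gx <- if (need_gx) crossprod(w, gout) else NULL
  list(gw = gw, gb = gb, gx = gx)
}

# --- softmax + cross-entropy -------------------------------------------------

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# labels: integer class index 1..K per column; returns loss and dlogits
cross_entropy <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(p)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(labels, seq_len(n))] <- dl[cbind(labels, seq_len(n))] - 1
  dl <- dl / n
  list(loss = loss, probs = p, dlogits = dl)
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
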