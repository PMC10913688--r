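## Low-level network primitives operating on batched feature maps stored
## as arrays of shape (channels, height, width, batch). Convolutions are
## computed as im2col gathers followed by a single BLAS matrix product;
## every primitive has a matching backward pass used by the trainer.

sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise softmax of a logits matrix (classes x batch), shift-stable
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

## ---- parameter initialisers (draw from the current RNG stream) --------

he_matrix <- function(n_out, n_in, fan_in = n_in)
  matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / fan_in)), n_out, n_in)

glorot_matrix <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

init_conv <- function(c_in, c_out, kh, kw) {
  list(W = he_matrix(c_out, kh * kw * c_in, fan_in = kh * kw * c_in),
       b = numeric(c_out), kh = kh, kw = kw, c_in = c_in, c_out = c_out)
}

init_bn <- function(C)
  list(gamma = rep(1, C), beta = numeric(C),
       mean = numeric(C), var = rep(1, C))

## ---- same-padded 2-D convolution --------------------------------------

# im2col gather indices for a (C, H, W) map and an odd kh x kw kernel.
# Row order within a column: channel fastest, then kernel row, then kernel
# column; output positions ordered height-fastest. With this ordering the
# gathered matrix can be reinterpreted as (kh*kw*C) x (H*W*B) by a dim<-.
conv_index <- function(C, H, W, kh, kw) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  cc <- rep(seq_len(C), kh * kw)
  dh <- rep(rep(seq_len(kh), each = C), kw)
  dw <- rep(seq_len(kw), each = C * kh)
  base <- cc + C * (dh - 1L) + C * Hp * (dw - 1L)
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  shift <- C * (h - 1L) + C * Hp * (w - 1L)
  idx <- as.integer(outer(base, shift, "+"))
  # interior rows of the zero-padded map, in (c, h, w) column-major order
  ic <- rep(seq_len(C), H * W)
  ih <- rep(rep(seq_len(H), each = C), W)
  iw <- rep(seq_len(W), each = C * H)
  pad_rows <- as.integer(ic + C * (ph + ih - 1L) + C * Hp * (pw + iw - 1L))
  list(idx = idx, uidx = sort(unique(idx)), pad_rows = pad_rows,
       C = C, H = H, W = W, kh = kh, kw = kw, ph = ph, pw = pw,
       Hp = Hp, Wp = Wp)
}

conv2d_forward <- function(x, p, ci) {
  B <- dim(x)[4]
  xm <- x; dim(xm) <- c(ci$C * ci$H * ci$W, B)
  xp <- matrix(0, ci$C * ci$Hp * ci$Wp, B)
  xp[ci$pad_rows, ] <- xm
  K <- xp[ci$idx, , drop = FALSE]
  dim(K) <- c(ci$kh * ci$kw * ci$C, ci$H * ci$W * B)
  y <- p$W %*% K + p$b
  dim(y) <- c(p$c_out, ci$H, ci$W, B)
  list(out = y, K = K, B = B)
}

conv2d_backward <- function(dy, p, cache, ci) {
  B <- cache$B
  dim(dy) <- c(p$c_out, ci$H * ci$W * B)
  dW <- tcrossprod(dy, cache$K)
  db <- .rowSums(dy, p$c_out, ci$H * ci$W * B)
  dK <- crossprod(p$W, dy)
  dim(dK) <- c(length(ci$idx), B)
  dxp <- matrix(0, ci$C * ci$Hp * ci$Wp, B)
  dxp[ci$uidx, ] <- rowsum(dK, group = ci$idx)
  dx <- dxp[ci$pad_rows, , drop = FALSE]
  dim(dx) <- c(ci$C, ci$H, ci$W, B)
  list(dx = dx, dW = dW, db = db)
}

## ---- batch normalisation (per channel over height, width, batch) ------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# p: list(gamma, beta, mean, var); rs: optional environment holding
# running statistics updated in place during training.
bn_forward <- function(x, p, training = FALSE, rs = NULL) {
  d <- dim(x); C <- d[1]; M <- prod(d[-1])
  xm <- x; dim(xm) <- c(C, M)
  if (training) {
    mu <- .rowMeans(xm, C, M)
    v <- pmax(.rowMeans(xm * xm, C, M) - mu * mu, 0)
    if (!is.null(rs)) {
      rs$mean <- (1 - BN_MOMENTUM) * rs$mean + BN_MOMENTUM * mu
      rs$var <- (1 - BN_MOMENTUM) * rs$var + BN_MOMENTUM * v
    }
  } else {
    mu <- if (!is.null(rs)) rs$mean else p$mean
    v <- if (!is.null(rs)) rs$var else p$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - mu) * inv
  y <- p$gamma * xhat + p$beta
  dim(y) <- d
  list(out = y, xhat = xhat, inv = inv, dims = d)
}

# training-mode backward (batch statistics participate in the gradient)
bn_backward <- function(dy, p, cache) {
  d <- cache$dims; C <- d[1]; M <- prod(d[-1])
  dim(dy) <- c(C, M)
  dgamma <- .rowSums(dy * cache$xhat, C, M)
  dbeta <- .rowSums(dy, C, M)
  dxhat <- dy * p$gamma
  dx <- (cache$inv / M) *
    (M * dxhat - .rowSums(dxhat, C, M) -
       cache$xhat * .rowSums(dxhat * cache$xhat, C, M))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

## ---- 2 x 2 average pooling, stride 2, ceiling-mode output sizes -------
## Each output cell averages only the cells that actually exist (so a
## constant map pools to the same constant, including at ragged edges).

avgpool2_forward <- function(x) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  Ho <- ceiling(H / 2); Wo <- ceiling(W / 2)
  He <- 2L * Ho; We <- 2L * Wo
  xp <- array(0, c(C, He, We, B))
  xp[, seq_len(H), seq_len(W), ] <- x
  oh <- seq(1L, He, 2L); eh <- seq(2L, He, 2L)
  ow <- seq(1L, We, 2L); ew <- seq(2L, We, 2L)
  ysum <- xp[, oh, ow, , drop = FALSE] + xp[, eh, ow, , drop = FALSE] +
    xp[, oh, ew, , drop = FALSE] + xp[, eh, ew, , drop = FALSE]
  cnt_h <- ifelse(2 * seq_len(Ho) <= H, 2, 1)
  cnt_w <- ifelse(2 * seq_len(Wo) <= W, 2, 1)
  cnt <- array(rep(outer(cnt_h, cnt_w), each = C), c(C, Ho, Wo))
  y <- ysum / c(cnt)                     # recycles over the batch axis
  list(out = y, cnt = cnt, H = H, W = W, Ho = Ho, Wo = Wo)
}

avgpool2_backward <- function(dy, cache) {
  d <- dim(dy); C <- d[1]; B <- d[4]
  He <- 2L * cache$Ho; We <- 2L * cache$Wo
  g <- dy / c(cache$cnt)
  dxp <- array(0, c(C, He, We, B))
  oh <- seq(1L, He, 2L); eh <- seq(2L, He, 2L)
  ow <- seq(1L, We, 2L); ew <- seq(2L, We, 2L)
  dxp[, oh, ow, ] <- g; dxp[, eh, ow, ] <- g
  dxp[, oh, ew, ] <- g; dxp[, eh, ew, ] <- g
  dxp[, seq_len(cache$H), seq_len(cache$W), , drop = FALSE]
}

## ---- small shared helpers ---------------------------------------------

# per-(channel, batch) mean and max over the spatial axis of a
# (C, H*W, B) array; returns C x B matrices plus argmax positions
spatial_reduce <- function(x3, C, HW, B) {
  A <- aperm(x3, c(1, 3, 2))          # (C, B, HW)
  dim(A) <- c(C * B, HW)
  avg <- .rowMeans(A, C * B, HW)
  arg <- max.col(A, ties.method = "first")
  mx <- A[cbind(seq_len(C * B), arg)]
  dim(avg) <- c(C, B); dim(mx) <- c(C, B)
  list(avg = avg, mx = mx, arg = arg)
}

# sum over the middle axis of a (C, HW, B) array -> C x B
mid_sum <- function(x3, C, HW, B) {
  A <- aperm(x3, c(1, 3, 2))
  dim(A) <- c(C * B, HW)
  s <- .rowSums(A, C * B, HW)
  dim(s) <- c(C, B)
  s
}

# per-position max over channels of a (C, M) matrix: values and argmax
channel_max <- function(xm, C, M) {
  tm <- t(xm)
  arg <- max.col(tm, ties.method = "first")
  list(mx = tm[cbind(seq_len(M), arg)], arg = arg)
}
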