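## BiGRU and self-attention: the global feature extractors that follow the
## convolutional stack, plus the softmax classifier head.

#' Initialise GRU parameters
#'
#' Weight matrices `W_*` map the input (dimension `d_in`) and `U_*` the
#' hidden state (dimension `d_h`) into the reset gate (`r`), update gate
#' (`z`) and candidate state (`h`); biases start at zero.
#'
#' @param d_in input dimension.
#' @param d_h hidden dimension.
#' @return parameter list `W_r, U_r, b_r, W_z, U_z, b_z, W_h, U_h, b_h`.
#' @export
init_gru <- function(d_in, d_h) {
  list(W_r = glorot_matrix(d_h, d_in), U_r = glorot_matrix(d_h, d_h),
       b_r = numeric(d_h),
       W_z = glorot_matrix(d_h, d_in), U_z = glorot_matrix(d_h, d_h),
       b_z = numeric(d_h),
       W_h = glorot_matrix(d_h, d_in), U_h = glorot_matrix(d_h, d_h),
       b_h = numeric(d_h))
}

#' @rdname init_gru
#' @export
init_bigru <- function(d_in, d_h)
  list(forward = init_gru(d_in, d_h), backward = init_gru(d_in, d_h))

# one batched GRU step; x (d_in x B), h_prev (d_h x B)
gru_cell <- function(x, h_prev, p) {
  r <- sigmoid(p$W_r %*% x + p$U_r %*% h_prev + p$b_r)
  z <- sigmoid(p$W_z %*% x + p$U_z %*% h_prev + p$b_z)
  rh <- r * h_prev
  hbar <- tanh(p$W_h %*% x + p$U_h %*% rh + p$b_h)
  h <- (1 - z) * h_prev + z * hbar
  list(h = h, r = r, z = z, hbar = hbar, rh = rh, h_prev = h_prev, x = x)
}

#' One GRU step
#'
#' Computes `r = sigmoid(W_r x + U_r h)`, `z = sigmoid(W_z x + U_z h)`,
#' `h' = tanh(W_h x + U_h (r * h))` and
#' `h_new = (1 - z) * h + z * h'`.
#'
#' @param x_t input vector (length `d_in`).
#' @param h_prev previous hidden state (length `d_h`).
#' @param params from [init_gru()].
#' @return the new hidden state vector.
#' @export
gru_step <- function(x_t, h_prev, params) {
  if (length(x_t) != ncol(params$W_r) || length(h_prev) != ncol(params$U_r))
    stop("parameter error: input/hidden dimensions do not match weights")
  as.vector(gru_cell(matrix(x_t), matrix(h_prev), params)$h)
}

# full unidirectional pass over X (d_in, T, B) from a zero initial state.
# All three input projections are done in one GEMM outside the time loop.
gru_seq_forward <- function(X, p) {
  d <- dim(X); T_ <- d[2]; B <- d[3]
  d_h <- nrow(p$W_r)
  Wall <- rbind(p$W_r, p$W_z, p$W_h)
  ball <- c(p$b_r, p$b_z, p$b_h)
  Xm <- X; dim(Xm) <- c(d[1], T_ * B)
  PX <- Wall %*% Xm + ball
  dim(PX) <- c(3L * d_h, T_, B)
  ir <- seq_len(d_h); iz <- d_h + ir; ih <- 2L * d_h + ir
  h <- matrix(0, d_h, B)
  H <- array(0, c(d_h, T_, B))
  caches <- vector("list", T_)
  for (t in seq_len(T_)) {
    px <- PX[, t, ]; dim(px) <- c(3L * d_h, B)
    r <- sigmoid(px[ir, , drop = FALSE] + p$U_r %*% h)
    z <- sigmoid(px[iz, , drop = FALSE] + p$U_z %*% h)
    rh <- r * h
    hbar <- tanh(px[ih, , drop = FALSE] + p$U_h %*% rh)
    caches[[t]] <- list(r = r, z = z, hbar = hbar, rh = rh, h_prev = h)
    h <- (1 - z) * h + z * hbar
    H[, t, ] <- h
  }
  list(H = H, caches = caches, Xm = Xm, Wall = Wall)
}

gru_seq_backward <- function(dH, p, cache, d_in) {
  d <- dim(dH); T_ <- d[2]; B <- d[3]
  d_h <- d[1]
  caches <- cache$caches
  g <- lapply(p, function(m) m * 0)
  dPX <- array(0, c(3L * d_h, T_, B))
  ir <- seq_len(d_h); iz <- d_h + ir; ih <- 2L * d_h + ir
  dh_next <- matrix(0, d_h, B)
  for (t in rev(seq_len(T_))) {
    st <- caches[[t]]
    dh <- dH[, t, ]; dim(dh) <- c(d_h, B)
    dh <- dh + dh_next
    dz <- dh * (st$hbar - st$h_prev)
    dhbar <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dhbar_pre <- dhbar * (1 - st$hbar^2)
    g$U_h <- g$U_h + tcrossprod(dhbar_pre, st$rh)
    drh <- crossprod(p$U_h, dhbar_pre)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dr_pre <- dr * st$r * (1 - st$r)
    dz_pre <- dz * st$z * (1 - st$z)
    g$U_r <- g$U_r + tcrossprod(dr_pre, st$h_prev)
    g$U_z <- g$U_z + tcrossprod(dz_pre, st$h_prev)
    dh_prev <- dh_prev + crossprod(p$U_r, dr_pre) + crossprod(p$U_z, dz_pre)
    dPX[ir, t, ] <- dr_pre
    dPX[iz, t, ] <- dz_pre
    dPX[ih, t, ] <- dhbar_pre
    dh_next <- dh_prev
  }
  dim(dPX) <- c(3L * d_h, T_ * B)
  dWall <- tcrossprod(dPX, cache$Xm)
  dball <- .rowSums(dPX, 3L * d_h, T_ * B)
  g$W_r <- dWall[ir, , drop = FALSE]; g$b_r <- dball[ir]
  g$W_z <- dWall[iz, , drop = FALSE]; g$b_z <- dball[iz]
  g$W_h <- dWall[ih, , drop = FALSE]; g$b_h <- dball[ih]
  dX <- crossprod(cache$Wall, dPX)
  dim(dX) <- c(d_in, T_, B)
  list(dX = dX, grads = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bigru_forward <- function(X, p) {
  d <- dim(X); T_ <- d[2]
  fw <- gru_seq_forward(X, p$forward)
  Xr <- X[, rev(seq_len(T_)), , drop = FALSE]
  bw <- gru_seq_forward(Xr, p$backward)
  Hb <- bw$H[, rev(seq_len(T_)), , drop = FALSE]
  d_h <- dim(fw$H)[1]
  H <- array(0, c(2L * d_h, T_, d[3]))
  H[seq_len(d_h), , ] <- fw$H
  H[d_h + seq_len(d_h), , ] <- Hb
  list(H = H, fw = fw, bw = bw, d_h = d_h)
}

bigru_backward <- function(dH, p, cache, d_in) {
  d_h <- cache$d_h
  T_ <- dim(dH)[2]
  dHf <- dH[seq_len(d_h), , , drop = FALSE]
  dHb <- dH[d_h + seq_len(d_h), , , drop = FALSE]
  gf <- gru_seq_backward(dHf, p$forward, cache$fw, d_in)
  gb <- gru_seq_backward(dHb[, rev(seq_len(T_)), , drop = FALSE],
                         p$backward, cache$bw, d_in)
  list(dX = gf$dX + gb$dX[, rev(seq_len(T_)), , drop = FALSE],
       grads = list(forward = gf$grads, backward = gb$grads))
}

#' Bidirectional GRU over a sequence
#'
#' Runs one GRU left-to-right and an independent GRU right-to-left, both
#' from zero initial states, and concatenates the per-position hidden
#' states, so each position carries `2 * d_h` features.
#'
#' @param X numeric matrix with one row per position (`T x d_in`).
#' @param params from [init_bigru()].
#' @return a `T x (2 * d_h)` matrix; columns `1:d_h` are the forward
#'   states, the rest the backward states.
#' @export
bigru <- function(X, params) {
  if (!is.matrix(X) || nrow(X) == 0)
    stop("input error: X must be a non-empty positions-by-features matrix")
  Xa <- array(t(X), c(ncol(X), nrow(X), 1L))
  t(bigru_forward(Xa, params)$H[, , 1, drop = TRUE])
}

## ---- self-attention ----------------------------------------------------

#' Initialise self-attention parameters
#'
#' @param d_in input feature dimension per position.
#' @param d_att dimension of the query/key/value projections.
#' @return list of projection matrices `Wq`, `Wk`, `Wv` (each
#'   `d_att x d_in`).
#' @export
init_self_attention <- function(d_in, d_att)
  list(Wq = glorot_matrix(d_att, d_in), Wk = glorot_matrix(d_att, d_in),
       Wv = glorot_matrix(d_att, d_in))

# Xs: (d_in, T, B). Returns context (d_att, T, B) and attention (T, T, B)
# with rows of each slice summing to 1.
attn_forward <- function(Xs, p, scale = TRUE) {
  d <- dim(Xs); T_ <- d[2]; B <- d[3]
  d_att <- nrow(p$Wq)
  Xm <- Xs; dim(Xm) <- c(d[1], T_ * B)
  Q <- p$Wq %*% Xm; K <- p$Wk %*% Xm; V <- p$Wv %*% Xm
  dim(Q) <- dim(K) <- dim(V) <- c(d_att, T_, B)
  sc <- if (scale) 1 / sqrt(d_att) else 1
  ctx <- array(0, c(d_att, T_, B))
  A <- array(0, c(T_, T_, B))
  for (b in seq_len(B)) {
    S <- crossprod(Q[, , b], K[, , b]) * sc      # T x T, row = query
    S <- S - apply(S, 1, max)
    E <- exp(S)
    Ab <- E / rowSums(E)
    A[, , b] <- Ab
    ctx[, , b] <- V[, , b] %*% t(Ab)
  }
  list(ctx = ctx, A = A, Q = Q, K = K, V = V, Xm = Xm, sc = sc)
}

attn_backward <- function(dctx, p, cache) {
  d_att <- dim(cache$Q)[1]; T_ <- dim(cache$Q)[2]; B <- dim(cache$Q)[3]
  dQ <- array(0, dim(cache$Q)); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    Ab <- cache$A[, , b]
    dc <- matrix(dctx[, , b], d_att, T_)
    dV[, , b] <- dc %*% Ab
    dA <- crossprod(dc, matrix(cache$V[, , b], d_att, T_))
    dS <- Ab * (dA - rowSums(dA * Ab))
    dQ[, , b] <- cache$sc * matrix(cache$K[, , b], d_att, T_) %*% t(dS)
    dK[, , b] <- cache$sc * matrix(cache$Q[, , b], d_att, T_) %*% dS
  }
  dim(dQ) <- dim(dK) <- dim(dV) <- c(d_att, T_ * B)
  dXm <- crossprod(p$Wq, dQ) + crossprod(p$Wk, dK) + crossprod(p$Wv, dV)
  list(dX = dXm,
       grads = list(Wq = tcrossprod(dQ, cache$Xm), Wk = tcrossprod(dK, cache$Xm),
                    Wv = tcrossprod(dV, cache$Xm)))
}

#' Self-attention over a sequence
#'
#' Linear maps produce queries, keys and values; scaled dot-product
#' similarities are softmax-normalised per query so every attention row
#' sums to 1, and the context is the attention-weighted sum of values.
#'
#' @param X `T x d_in` matrix, one row per position.
#' @param params from [init_self_attention()].
#' @param scale divide similarities by `sqrt(d_att)` (recommended for
#'   numerical stability; set `FALSE` for raw dot products).
#' @return `list(context, weights)`: context is `T x d_att`, weights is
#'   the `T x T` attention map.
#' @export
self_attention <- function(X, params, scale = TRUE) {
  if (!is.matrix(X) || nrow(X) == 0)
    stop("input error: X must be a non-empty positions-by-features matrix")
  Xa <- array(t(X), c(ncol(X), nrow(X), 1L))
  r <- attn_forward(Xa, params, scale)
  list(context = t(matrix(r$ctx[, , 1], nrow(params$Wq), nrow(X))),
       weights = matrix(r$A[, , 1], nrow(X), nrow(X)))
}

## ---- classifier head ---------------------------------------------------

#' Initialise the classifier head
#'
#' @param d_in pooled feature dimension.
#' @param n_classes number of output classes (2: spurious vs true site).
#' @return list with weight matrix `W` (`n_classes x d_in`) and bias `b`.
#' @export
init_classifier <- function(d_in, n_classes = 2L)
  list(W = glorot_matrix(n_classes, d_in), b = numeric(n_classes))

#' Softmax classifier head
#'
#' A fully connected layer followed by softmax; element 2 is the
#' positive-class (true 5mC site) probability, the model score.
#'
#' @param features pooled feature vector.
#' @param params from [init_classifier()].
#' @return probability vector summing to 1.
#' @export
classifier_head <- function(features, params) {
  z <- params$W %*% matrix(features) + params$b
  as.vector(softmax_cols(z))
}
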