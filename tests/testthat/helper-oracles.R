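# Independent brute-force oracles, written as explicit scalar loops so they
# share no code with the implementation under test. x is a single feature
# map of shape (C, H, W).

o_logistic <- function(z) 1 / (1 + exp(-z))

o_mlp2 <- function(s, W1, b1, W2, b2) {
  hid <- numeric(nrow(W1))
  for (i in seq_len(nrow(W1))) {
    acc <- b1[i]
    for (j in seq_along(s)) acc <- acc + W1[i, j] * s[j]
    hid[i] <- max(acc, 0)
  }
  out <- numeric(nrow(W2))
  for (i in seq_len(nrow(W2))) {
    acc <- b2[i]
    for (j in seq_along(hid)) acc <- acc + W2[i, j] * hid[j]
    out[i] <- acc
  }
  out
}

o_channel_attention <- function(x, p) {
  C <- dim(x)[1]
  s_avg <- s_max <- numeric(C)
  for (c in seq_len(C)) {
    s_avg[c] <- mean(x[c, , ])
    s_max[c] <- max(x[c, , ])
  }
  z <- o_mlp2(s_avg, p$W1, p$b1, p$W2, p$b2) +
    o_mlp2(s_max, p$W1, p$b1, p$W2, p$b2)
  w <- o_logistic(z)
  y <- x
  for (c in seq_len(C)) y[c, , ] <- x[c, , ] * w[c]
  list(weights = w, output = y)
}

# naive same-padded 2-D convolution of a (C, H, W) map
o_conv2d <- function(x, W, b, c_out, kh, kw) {
  C <- dim(x)[1]; H <- dim(x)[2]; Wd <- dim(x)[3]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  y <- array(0, c(c_out, H, Wd))
  for (o in seq_len(c_out)) for (h in seq_len(H)) for (w in seq_len(Wd)) {
    acc <- b[o]
    for (dh in seq_len(kh)) for (dw in seq_len(kw)) for (c in seq_len(C)) {
      hh <- h + dh - 1 - ph; ww <- w + dw - 1 - pw
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= Wd) {
        # weight row order: channel fastest, then kernel row, then column
        k <- c + C * (dh - 1) + C * kh * (dw - 1)
        acc <- acc + W[o, k] * x[c, hh, ww]
      }
    }
    y[o, h, w] <- acc
  }
  y
}

o_spatial_attention <- function(x, p) {
  C <- dim(x)[1]; H <- dim(x)[2]; Wd <- dim(x)[3]
  stk <- array(0, c(2, H, Wd))
  for (h in seq_len(H)) for (w in seq_len(Wd)) {
    stk[1, h, w] <- mean(x[, h, w])
    stk[2, h, w] <- max(x[, h, w])
  }
  z <- o_conv2d(stk, p$W, p$b, 1, p$kh, p$kw)
  s <- o_logistic(z[1, , ])
  y <- x
  for (c in seq_len(C)) y[c, , ] <- x[c, , ] * s
  list(weights = s, output = y)
}

# BN (given mean/var) -> ReLU -> 3x3 conv -> channel attn -> spatial attn
o_dense_layer_eval <- function(x, p) {
  C <- dim(x)[1]
  xb <- x
  for (c in seq_len(C)) {
    xb[c, , ] <- p$bn$gamma[c] * (x[c, , ] - p$bn$mean[c]) /
      sqrt(p$bn$var[c] + 1e-5) + p$bn$beta[c]
  }
  xb[xb < 0] <- 0
  cv <- o_conv2d(xb, p$conv$W, p$conv$b, p$conv$c_out, 3, 3)
  ca <- o_channel_attention(cv, p$ca)
  o_spatial_attention(ca$output, p$sa)$output
}

# scalar-loop GRU step
o_gru_step <- function(x, h, p) {
  dh <- length(h)
  r <- z <- hb <- hn <- numeric(dh)
  for (i in seq_len(dh)) {
    a <- p$b_r[i]; b <- p$b_z[i]
    for (j in seq_along(x)) { a <- a + p$W_r[i, j] * x[j]
                              b <- b + p$W_z[i, j] * x[j] }
    for (j in seq_len(dh)) { a <- a + p$U_r[i, j] * h[j]
                             b <- b + p$U_z[i, j] * h[j] }
    r[i] <- o_logistic(a); z[i] <- o_logistic(b)
  }
  for (i in seq_len(dh)) {
    a <- p$b_h[i]
    for (j in seq_along(x)) a <- a + p$W_h[i, j] * x[j]
    for (j in seq_len(dh)) a <- a + p$U_h[i, j] * (r[j] * h[j])
    hb[i] <- tanh(a)
  }
  for (i in seq_len(dh)) hn[i] <- (1 - z[i]) * h[i] + z[i] * hb[i]
  hn
}

# loop self-attention on a T x d input
o_self_attention <- function(X, p, scale = TRUE) {
  T_ <- nrow(X); d_att <- nrow(p$Wq)
  Q <- K <- V <- matrix(0, T_, d_att)
  for (t in seq_len(T_)) for (i in seq_len(d_att)) {
    Q[t, i] <- sum(p$Wq[i, ] * X[t, ])
    K[t, i] <- sum(p$Wk[i, ] * X[t, ])
    V[t, i] <- sum(p$Wv[i, ] * X[t, ])
  }
  sc <- if (scale) 1 / sqrt(d_att) else 1
  A <- matrix(0, T_, T_)
  for (i in seq_len(T_)) {
    sim <- numeric(T_)
    for (j in seq_len(T_)) sim[j] <- sum(Q[i, ] * K[j, ]) * sc
    e <- exp(sim - max(sim))
    A[i, ] <- e / sum(e)
  }
  ctx <- matrix(0, T_, d_att)
  for (i in seq_len(T_)) for (k in seq_len(d_att))
    ctx[i, k] <- sum(A[i, ] * V[, k])
  list(context = ctx, weights = A)
}

# direct evaluation of the confusion-matrix metric formulas
o_metrics <- function(TP, TN, FP, FN) {
  den <- sqrt((TP + FP) * (TP + FN)) * sqrt((TN + FP) * (TN + FN))
  list(sn = if (TP + FN == 0) 0 else TP / (TP + FN),
       sp = if (TN + FP == 0) 0 else TN / (TN + FP),
       acc = (TP + TN) / (TP + TN + FP + FN),
       mcc = if (den == 0) 0 else (TP * TN - FP * FN) / den)
}

# all-pairs comparison AUC with ties counted half
o_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels != 1]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive threshold-sweep PR area
o_pr_auc_sweep <- function(labels, scores) {
  np <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels != 1)
    rec <- tp / np; prec <- tp / (tp + fp)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# general-position random map (no exact ties anywhere)
rand_map <- function(C, H, W, B = NULL) {
  n <- C * H * W * max(1, B %||% 1)
  x <- array(stats::rnorm(n), if (is.null(B)) c(C, H, W) else c(C, H, W, B))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parameters in general position: add noise to every trainable leaf so
# exact ties (e.g. all-zero biases) cannot mask gradient defects
noise_params <- function(p, sd = 0.05, nm = NULL) {
  if (is.list(p)) {
    nms <- names(p)
    for (i in seq_along(p))
      p[[i]] <- noise_params(p[[i]], sd, if (is.null(nms)) NULL else nms[i])
    p
  } else if (is.numeric(p) && !is.null(nm) && nm %in% deep5mC:::.TRAINABLE)
    p + stats::rnorm(length(p), 0, sd)
  else p
}
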