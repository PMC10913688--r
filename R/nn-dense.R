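## Improved dense blocks: each layer is BatchNorm -> ReLU -> 3x3 same-padded
## convolution (growth_rate output channels) -> CBAM, and consumes the
## channel-concatenation of the block input and all previous layer outputs.
## Transition layers (BatchNorm -> 1x1 convolution -> 2x2 average pooling)
## compress channels and halve the spatial extent between blocks.

#' Initialise one dense-block layer
#'
#' @param c_in input channels (for layer `l` of a block this is
#'   `block_input + (l-1) * growth_rate`).
#' @param growth_rate channels produced by the 3x3 convolution.
#' @param cbam_reduction,spatial_kernel CBAM hyperparameters; see
#'   [init_cbam()].
#' @param use_cbam attach CBAM after the convolution? Disabling it yields
#'   the primitive (unmodified) dense layer.
#' @return a parameter list with fields `bn`, `conv` and (optionally)
#'   `ca`, `sa`.
#' @export
init_dense_layer <- function(c_in, growth_rate = 12, cbam_reduction = 8,
                             spatial_kernel = 7, use_cbam = TRUE) {
  p <- list(bn = init_bn(c_in), conv = init_conv(c_in, growth_rate, 3L, 3L))
  if (use_cbam) {
    p$ca <- init_channel_attention(growth_rate, cbam_reduction)
    p$sa <- init_spatial_attention(spatial_kernel)
  }
  p
}

# cis: list(conv = conv_index for (c_in,H,W,3x3), sa = conv_index for the
# spatial-attention kernel on (2,H,W)); rs: optional env with running BN
# statistics.
dl_forward <- function(x, p, cis, training = FALSE, rs = NULL) {
  bn <- bn_forward(x, p$bn, training, rs)
  rl <- relu_forward(bn$out)
  cv <- conv2d_forward(rl$out, p$conv, cis$conv)
  if (!is.null(p$ca)) {
    ca <- ca_forward(cv$out, p$ca)
    sa <- sa_forward(ca$out, p$sa, cis$sa)
    out <- sa$out
  } else ca <- sa <- NULL
  list(out = if (is.null(sa)) cv$out else sa$out,
       cache = list(bn = bn, rl = rl, cv = cv, ca = ca, sa = sa))
}

dl_backward <- function(dy, p, cache, cis) {
  g <- list()
  if (!is.null(cache$sa)) {
    sb <- sa_backward(dy, p$sa, cache$sa$cache, cis$sa)
    cb <- ca_backward(sb$dx, p$ca, cache$ca$cache)
    g$sa <- list(W = sb$dW, b = sb$db)
    g$ca <- list(W1 = cb$dW1, b1 = cb$db1, W2 = cb$dW2, b2 = cb$db2)
    dy <- cb$dx
  }
  vb <- conv2d_backward(dy, p$conv, cache$cv, cis$conv)
  g$conv <- list(W = vb$dW, b = vb$db)
  drl <- vb$dx * cache$rl$mask
  bb <- bn_backward(drl, p$bn, cache$bn)
  g$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
  list(dx = bb$dx, grads = g)
}

#' Initialise a dense block
#'
#' @param c_in channels entering the block.
#' @param n_layers number of dense layers.
#' @inheritParams init_dense_layer
#' @return a list of `n_layers` layer parameter lists; layer `l` expects
#'   `c_in + (l-1) * growth_rate` input channels.
#' @export
init_dense_block <- function(c_in, n_layers, growth_rate = 12,
                             cbam_reduction = 8, spatial_kernel = 7,
                             use_cbam = TRUE) {
  lapply(seq_len(n_layers), function(l)
    init_dense_layer(c_in + (l - 1L) * growth_rate, growth_rate,
                     cbam_reduction, spatial_kernel, use_cbam))
}

db_forward <- function(x, layers, cis_list, training = FALSE, rs_list = NULL) {
  d <- dim(x); H <- d[2]; W <- d[3]; B <- d[4]
  cur <- x
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    r <- dl_forward(cur, layers[[l]], cis_list[[l]], training,
                    if (is.null(rs_list)) NULL else rs_list[[l]])
    caches[[l]] <- r$cache
    nxt <- array(0, c(dim(cur)[1] + dim(r$out)[1], H, W, B))
    nxt[seq_len(dim(cur)[1]), , , ] <- cur
    nxt[dim(cur)[1] + seq_len(dim(r$out)[1]), , , ] <- r$out
    cur <- nxt
  }
  list(out = cur, caches = caches, c_in = d[1])
}

db_backward <- function(dy, layers, caches, cis_list, c_in) {
  k <- dim(caches[[1]]$cv$out)[1]
  grads <- vector("list", length(layers))
  dcur <- dy
  for (l in rev(seq_along(layers))) {
    c_before <- c_in + (l - 1L) * k
    dout_l <- dcur[c_before + seq_len(k), , , , drop = FALSE]
    r <- dl_backward(dout_l, layers[[l]], caches[[l]], cis_list[[l]])
    grads[[l]] <- r$grads
    dcur <- dcur[seq_len(c_before), , , , drop = FALSE] + r$dx
  }
  list(dx = dcur, grads = grads)
}

#' Initialise a transition layer
#'
#' @param c_in channels entering the transition.
#' @param compression channel compression in (0, 1\]; the 1x1 convolution
#'   keeps `ceiling(compression * c_in)` channels.
#' @return parameter list with fields `bn` and `conv`.
#' @export
init_transition <- function(c_in, compression = 0.5) {
  if (!(compression > 0 && compression <= 1))
    stop("compression must lie in (0, 1]")
  c_out <- as.integer(ceiling(compression * c_in))
  list(bn = init_bn(c_in), conv = init_conv(c_in, c_out, 1L, 1L))
}

tr_forward <- function(x, p, training = FALSE, rs = NULL) {
  bn <- bn_forward(x, p$bn, training, rs)
  d <- dim(bn$out)
  xm <- bn$out; dim(xm) <- c(d[1], prod(d[-1]))
  y <- p$conv$W %*% xm + p$conv$b
  dim(y) <- c(p$conv$c_out, d[2], d[3], d[4])
  pl <- avgpool2_forward(y)
  list(out = pl$out, cache = list(bn = bn, xm = xm, d = d, pl = pl))
}

tr_backward <- function(dy, p, cache) {
  dgpool <- avgpool2_backward(dy, cache$pl)
  d <- cache$d
  dim(dgpool) <- c(p$conv$c_out, prod(d[-1]))
  dW <- tcrossprod(dgpool, cache$xm)
  db <- rowSums(dgpool)
  dxm <- crossprod(p$conv$W, dgpool)
  dim(dxm) <- d
  bb <- bn_backward(dxm, p$bn, cache$bn)
  list(dx = bb$dx,
       grads = list(bn = list(gamma = bb$dgamma, beta = bb$dbeta),
                    conv = list(W = dW, b = db)))
}

## ---- public wrappers ---------------------------------------------------

#' One improved dense-block layer
#'
#' BatchNorm, ReLU, 3x3 same-padded convolution to `growth_rate` channels,
#' then CBAM (when the parameters carry it). Height and width are
#' unchanged. In evaluation mode (the default) batch normalisation uses
#' the stored running statistics.
#'
#' @param x feature map of shape (channels, height, width) or with a
#'   trailing batch axis.
#' @param params from [init_dense_layer()].
#' @param training use batch statistics in BatchNorm?
#' @return the layer output map.
#' @export
dense_layer <- function(x, params, training = FALSE) {
  single <- length(dim(x)) == 3L
  x4 <- as_map4(x)
  d <- dim(x4)
  cis <- list(conv = conv_index(d[1], d[2], d[3], 3L, 3L),
              sa = if (!is.null(params$sa))
                conv_index(2L, d[2], d[3], params$sa$kh, params$sa$kw))
  r <- dl_forward(x4, params, cis, training = training)
  if (single) drop_batch(r$out) else r$out
}

#' A dense block
#'
#' Layer `l` consumes the channel-concatenation of the block input and all
#' previous layer outputs; the block output concatenates the input with
#' every layer output, so output channels equal
#' `c_in + n_layers * growth_rate` and the first `c_in` channels are the
#' input passed through unchanged.
#'
#' @inheritParams dense_layer
#' @param params from [init_dense_block()].
#' @return the concatenated block output map.
#' @export
dense_block <- function(x, params, training = FALSE) {
  single <- length(dim(x)) == 3L
  x4 <- as_map4(x)
  d <- dim(x4)
  k <- params[[1]]$conv$c_out
  cis <- lapply(seq_along(params), function(l) {
    list(conv = conv_index(d[1] + (l - 1L) * k, d[2], d[3], 3L, 3L),
         sa = if (!is.null(params[[l]]$sa))
           conv_index(2L, d[2], d[3], params[[l]]$sa$kh, params[[l]]$sa$kw))
  })
  r <- db_forward(x4, params, cis, training = training)
  if (single) drop_batch(r$out) else r$out
}

#' A transition layer
#'
#' BatchNorm, 1x1 convolution compressing channels to
#' `ceiling(compression * c_in)`, then 2x2 average pooling with stride 2
#' and ceiling-mode output sizes (a dimension of size 1 stays 1; it never
#' collapses to 0).
#'
#' @inheritParams dense_layer
#' @param params from [init_transition()].
#' @return the compressed, pooled map.
#' @export
transition_layer <- function(x, params, training = FALSE) {
  single <- length(dim(x)) == 3L
  r <- tr_forward(as_map4(x), params, training = training)
  if (single) drop_batch(r$out) else r$out
}
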