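## CBAM: channel attention followed by spatial attention.

#' Initialise CBAM parameters
#'
#' The channel module is a shared two-layer bottleneck applied to the
#' globally max- and average-pooled channel vectors; the spatial module is
#' a same-padded `kernel x kernel` convolution over the stacked
#' channel-wise average and max maps.
#'
#' @param channels number of input channels.
#' @param reduction bottleneck reduction ratio; the hidden width is
#'   `max(1, channels %/% reduction)`.
#' @param spatial_kernel odd convolution kernel size of the spatial module.
#' @return `list(channel = , spatial = )` parameter lists.
#' @export
init_cbam <- function(channels, reduction = 8, spatial_kernel = 7) {
  list(channel = init_channel_attention(channels, reduction),
       spatial = init_spatial_attention(spatial_kernel))
}

#' @rdname init_cbam
#' @export
init_channel_attention <- function(channels, reduction = 8) {
  hid <- max(1L, channels %/% reduction)
  list(W1 = he_matrix(hid, channels), b1 = numeric(hid),
       W2 = he_matrix(channels, hid), b2 = numeric(channels),
       reduction = reduction)
}

#' @rdname init_cbam
#' @export
init_spatial_attention <- function(spatial_kernel = 7) {
  if (spatial_kernel %% 2 != 1) stop("spatial kernel must be odd")
  init_conv(2L, 1L, spatial_kernel, spatial_kernel)
}

## ---- channel attention -------------------------------------------------

ca_forward <- function(x, p) {
  if (any(!is.finite(x))) stop("numeric error: non-finite input")
  d <- dim(x); C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  x3 <- x; dim(x3) <- c(C, HW, B)
  red <- spatial_reduce(x3, C, HW, B)
  mlp <- function(s) {
    h_pre <- p$W1 %*% s + p$b1
    h <- h_pre * (h_pre > 0)
    list(out = p$W2 %*% h + p$b2, h = h, h_pre = h_pre)
  }
  pa <- mlp(red$avg); pm <- mlp(red$mx)
  a <- sigmoid(pa$out + pm$out)              # C x B channel weights
  j <- rep(seq_len(B), each = HW)
  abig <- a[, j, drop = FALSE]
  xm <- x; dim(xm) <- c(C, HW * B)
  y <- xm * abig
  dim(y) <- d
  list(out = y, weights = a,
       cache = list(xm = xm, abig = abig, a = a, red = red, pa = pa,
                    pm = pm, d = d, C = C, HW = HW, B = B, j = j))
}

ca_backward <- function(dy, p, cache) {
  C <- cache$C; HW <- cache$HW; B <- cache$B
  dym <- dy; dim(dym) <- c(C, HW * B)
  dx <- dym * cache$abig
  dacc <- dym * cache$xm
  dim(dacc) <- c(C, HW, B)
  da <- mid_sum(dacc, C, HW, B)
  dz <- da * cache$a * (1 - cache$a)
  bwd_mlp <- function(pc, s) {
    dh <- crossprod(p$W2, dz)
    dh_pre <- dh * (pc$h_pre > 0)
    list(dW2 = tcrossprod(dz, pc$h), db2 = rowSums(dz),
         dW1 = tcrossprod(dh_pre, s), db1 = rowSums(dh_pre),
         ds = crossprod(p$W1, dh_pre))
  }
  ga <- bwd_mlp(cache$pa, cache$red$avg)
  gm <- bwd_mlp(cache$pm, cache$red$mx)
  # average-pooling path spreads ds/HW over every spatial position
  dx <- dx + (ga$ds / HW)[, cache$j, drop = FALSE]
  # max-pooling path routes ds to each channel's argmax position
  cb <- seq_len(C * B) - 1L
  cvec <- cb %% C + 1L
  bvec <- cb %/% C + 1L
  lin <- cvec + C * (cache$red$arg - 1L) + C * HW * (bvec - 1L)
  dx[lin] <- dx[lin] + as.vector(gm$ds)
  dim(dx) <- cache$d
  list(dx = dx,
       dW1 = ga$dW1 + gm$dW1, db1 = ga$db1 + gm$db1,
       dW2 = ga$dW2 + gm$dW2, db2 = ga$db2 + gm$db2)
}

## ---- spatial attention -------------------------------------------------

sa_forward <- function(x, p, ci) {
  if (any(!is.finite(x))) stop("numeric error: non-finite input")
  d <- dim(x); C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  xm <- x; dim(xm) <- c(C, HW * B)
  cm <- .colSums(xm, C, HW * B) / C             # channel-wise mean map
  r <- channel_max(xm, C, HW * B)               # channel-wise max map
  mx <- r$mx; arg <- r$arg
  stacked <- rbind(cm, mx)                      # 2 x (HW*B): avg, max
  dim(stacked) <- c(2L, d[2], d[3], B)
  cv <- conv2d_forward(stacked, p, ci)
  s <- sigmoid(as.vector(cv$out))               # HW*B spatial weights
  y <- xm * rep(s, each = C)
  dim(y) <- d
  wmap <- s; dim(wmap) <- c(d[2], d[3], B)
  list(out = y, weights = wmap,
       cache = list(xm = xm, s = s, arg = arg, cv = cv, d = d, C = C,
                    HW = HW, B = B))
}

sa_backward <- function(dy, p, cache, ci) {
  C <- cache$C; HW <- cache$HW; B <- cache$B
  dym <- dy; dim(dym) <- c(C, HW * B)
  dx <- dym * rep(cache$s, each = C)
  ds <- .colSums(dym * cache$xm, C, HW * B)
  dz <- ds * cache$s * (1 - cache$s)
  dim(dz) <- c(1L, cache$d[2], cache$d[3], B)
  cb <- conv2d_backward(dz, p, cache$cv, ci)
  dstk <- cb$dx; dim(dstk) <- c(2L, HW * B)
  dcm <- dstk[1L, ]; dmx <- dstk[2L, ]
  dx <- dx + matrix(rep(dcm / C, each = C), C)
  lin <- cache$arg + C * (seq_len(HW * B) - 1L)
  dx[lin] <- dx[lin] + dmx
  dim(dx) <- cache$d
  list(dx = dx, dW = cb$dW, db = cb$db)
}

## ---- public single-map wrappers ---------------------------------------

as_map4 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L)
    stop("expected a feature map of shape (channels, height, width)")
  x
}

drop_batch <- function(x) { d <- dim(x); dim(x) <- d[-4]; x }

#' Channel attention over a feature map
#'
#' Global max- and average-pooling compress the map to two per-channel
#' vectors; both pass through one shared two-layer bottleneck, their sum
#' goes through the logistic function, and the resulting per-channel
#' weights in (0,1) rescale the input.
#'
#' @param x feature map array of shape (channels, height, width) or
#'   (channels, height, width, batch).
#' @param params parameters from [init_channel_attention()].
#' @return `list(weights, output)`; `output` has the shape of `x`.
#' @export
channel_attention <- function(x, params) {
  single <- length(dim(x)) == 3L
  r <- ca_forward(as_map4(x), params)
  if (single) list(weights = r$weights[, 1], output = drop_batch(r$out))
  else list(weights = r$weights, output = r$out)
}

#' Spatial attention over a feature map
#'
#' The channel-wise average and max maps are stacked into a 2-channel map,
#' convolved with a same-padded odd kernel to a single channel, passed
#' through the logistic function, and the resulting per-position weights
#' in (0,1) rescale every channel of the input.
#'
#' @inheritParams channel_attention
#' @param params parameters from [init_spatial_attention()].
#' @return `list(weights, output)`.
#' @export
spatial_attention <- function(x, params) {
  single <- length(dim(x)) == 3L
  x4 <- as_map4(x)
  d <- dim(x4)
  ci <- conv_index(2L, d[2], d[3], params$kh, params$kw)
  r <- sa_forward(x4, params, ci)
  if (single) list(weights = r$weights[, , 1], output = drop_batch(r$out))
  else list(weights = r$weights, output = r$out)
}

#' Convolutional block attention (CBAM)
#'
#' Applies channel attention, then spatial attention to the
#' channel-weighted map; the output shape equals the input shape.
#'
#' @inheritParams channel_attention
#' @param params parameters from [init_cbam()].
#' @return the reweighted feature map.
#' @export
cbam <- function(x, params) {
  y <- channel_attention(x, params$channel)$output
  spatial_attention(y, params$spatial)$output
}
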