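## Full model: encoded window (rows x L, entering as a 1-channel 2-D map)
## -> dense blocks with CBAM, transitions between consecutive blocks (no
## initial convolution) -> width-indexed sequence -> BiGRU ->
## self-attention -> mean-pooled context -> softmax head.

#' Model configuration
#'
#' All architectural hyperparameters with their defaults: four dense
#' blocks of four layers at growth rate 12, compression 0.5 transitions,
#' CBAM with reduction 8 and a 7-wide spatial kernel, a 64-unit BiGRU,
#' 64-dimensional self-attention, dropout 0.2 before the head.
#'
#' @param encoding input encoding: `"merged"` (7 rows), `"onehot"` (4) or
#'   `"ncp"` (3).
#' @param num_dense_blocks number of dense blocks (transitions sit between
#'   consecutive blocks, so there are `num_dense_blocks - 1` of them).
#' @param layers_per_block dense layers per block.
#' @param growth_rate channels added by each dense layer.
#' @param compression transition channel compression in (0, 1].
#' @param cbam_reduction,spatial_kernel CBAM hyperparameters.
#' @param gru_hidden hidden units per GRU direction.
#' @param attention_dim query/key/value dimension of the self-attention.
#' @param dropout dropout probability on the pooled context (training
#'   only).
#' @param window_length input window length in nucleotides.
#' @param use_cbam disable to obtain the primitive (unmodified) dense
#'   blocks.
#' @param attn_scale scale attention similarities by
#'   `1 / sqrt(attention_dim)`.
#' @param seed integer seed fixing parameter initialisation.
#' @return an object of class `m5c_config`.
#' @export
model_config <- function(encoding = "merged", num_dense_blocks = 4,
                         layers_per_block = 4, growth_rate = 12,
                         compression = 0.5, cbam_reduction = 8,
                         spatial_kernel = 7, gru_hidden = 64,
                         attention_dim = 64, dropout = 0.2,
                         window_length = 41, use_cbam = TRUE,
                         attn_scale = TRUE, seed = 1) {
  stopifnot(num_dense_blocks >= 1, layers_per_block >= 1, growth_rate >= 1,
            compression > 0, compression <= 1, cbam_reduction >= 1,
            spatial_kernel %% 2 == 1, gru_hidden >= 1, attention_dim >= 1,
            dropout >= 0, dropout < 1, window_length >= 1)
  encoding <- match.arg(encoding, c("merged", "onehot", "ncp"))
  structure(as.list(environment()), class = "m5c_config")
}

#' Desk-scale model preset
#'
#' A reduced configuration for laptop-scale experiments and the synthetic
#' benchmark: two dense blocks of two layers at growth rate 8, a 16-unit
#' BiGRU and 16-dimensional self-attention. It keeps every architectural
#' ingredient of the full model (CBAM, transition, BiGRU, self-attention)
#' at a fraction of the cost; the full-scale defaults of [model_config()]
#' remain available for larger runs.
#'
#' @param ... overrides passed to [model_config()].
#' @return an `m5c_config`.
#' @export
small_config <- function(...) {
  args <- list(num_dense_blocks = 2, layers_per_block = 2, growth_rate = 8,
               gru_hidden = 16, attention_dim = 16)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

encoding_rows <- function(encoding)
  switch(encoding, merged = 7L, onehot = 4L, ncp = 3L)

# closed-form shape bookkeeping: channels follow c + L*k per block and
# ceiling(compression * c) per transition; height/width follow
# ceiling-mode 2x2/stride-2 pooling.
model_shapes <- function(config) {
  C <- 1L; H <- encoding_rows(config$encoding); W <- config$window_length
  shapes <- list(list(stage = "input", C = C, H = H, W = W))
  for (i in seq_len(config$num_dense_blocks)) {
    C <- C + config$layers_per_block * config$growth_rate
    shapes[[length(shapes) + 1L]] <-
      list(stage = paste0("dense_block_", i), C = C, H = H, W = W)
    if (i < config$num_dense_blocks) {
      C <- as.integer(ceiling(config$compression * C))
      H <- as.integer(ceiling(H / 2)); W <- as.integer(ceiling(W / 2))
      shapes[[length(shapes) + 1L]] <-
        list(stage = paste0("transition_", i), C = C, H = H, W = W)
    }
  }
  if (C < 1 || H < 1 || W < 1)
    stop("configuration error: a zero-size intermediate feature map")
  list(table = shapes, C = C, H = H, W = W, T = W, D = C * H)
}

#' Build the full model
#'
#' Assembles dense blocks, transitions, BiGRU, self-attention and the
#' classifier head with freshly initialised parameters (seeded by
#' `config$seed`) and reports the total trainable parameter count.
#'
#' @param config a [model_config()].
#' @param quiet suppress the parameter-count message.
#' @return an object of class `deep5mc_model`.
#' @examples
#' m <- build_model(model_config(num_dense_blocks = 2, layers_per_block = 1,
#'                               growth_rate = 4, gru_hidden = 8,
#'                               attention_dim = 8), quiet = TRUE)
#' m$n_params
#' @export
build_model <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "m5c_config"))
  sh <- model_shapes(config)
  set.seed(config$seed)
  C <- 1L; H <- encoding_rows(config$encoding); W <- config$window_length
  blocks <- list(); trans <- list(); arch <- list()
  state <- list(blocks = list(), trans = list())
  for (i in seq_len(config$num_dense_blocks)) {
    blocks[[i]] <- init_dense_block(C, config$layers_per_block,
                                    config$growth_rate,
                                    config$cbam_reduction,
                                    config$spatial_kernel, config$use_cbam)
    sa_ci <- if (config$use_cbam)
      conv_index(2L, H, W, config$spatial_kernel, config$spatial_kernel)
    arch$blocks[[i]] <- lapply(seq_len(config$layers_per_block), function(l)
      list(conv = conv_index(C + (l - 1L) * config$growth_rate, H, W, 3L, 3L),
           sa = sa_ci))
    state$blocks[[i]] <- lapply(blocks[[i]], function(lp) {
      e <- new.env(parent = emptyenv())
      e$mean <- lp$bn$mean; e$var <- lp$bn$var; e
    })
    C <- C + config$layers_per_block * config$growth_rate
    if (i < config$num_dense_blocks) {
      trans[[i]] <- init_transition(C, config$compression)
      e <- new.env(parent = emptyenv())
      e$mean <- trans[[i]]$bn$mean; e$var <- trans[[i]]$bn$var
      state$trans[[i]] <- e
      C <- as.integer(ceiling(config$compression * C))
      H <- as.integer(ceiling(H / 2)); W <- as.integer(ceiling(W / 2))
    }
  }
  params <- list(blocks = blocks, trans = trans,
                 gru = init_bigru(sh$D, config$gru_hidden),
                 attn = init_self_attention(2L * config$gru_hidden,
                                            config$attention_dim),
                 head = init_classifier(config$attention_dim, 2L))
  model <- structure(list(config = config, params = params, state = state,
                          arch = arch, shapes = sh,
                          n_params = count_params(params)),
                     class = "deep5mc_model")
  if (!quiet)
    message("built model: ", config$num_dense_blocks, " dense blocks, ",
            format(model$n_params, big.mark = ","), " trainable parameters")
  model
}

.TRAINABLE <- c("W", "b", "W1", "b1", "W2", "b2", "gamma", "beta",
                "W_r", "U_r", "b_r", "W_z", "U_z", "b_z", "W_h", "U_h",
                "b_h", "Wq", "Wk", "Wv")

# nested list of trainable arrays only (drops BN buffers and metadata)
trainable_params <- function(p, name = NULL) {
  if (is.list(p)) {
    nms <- names(p)
    out <- list()
    for (i in seq_along(p)) {
      r <- trainable_params(p[[i]], if (is.null(nms)) NULL else nms[i])
      if (!is.null(r)) {
        if (is.null(nms)) out[[length(out) + 1L]] <- r
        else out[[nms[i]]] <- r
      }
    }
    if (length(out)) out else NULL
  } else if (is.numeric(p) && !is.null(name) && name %in% .TRAINABLE) p
  else NULL
}

count_params <- function(params) {
  tot <- 0
  rapply(trainable_params(params), function(x) tot <<- tot + length(x))
  as.integer(tot)
}

## ---- batched forward / backward ---------------------------------------

# x: encoded array (rows, L, B) or 4-d (1, rows, L, B)
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  B <- dim(x)[4]
  cur <- x
  bl_caches <- list(); tr_caches <- list()
  for (i in seq_len(cfg$num_dense_blocks)) {
    r <- db_forward(cur, model$params$blocks[[i]], model$arch$blocks[[i]],
                    training, model$state$blocks[[i]])
    bl_caches[[i]] <- r
    cur <- r$out
    if (i < cfg$num_dense_blocks) {
      r <- tr_forward(cur, model$params$trans[[i]], training,
                      model$state$trans[[i]])
      tr_caches[[i]] <- r$cache
      cur <- r$out
    }
  }
  map_dim <- dim(cur)
  Xs <- cur; dim(Xs) <- c(map_dim[1] * map_dim[2], map_dim[3], B)
  gr <- bigru_forward(Xs, model$params$gru)
  at <- attn_forward(gr$H, model$params$attn, cfg$attn_scale)
  d_att <- cfg$attention_dim; T_ <- dim(at$ctx)[2]
  pooled <- mid_sum(at$ctx, d_att, T_, B) / T_
  if (training && cfg$dropout > 0) {
    mask <- (stats::runif(length(pooled)) >= cfg$dropout) / (1 - cfg$dropout)
    dim(mask) <- dim(pooled)
    pooled_d <- pooled * mask
  } else {
    mask <- NULL
    pooled_d <- pooled
  }
  logits <- model$params$head$W %*% pooled_d + model$params$head$b
  probs <- softmax_cols(logits)
  list(probs = probs, logits = logits,
       cache = list(bl = bl_caches, tr = tr_caches, gr = gr, at = at,
                    pooled_d = pooled_d, mask = mask, map_dim = map_dim,
                    T_ = T_, B = B))
}

model_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  cache <- fw$cache
  g <- list()
  g$head <- list(W = tcrossprod(dlogits, cache$pooled_d), b = rowSums(dlogits))
  dpooled <- crossprod(model$params$head$W, dlogits)
  if (!is.null(cache$mask)) dpooled <- dpooled * cache$mask
  T_ <- cache$T_; B <- cache$B; d_att <- cfg$attention_dim
  dctx <- array(0, c(d_att, T_, B))
  dp <- dpooled / T_
  for (t in seq_len(T_)) dctx[, t, ] <- dp
  ab <- attn_backward(dctx, model$params$attn, cache$at)
  g$attn <- ab$grads
  dH <- ab$dX; dim(dH) <- c(2L * cfg$gru_hidden, T_, B)
  gb <- bigru_backward(dH, model$params$gru, cache$gr,
                       d_in = cache$map_dim[1] * cache$map_dim[2])
  g$gru <- gb$grads
  dcur <- gb$dX
  dim(dcur) <- c(cache$map_dim[1:3], B)
  g$blocks <- vector("list", cfg$num_dense_blocks)
  g$trans <- if (cfg$num_dense_blocks > 1)
    vector("list", cfg$num_dense_blocks - 1L) else list()
  for (i in rev(seq_len(cfg$num_dense_blocks))) {
    if (i < cfg$num_dense_blocks) {
      r <- tr_backward(dcur, model$params$trans[[i]], cache$tr[[i]])
      g$trans[[i]] <- r$grads
      dcur <- r$dx
    }
    r <- db_backward(dcur, model$params$blocks[[i]], cache$bl[[i]]$caches,
                     model$arch$blocks[[i]], cache$bl[[i]]$c_in)
    g$blocks[[i]] <- r$grads
    dcur <- r$dx
  }
  g
}

#' Predict positive-class probabilities
#'
#' Runs the model in evaluation mode (BatchNorm running statistics, no
#' dropout) over a labelled dataset or a pre-encoded array.
#'
#' @param model a trained [build_model()] object.
#' @param newdata a [m5c_dataset()] or an encoded array
#'   (`rows x length x n`) matching the model's encoding.
#' @param batch_size forward-pass batch size.
#' @return numeric vector of probabilities that each window is a true 5mC
#'   site, named by sequence id where available.
#' @export
predict_proba <- function(model, newdata, batch_size = 256) {
  stopifnot(inherits(model, "deep5mc_model"))
  x <- if (inherits(newdata, "m5c_dataset"))
    encode_dataset(newdata, model$config$encoding) else newdata
  n <- dim(x)[3]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    fw <- model_forward(model, x[, , idx, drop = FALSE], training = FALSE)
    out[idx] <- fw$probs[2L, ]
  }
  names(out) <- dimnames(x)[[3]]
  out
}

#' Describe a model's stages and shapes
#'
#' @param model a [build_model()] object.
#' @return data frame of stage names and output shapes
#'   (channels x height x width), with the trainable parameter count as an
#'   attribute.
#' @export
describe_model <- function(model) {
  stopifnot(inherits(model, "deep5mc_model"))
  tab <- do.call(rbind, lapply(model$shapes$table, as.data.frame))
  seq_rows <- data.frame(
    stage = c("sequence", "bigru", "self_attention", "head"),
    C = c(model$shapes$D, 2L * model$config$gru_hidden,
          model$config$attention_dim, 2L),
    H = 1L, W = c(model$shapes$T, model$shapes$T, model$shapes$T, 1L))
  out <- rbind(tab, seq_rows)
  attr(out, "n_params") <- model$n_params
  out
}

#' @export
print.deep5mc_model <- function(x, ...) {
  cat("<deep5mc_model>", x$config$num_dense_blocks, "dense blocks x",
      x$config$layers_per_block, "layers, growth", x$config$growth_rate,
      if (x$config$use_cbam) "+ CBAM" else "(no CBAM)", "\n")
  tab <- describe_model(x)
  cat(paste0("  ", format(tab$stage, width = 16), tab$C, " x ", tab$H,
             " x ", tab$W, collapse = "\n"), "\n")
  cat("  trainable parameters:", format(x$n_params, big.mark = ","), "\n")
  invisible(x)
}

## ---- Adam on nested gradient structures -------------------------------

adam_update <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  if (is.list(g)) {
    if (is.null(m)) { m <- vector("list", length(g)); v <- m }
    nms <- names(g)
    for (i in seq_along(g)) {
      key <- if (is.null(nms) || nms[i] == "") i else nms[i]
      r <- adam_update(p[[key]], g[[i]],
                       if (length(m) >= i) m[[i]] else NULL,
                       if (length(v) >= i) v[[i]] else NULL,
                       lr, t, beta1, beta2, eps)
      p[[key]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else {
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
}
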