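## Single-file text checkpoints: JSON holding the configuration, every
## parameter array (with shapes) and the BatchNorm running statistics.

pack_params <- function(p) {
  if (is.list(p)) lapply(p, pack_params)
  else if (is.numeric(p)) list(.dim = dim(p), .data = as.vector(p))
  else p
}

unpack_params <- function(p) {
  if (is.list(p) && !is.null(p$.data)) {
    x <- as.numeric(p$.data)
    if (!is.null(p$.dim) && length(p$.dim)) dim(x) <- as.integer(p$.dim)
    x
  } else if (is.list(p)) lapply(p, unpack_params)
  else p
}

#' Save a model checkpoint
#'
#' Writes configuration, parameters and BatchNorm running statistics to a
#' single JSON file at full numeric precision.
#'
#' @param model a [build_model()] (possibly trained) object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "deep5mc_model"))
  obj <- list(format = "deep5mC-checkpoint", format_version = 1L,
              config = unclass(model$config),
              params = pack_params(model$params),
              state = pack_params(snapshot_state(model$state)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "deep5mC-checkpoint"))
    stop("not a deep5mC checkpoint: ", path)
  cfg_args <- obj$config[names(obj$config) %in% names(formals(model_config))]
  config <- do.call(model_config, cfg_args)
  model <- build_model(config, quiet = TRUE)
  model$params <- unpack_params(obj$params)
  restore_state(model$state, unpack_params(obj$state))
  model$n_params <- count_params(model$params)
  model
}
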