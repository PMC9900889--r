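#' Save a parameter checkpoint
#'
#' Writes the seven parameter groups, architecture sizes, and optional
#' metadata to a portable JSON container (one named entry per parameter
#' group plus a metadata block).
#'
#' @param object An `rnn_fit` or `rnn_params`.
#' @param path Output file path.
#' @param metadata Optional named list stored alongside the parameters.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path, metadata = list()) {
  params <- if (inherits(object, "rnn_fit")) object$params else object
  check_params(params)
  if (inherits(object, "rnn_fit")) {
    metadata <- c(metadata, list(
      task = unclass(object$task),
      train_config = unclass(object$config)
    ))
  }
  payload <- list(
    params = lapply(
      params[c("A", "B", "beta", "C", "alpha", "D", "gamma")], unclass
    ),
    sizes = list(
      n_units = params$n_units, n_states = params$n_states,
      n_spatial_dims = params$n_spatial_dims
    ),
    metadata = metadata
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a parameter checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A list with `params` (an `rnn_params`) and `metadata`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- payload$params
  params <- structure(
    list(
      A = as.matrix(p$A), B = as.matrix(p$B), beta = as.vector(p$beta),
      C = as.matrix(p$C), alpha = as.vector(p$alpha),
      D = as.matrix(p$D), gamma = as.vector(p$gamma),
      n_units = as.integer(payload$sizes$n_units),
      n_states = as.integer(payload$sizes$n_states),
      n_spatial_dims = as.integer(payload$sizes$n_spatial_dims)
    ),
    class = "rnn_params"
  )
  list(params = params, metadata = payload$metadata)
}
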