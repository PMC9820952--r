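#' Save a model checkpoint
#'
#' The checkpoint bundles the parameter collection, the network
#' configuration, the initialisation seed, fitted preprocessing statistics
#' (when present) and the configuration hash in a single file.
#'
#' @param model a `mm_model`.
#' @param path destination file (conventionally `.rds`).
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mm_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint file.
#' @return A `mm_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  m <- readRDS(path)
  class(m$cfg) <- "mm_network_config"
  structure(m, class = "mm_model")
}
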