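#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the named parameter map and an
#' echo of the architecture configuration, so a model can be rebuilt and
#' verified on load.
#'
#' @param model a `u2net_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `u2net_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "u2net_model"))
  saveRDS(list(format = "spectboost-checkpoint-1",
               config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "spectboost-checkpoint-1"))
    stop("not a spectboost checkpoint: ", path)
  structure(list(config = ck$config, params = ck$params), class = "u2net_model")
}
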