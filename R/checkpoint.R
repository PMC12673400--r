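# Model persistence: a single-file checkpoint holding the configuration,
# all weights, the training history and an alphabet fingerprint.

CHECKPOINT_FORMAT <- "pepfunnel-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' @param model A `pf_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pf_model"))
  obj <- list(
    format = CHECKPOINT_FORMAT,
    version = CHECKPOINT_VERSION,
    config = unclass(model$config),
    params = model$params,
    history = model$history,
    alphabet = model$alphabet
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Restores a model saved with [save_checkpoint()]. The configuration
#' round-trips exactly and predictions agree with the saved model to
#' numerical identity. Corrupt, truncated or foreign files raise an error
#' without yielding a partial model.
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A `pf_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop2("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop2("cannot read checkpoint '", path, "': ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, CHECKPOINT_FORMAT)) {
    stop2("file is not a pepfunnel checkpoint: ", path)
  }
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    stop2("unsupported checkpoint version: ", obj$version)
  }
  if (!identical(obj$alphabet, paste(residue_alphabet(), collapse = ""))) {
    stop2("checkpoint alphabet does not match this package's alphabet")
  }
  cfg <- do.call(model_config, obj$config)
  model <- list(config = cfg, params = obj$params, history = obj$history,
                alphabet = obj$alphabet)
  class(model) <- "pf_model"
  model
}
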