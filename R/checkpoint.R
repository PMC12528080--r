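CHECKPOINT_VERSION <- 1L

#' Save a fit or model checkpoint
#'
#' Single-file, versioned checkpoint with the full parameter set, the
#' architecture and training configuration, the prior/pathway objects
#' and split bookkeeping embedded, so a reload reproduces predictions
#' bit-identically.
#'
#' @param object a [pf_fit()] or [pf_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
pf_save <- function(object, path) {
  saveRDS(list(version = CHECKPOINT_VERSION,
               class = class(object)[1],
               object = object),
          path)
  invisible(path)
}

#' Load a checkpoint written by [pf_save()]
#'
#' @param path checkpoint file.
#' @return the saved [pf_fit()] or [pf_model()].
#' @export
pf_load <- function(path) {
  if (!file.exists(path)) abort(paste0("checkpoint not found: ", path))
  ck <- readRDS(path)
  if (!identical(ck$version, CHECKPOINT_VERSION))
    abort(sprintf("unsupported checkpoint version %s", ck$version))
  ck$object
}
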