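# Checkpoint container: a single RDS file holding named sub-trees
# {encoder, contextualizer, heads} plus configurations and a schema
# version, so that encoder-only loading (fine-tune variants 2/6) and
# resumable optimization are supported.

.CHECKPOINT_SCHEMA <- 1L

#' Save a model checkpoint
#'
#' @param model Model list (`enc_params`, `ctx_params`, `enc_cfg`,
#'   `ctx_cfg`).
#' @param path Output path.
#' @param opt_state Optional optimizer state (for resuming).
#' @param step Last completed optimization step.
#' @param heads Optional named list of classification heads.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, opt_state = NULL, step = 0L,
                            heads = NULL) {
  obj <- list(schema = .CHECKPOINT_SCHEMA,
              enc_params = model$enc_params, ctx_params = model$ctx_params,
              enc_cfg = model$enc_cfg, ctx_cfg = model$ctx_cfg,
              opt_state = opt_state, step = as.integer(step), heads = heads)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The checkpoint list (schema-checked).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema > .CHECKPOINT_SCHEMA) {
    stop("incompatible checkpoint schema: ",
         if (is.null(obj$schema)) "missing" else obj$schema)
  }
  obj
}
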