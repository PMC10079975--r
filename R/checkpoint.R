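# Checkpoint serialization: a single JSON document holding the config
# header and every weight tensor at full precision. Text-based on
# purpose (portable, diffable, no binary artifacts).

#' Save model parameters to a checkpoint file
#'
#' @param params A `gbert_params`.
#' @param path Output path (JSON).
#' @export
save_checkpoint <- function(params, path) {
  ser_tensor <- function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = length(x), data = as.numeric(x))
  }
  doc <- list(
    format = "pairGBERT-checkpoint-v1",
    config = params$config,
    tensors = list(
      W_embed = ser_tensor(params$W_embed),
      b_embed = ser_tensor(params$b_embed),
      W_res = ser_tensor(params$W_res),
      b_res = ser_tensor(params$b_res),
      W_cls = ser_tensor(params$W_cls),
      b_cls = ser_tensor(params$b_cls),
      layers = lapply(params$layers, function(lw) lapply(lw, ser_tensor))
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load model parameters from a checkpoint file
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return A `gbert_params`.
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "pairGBERT-checkpoint-v1")) {
    gb_stop("gb_config", "not a recognized checkpoint: %s", path)
  }
  de_tensor <- function(t) {
    d <- unlist(t$dim)
    x <- as.numeric(unlist(t$data))
    if (length(d) == 2L) matrix(x, d[1], d[2]) else x
  }
  cfg <- doc$config
  for (nm in c("d_in", "d_h", "k", "n_layers", "heads", "max_hop")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  for (nm in c("hidden_dropout", "attention_dropout", "alpha")) {
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  }
  cfg$pure_eq3 <- isTRUE(cfg$pure_eq3)
  cfg$readout <- cfg$readout %||% "target"
  tn <- doc$tensors
  structure(list(
    W_embed = de_tensor(tn$W_embed), b_embed = de_tensor(tn$b_embed),
    W_res = de_tensor(tn$W_res), b_res = de_tensor(tn$b_res),
    layers = lapply(tn$layers, function(lw) lapply(lw, de_tensor)),
    W_cls = de_tensor(tn$W_cls), b_cls = de_tensor(tn$b_cls),
    config = cfg
  ), class = "gbert_params")
}
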