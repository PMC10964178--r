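# Model containers and checkpointing. A checkpoint is a single-file archive
# (versioned header) holding every parameter array keyed by hierarchical
# name plus the configurations needed to rebuild the models.

#' Build the full model set: two generators and two discriminators
#' @param gen_config Generator configuration for the OCT-to-H&E direction;
#'   the reverse generator mirrors its channel counts.
#' @param disc_base_width Base width of both patch discriminators.
#' @param seed Master seed for all parameter initialization.
#' @return List with `g_oh`, `g_ho`, `d_h`, `d_o`.
#' @export
models_new <- function(gen_config = generator_config(), disc_base_width = 16L,
                       seed = 1L) {
  cfg_ho <- gen_config
  cfg_ho$in_channels <- gen_config$out_channels
  cfg_ho$out_channels <- gen_config$in_channels
  list(
    g_oh = generator_new(gen_config, seed = seed * 4L + 1L),
    g_ho = generator_new(cfg_ho, seed = seed * 4L + 2L),
    d_h = discriminator_new(discriminator_config(gen_config$out_channels,
                                                 disc_base_width),
                            seed = seed * 4L + 3L),
    d_o = discriminator_new(discriminator_config(gen_config$in_channels,
                                                 disc_base_width),
                            seed = seed * 4L + 4L)
  )
}

param_values <- function(x) lapply(collect_params(x), function(p) p$value)

set_param_values <- function(x, values) {
  ps <- collect_params(x)
  if (!setequal(names(ps), names(values))) {
    stop("checkpoint parameters do not match the model structure")
  }
  for (nm in names(ps)) ps[[nm]]$value <- values[[nm]]
  invisible(x)
}

#' Save models (and optional training state) to a checkpoint file
#' @param models From [models_new()].
#' @param path Destination file.
#' @param step Training step counter.
#' @param extra List of additional state (optimizer moments, RNG state, ...).
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(models, path, step = 0L, extra = list()) {
  obj <- list(
    format = "octstain-checkpoint", version = 1L,
    gen_config = models$g_oh$config,
    disc_base_width = models$d_h$config$base_width,
    step = step,
    params = list(
      g_oh = param_values(models$g_oh), g_ho = param_values(models$g_ho),
      d_h = param_values(models$d_h), d_o = param_values(models$d_o)
    ),
    extra = extra
  )
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' Load a checkpoint into freshly built models
#' @param path Checkpoint file from [save_checkpoint()].
#' @return List with `models`, `step` and `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "octstain-checkpoint")) stop("not a checkpoint file")
  if (obj$version > 1L) stop("checkpoint version ", obj$version, " not supported")
  models <- models_new(obj$gen_config, obj$disc_base_width, seed = 1L)
  for (nm in names(obj$params)) set_param_values(models[[nm]], obj$params[[nm]])
  list(models = models, step = obj$step, extra = obj$extra)
}
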