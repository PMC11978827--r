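# YAML run configuration: nested sections mirroring the module configs, with
# strict key validation (unknown keys are rejected with a nearest-match
# suggestion) and all defaults filled from the method's stated
# hyperparameters (conv kernel 32 / stride 16, window 64 / stride 32, two
# layers, six ROIs, learning rate 1e-4, 224x224 images).

default_run_config <- function() {
  list(
    synthetic = list(n_samples = 64, n_vox = 60, n_roi = 6, img_size = 224,
                     d_latent = 4, alignment_strength = 0.8, noise_sd = 0.1,
                     t_steps = 1, ar_coef = 0.5, seed = 1),
    tokenizer = list(kernel = 32, stride = 16),
    timeformer = list(w = 64, s = 32, h = 2, d = 32, n_heads = 4,
                      pad_policy = "pad_last"),
    loss = list(sigma = 0.07, lambda_con = 1, lambda_bfg = 1,
                normalize_features = TRUE, bfg_batch_norm = FALSE),
    train = list(lr = 1e-4, epochs = 30, batch_size = 32, seed = 1,
                 holdout_frac = 0.2, mse_weight = 0.1),
    paths = list(data = NULL, out = NULL)
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      cand <- names(defaults)
      sug <- if (length(cand)) cand[which.min(utils::adist(key, cand))] else NULL
      hint <- if (!is.null(sug)) sprintf("; did you mean '%s'?", sug) else ""
      nf_config_error("unknown config key '%s'%s", full, hint)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        nf_config_error("config key '%s' must be a mapping", full)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[key] <- list(user[[key]]) # preserves explicit NULLs
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending (dotted) key named and the
#' nearest valid key suggested; an empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return validated nested config list of class `nf_run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) nf_io_error("config file '%s' not found", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) nf_config_error("config root must be a mapping")
  cfg <- merge_config(default_run_config(), user)
  structure(cfg, class = "nf_run_config")
}

#' Save a run configuration as YAML
#'
#' @param cfg config list (e.g. from [load_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Build typed module configs out of a validated run config.
config_objects <- function(cfg) {
  list(
    synthetic = do.call(synthetic_config, cfg$synthetic),
    timeformer = do.call(timeformer_config, cfg$timeformer),
    loss = do.call(loss_config, cfg$loss),
    train = do.call(train_config, c(cfg$train, list(loss = do.call(loss_config, cfg$loss))))
  )
}

config_hash <- function(cfg) {
  digest::digest(yaml::as.yaml(unclass(cfg)), algo = "sha256",
                 serialize = FALSE)
}

# ---- model archive ----------------------------------------------------------

#' Save a model (construction recipe + trained head weights)
#'
#' The frozen backbone and Timeformer body are reproduced deterministically
#' from the stored seed; the trainable head tensors are stored at full
#' precision. Checksummed text archive, bit-exact round trip.
#'
#' @param model an [nf_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  body <- list(
    kind = "neurofusion-model-v1",
    n_vox = model$n_vox, n_roi = model$n_roi, d = model$d,
    img_size = model$img_size,
    conv_kernel = model$conv$kernel, conv_stride = model$conv$stride,
    tf = list(w = model$tf_cfg$w, s = model$tf_cfg$s, h = model$tf_cfg$h,
              d = model$tf_cfg$d, n_heads = model$tf_cfg$n_heads,
              pad_policy = model$tf_cfg$pad_policy),
    grid_channels = model$vision$spec$grid_channels,
    seed = model$seed,
    theta = flatten_tensors(get_theta(model))
  )
  json <- as.character(jsonlite::toJSON(body, digits = NA, auto_unbox = TRUE))
  sum <- digest::digest(json, algo = "sha256", serialize = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("neurofusion-model-v1 sha256:", sum), json), con)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path archive path.
#' @return the reconstructed [nf_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) nf_io_error("model archive '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || !startsWith(lines[1], "neurofusion-model-v1 sha256:"))
    nf_io_error("'%s' is not a neurofusion model archive", path)
  json <- paste(lines[-1], collapse = "\n")
  actual <- digest::digest(json, algo = "sha256", serialize = FALSE)
  if (!identical(sub("^neurofusion-model-v1 sha256:", "", lines[1]), actual))
    nf_io_error("model archive checksum failure")
  b <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  tf <- timeformer_config(w = b$tf$w, s = b$tf$s, h = b$tf$h, d = b$tf$d,
                          n_heads = b$tf$n_heads, pad_policy = b$tf$pad_policy)
  model <- nf_model(n_vox = b$n_vox, n_roi = b$n_roi, d = b$d,
                    img_size = b$img_size, conv_kernel = b$conv_kernel,
                    conv_stride = b$conv_stride, tf = tf,
                    backbone = backbone_spec(d = b$d,
                                             grid_channels = b$grid_channels),
                    seed = b$seed)
  theta <- get_theta(model)
  for (nm in names(theta)) {
    t <- b$theta[[nm]]
    v <- as.numeric(t$data)
    theta[[nm]] <- if (length(t$dim) == 2) matrix(v, t$dim[1], t$dim[2]) else v
  }
  set_theta(model, theta)
}
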