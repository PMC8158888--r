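# YAML run configuration with a strict schema: omitted keys get defaults,
# unknown keys are rejected by name.

.config_defaults <- function() {
  list(
    model = list(in_size = c(224L, 224L), n_blocks = 4L, base_channels = 32L,
                 dense_layers = 6L, growth = 32L, n3d_blocks = 2L,
                 attention = "hybrid", norm = "instance"),
    train = list(epochs = 30L, learning_rate = 1e-5, batch_size = 1L,
                 val_fraction = 0.10, min_pancreas_pixels = 100L, seed = 1L,
                 folds = 4L),
    preprocess = list(window_lo = -100, window_hi = 240, out_lo = 0,
                      out_hi = 255, target_size = c(224L, 224L)),
    cascade = list(margin = 20L, vote_threshold = 0.5),
    paths = list(input = NULL, output = NULL, data_dir = NULL,
                 model_dir = NULL)
  )
}

.merge_strict <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key", if (length(unknown) > 1) "s" else "", ": ",
         paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_strict(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "."))
    } else {
      v <- user[[nm]]
      if (is.list(v)) v <- unlist(v)
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML file with sections `model`, `train`, `preprocess`, `cascade`
#' and `paths`; omitted keys take the package defaults (the reference
#' training regime), unknown keys raise an error naming the key, and every
#' section is validated through its constructor.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return An object of class `run_config` with validated members `model`
#'   ([model_config]), `train` ([train_config]), `preprocess`
#'   ([preprocess_spec]), `cascade`, and `paths`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merged <- .merge_strict(.config_defaults(), user)
  structure(list(
    model = do.call(model_config, merged$model),
    train = do.call(train_config,
                    merged$train[setdiff(names(merged$train), "optimizer")]),
    preprocess = do.call(preprocess_spec, merged$preprocess),
    cascade = merged$cascade,
    paths = merged$paths
  ), class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config]: `load_config(dump_config(cfg, f))` reproduces
#' `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(
    model = unclass(cfg$model),
    train = unclass(cfg$train)[setdiff(names(unclass(cfg$train)), "optimizer")],
    preprocess = unclass(cfg$preprocess),
    cascade = cfg$cascade,
    paths = cfg$paths[!vapply(cfg$paths, is.null, logical(1))]
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
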