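# Configuration resolution: built-in defaults < YAML file < overrides, with
# unknown keys rejected so typos fail loudly.

#' Built-in pipeline defaults
#'
#' Every tunable default of the pipeline, grouped by stage. See the methods
#' vignette for the rationale behind each value.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    dataset = "synthetic",
    data = list(
      synthetic = TRUE,
      interactions = NULL, drug_sim = NULL, target_sim = NULL,
      transpose = FALSE,
      n_drugs = 50L, n_targets = 40L, latent_dim = 4L,
      interaction_density = 0.05, similarity_noise = 0.05,
      synthetic_seed = 7L
    ),
    labeling = list(k_percent = 10, threshold = 0.5, negative_ratio = 3),
    gru = list(learning_rate = 0.3, epochs = 120, batch_size = 32,
               hidden_units = 16, time_steps = 8),
    wdo = list(enabled = FALSE, alpha = 0.4, g = 0.2, RT = 3, c = 0.4,
               population = 5L, iterations = 4L, v_max = 0.3),
    evaluation = list(seeds = c(3201L, 2033L, 5179L, 2931L, 9117L), folds = 5L)
  )
}

merge_config <- function(base, upd, path = character()) {
  for (nm in names(upd)) {
    here <- c(path, nm)
    if (!nm %in% names(base)) {
      stop_fmt("unknown configuration key '%s'", paste(here, collapse = "."))
    }
    if (is.list(base[[nm]]) && !is.null(base[[nm]])) {
      if (!is.list(upd[[nm]])) {
        stop_fmt("configuration key '%s' must be a section", paste(here, collapse = "."))
      }
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]], here)
    } else {
      val <- upd[[nm]]
      old <- base[[nm]]
      if (!is.null(old) && !is.null(val)) {
        if (is.numeric(old) && !is.numeric(val)) {
          stop_fmt("configuration key '%s' must be numeric", paste(here, collapse = "."))
        }
        if (is.logical(old) && !is.logical(val)) {
          stop_fmt("configuration key '%s' must be logical", paste(here, collapse = "."))
        }
        if (is.character(old) && !is.character(val)) {
          stop_fmt("configuration key '%s' must be character", paste(here, collapse = "."))
        }
      }
      base[[nm]] <- val
    }
  }
  base
}

#' Resolve the pipeline configuration
#'
#' Precedence: built-in defaults, then the YAML `file`, then `overrides`.
#' Unknown keys at any level are rejected with the offending key named, and
#' values must match the type of the default they replace.
#'
#' @param file optional YAML configuration file path.
#' @param overrides optional nested named list of overrides.
#' @return The resolved configuration list, of class `run_config`.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.list(y)) stop_fmt("%s: configuration file must be a mapping", file)
    cfg <- merge_config(cfg, y)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = c("run_config", "list"))
}
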