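# Configuration: shipped defaults + user overrides.

config_env <- new.env(parent = emptyenv())

#' Load the pipeline configuration
#'
#' Reads the packaged default configuration (structural model constants,
#' grid presets, cohort-generator settings, drug PK defaults) and merges a
#' user-supplied YAML/JSON file or list over it, recursively.
#'
#' @param overrides Optional path to a YAML/JSON file, or a named list.
#' @return Nested configuration list.
#' @export
silk_config <- function(overrides = NULL) {
  if (is.null(config_env$default)) {
    path <- system.file("extdata", "default-config.yaml", package = "silkfit")
    config_env$default <- yaml::read_yaml(path)
  }
  cfg <- config_env$default
  if (is.null(overrides)) return(cfg)
  if (is.character(overrides)) {
    overrides <- if (grepl("\\.json$", overrides, ignore.case = TRUE)) {
      jsonlite::read_json(overrides, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(overrides)
    }
  }
  merge_config(cfg, overrides)
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Default sampling schedule from configuration
#'
#' @param config Configuration list from [silk_config()].
#' @return A [sample_schedule()].
#' @export
default_schedule <- function(config = silk_config()) {
  sc <- config$schedule
  sample_schedule(seq(sc$times_start, sc$times_end, by = sc$times_step),
                  sc$draw_volume_ml)
}

#' Default leucine infusion enrichment curve from configuration
#'
#' @param config Configuration list from [silk_config()].
#' @return An [enrichment_infusion()] curve.
#' @export
default_enrichment <- function(config = silk_config()) {
  inf <- config$infusion
  enrichment_infusion(e_ss = inf$e_ss, k_rise = inf$k_rise,
                      k_decay = inf$k_decay, t_infusion = inf$duration_h)
}
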