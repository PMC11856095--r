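## cli_config: pipeline configuration, YAML loading, precedence, validation.

#' Pipeline configuration
#'
#' Bundles every tunable of the preprocessing chain and the embedded filter
#' and QC configurations. Defaults follow the reference pipeline: 5x5
#' structuring element, 3 closing iterations, 256-bin Otsu, 1-99 percentile
#' contrast stretch, 0.1% small-object cutoff, 5% minimum object area.
#'
#' @param normalize apply min-max normalization first (default TRUE).
#' @param contrast_low,contrast_high contrast-stretch percentiles.
#' @param otsu_bins histogram bins for [otsu_threshold()].
#' @param se_size odd side length of the square structuring element.
#' @param morph_iterations closing passes in [refine_morphology()].
#' @param small_object_frac area cutoff for [remove_small_objects()].
#' @param filter a [filter_config()].
#' @param qc a [qc_config()].
#' @param output_format `"png"` or `"tiff"` for written masks.
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @param seed optional integer seed funneling all randomness of a run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(normalize = TRUE, contrast_low = 1,
                            contrast_high = 99, otsu_bins = 256L,
                            se_size = 5L, morph_iterations = 3L,
                            small_object_frac = 0.001,
                            filter = filter_config(), qc = qc_config(),
                            output_format = "png", log_level = "info",
                            seed = NULL) {
  cfg <- structure(list(normalize = isTRUE(normalize),
                        contrast_low = contrast_low,
                        contrast_high = contrast_high,
                        otsu_bins = as.integer(otsu_bins),
                        se_size = as.integer(se_size),
                        morph_iterations = as.integer(morph_iterations),
                        small_object_frac = small_object_frac,
                        filter = filter, qc = qc,
                        output_format = output_format,
                        log_level = log_level,
                        seed = if (is.null(seed)) NULL else as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  check <- function(ok, what) if (!ok) stop_validation("invalid config: ", what)
  check(cfg$se_size >= 1L && cfg$se_size %% 2L == 1L, "se_size must be odd and >= 1")
  check(cfg$morph_iterations >= 1L, "morph_iterations must be >= 1")
  check(cfg$otsu_bins >= 2L, "otsu_bins must be >= 2")
  check(cfg$contrast_low >= 0 && cfg$contrast_low < cfg$contrast_high &&
          cfg$contrast_high <= 100,
        "contrast percentiles must satisfy 0 <= low < high <= 100")
  check(cfg$small_object_frac >= 0 && cfg$small_object_frac < 1,
        "small_object_frac must be in [0, 1)")
  check(cfg$output_format %in% c("png", "tif", "tiff"),
        "output_format must be png or tiff")
  check(cfg$log_level %in% c("debug", "info", "warn"),
        "log_level must be one of debug, info, warn")
  check(inherits(cfg$filter, "filter_config"), "filter must be a filter_config")
  check(inherits(cfg$qc, "qc_config"), "qc must be a qc_config")
  invisible(cfg)
}

## flatten a config into plain lists for YAML echo / provenance capture
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$filter <- unclass(cfg$filter)
  out$qc <- unclass(cfg$qc)
  out
}

apply_config_keys <- function(base, values, context) {
  known_nested <- c("filter", "qc")
  for (key in names(values)) {
    if (key %in% known_nested) {
      sub <- values[[key]]
      if (!is.list(sub)) stop_validation(context, ": '", key, "' must be a mapping")
      allowed <- names(base[[key]])
      unknown <- setdiff(names(sub), allowed)
      if (length(unknown)) {
        stop_validation(context, ": unknown ", key, " key(s): ",
                        paste(unknown, collapse = ", "))
      }
      for (k in names(sub)) base[[key]][[k]] <- sub[[k]]
    } else if (key %in% setdiff(names(base), known_nested)) {
      base[[key]] <- values[[key]]
    } else {
      stop_validation(context, ": unknown key(s): ", key)
    }
  }
  base
}

#' Load a pipeline configuration with precedence flags > file > defaults
#'
#' Starts from the package defaults, overlays the YAML file (when given),
#' then overlays explicit overrides (e.g. parsed command-line flags).
#' Unknown keys are a validation error naming them; the merged
#' configuration is re-validated.
#'
#' @param path optional path to a YAML file; top-level keys mirror
#'   [pipeline_config()] arguments, with `filter:` and `qc:` as nested
#'   mappings.
#' @param overrides optional named list in the same structure.
#' @return a validated [pipeline_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_to_list(pipeline_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (!is.null(vals)) cfg <- apply_config_keys(cfg, vals, paste0("config file ", path))
  }
  if (length(overrides)) cfg <- apply_config_keys(cfg, overrides, "flags")
  out <- pipeline_config(
    normalize = cfg$normalize, contrast_low = cfg$contrast_low,
    contrast_high = cfg$contrast_high, otsu_bins = cfg$otsu_bins,
    se_size = cfg$se_size, morph_iterations = cfg$morph_iterations,
    small_object_frac = cfg$small_object_frac,
    filter = do.call(filter_config, cfg$filter),
    qc = do.call(qc_config, cfg$qc),
    output_format = cfg$output_format, log_level = cfg$log_level,
    seed = cfg$seed
  )
  lp_log("debug", "effective config: ",
         paste(utils::capture.output(utils::str(config_to_list(out))), collapse = " "))
  out
}
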