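.run_config_schema <- function() list(
  map = c("tau_log10_min", "tau_log10_max", "tau_points_per_decade",
          "s_log10_min", "s_log10_max", "s_points_per_decade",
          "multiplicity", "normalization", "png"),
  simulate = c("rh_percent", "temperature_c", "seed", "snr", "noise_sigma"),
  process = c("lb_hz", "zero_fill_to", "phase", "baseline",
              "reference_observed_ppm"),
  classify = c("frac", "onset_frac", "window_half_width_ppm"),
  settings = names(formals(experiment_settings))
)

#' Read and validate a run configuration file
#'
#' A run configuration is a YAML mapping with optional sections `map`,
#' `simulate`, `process`, `classify` and `settings` (the latter mirroring
#' [experiment_settings()] keys).  Unknown sections or keys are rejected so
#' misspelled options cannot silently take default values.
#'
#' @param path YAML file path; `NULL` gives an empty (all-defaults) config.
#' @return Named list of validated sections, with `settings` already
#'   instantiated as an `experiment_settings` object.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) pt_data_error("Run config must be a YAML mapping.")
  schema <- .run_config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0) {
    pt_usage_error(sprintf("Unknown config section(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad) > 0) {
      pt_usage_error(sprintf("Unknown key(s) in section `%s`: %s",
                             sec, paste(bad, collapse = ", ")))
    }
  }
  cfg$settings <- do.call(experiment_settings, cfg$settings %||% list())
  cfg
}

#' Hash of a configuration file for run logging
#'
#' @param path File path (or `NULL`).
#' @return MD5 string, or `"none"` when no file was given.
#' @export
config_hash <- function(path = NULL) {
  if (is.null(path)) return("none")
  unname(tools::md5sum(path))
}
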