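#' Analysis configuration
#'
#' Bundles every tunable of the curve analysis and grading so that batch
#' runs are reproducible from a single object. All defaults are the
#' conventions documented in the methods vignette.
#'
#' @param smooth Smooth filling rates with a 3-point cyclic moving average
#'   before peak detection (default `FALSE`).
#' @param refine_peaks Refine peak values/times off-grid with a 3-point
#'   parabola through the sampled extremum (default `TRUE`). On 30-frame
#'   grids the raw sample can miss a lobe peak by several percent.
#' @param refine_es Refine the end-systolic time by linear interpolation of
#'   the filling-rate zero crossing near the minimum-volume frame
#'   (default `TRUE`). With `FALSE` the sampled frame time is used.
#' @param dt_method Deceleration-time fit on the E-wave downslope:
#'   `"least_squares"` over all downslope samples, or `"chord"` through its
#'   first and last sample.
#' @param eprime_window_frac Early-diastolic window for E': from end-systole
#'   to `es + eprime_window_frac * (rr - es)`, shortened to the detected
#'   A-lobe onset when one exists. Default 0.6.
#' @param ee_mean_mode How the mean CMR E/E' is formed: `"mean_of_ratios"`
#'   (mean of septal and lateral E/E', the default) or `"ratio_of_means"`
#'   (E divided by mean E').
#' @param echo_ratio_mode How the grading criterion E/e' is formed from echo
#'   measures: `"ratio_of_means"` (E over the mean of septal and lateral e',
#'   the default reading of "average E and average e'") or
#'   `"mean_of_ratios"`.
#' @param thresholds Grading thresholds: septal e' (cm/s), lateral e' (cm/s),
#'   mean E/e', and the sex-specific LV-mass-index hypertrophy cutoffs
#'   (g/m^2).
#' @param fisher_enum_limit Largest table total for which the exact r x c
#'   test enumerates; larger tables fall back to seeded Monte Carlo.
#' @param mc_draws Monte-Carlo replicates for the fallback.
#' @param seed Seed for any stochastic step (Monte-Carlo Fisher).
#' @return A list of class `lvd_config`.
#' @export
analysis_config <- function(smooth = FALSE,
                            refine_peaks = TRUE,
                            refine_es = TRUE,
                            dt_method = c("least_squares", "chord"),
                            eprime_window_frac = 0.6,
                            ee_mean_mode = c("mean_of_ratios", "ratio_of_means"),
                            echo_ratio_mode = c("ratio_of_means", "mean_of_ratios"),
                            thresholds = list(
                              eprime_septal_cm_s = 8,
                              eprime_lateral_cm_s = 10,
                              ee_mean = 10,
                              lvmi_male_g_m2 = 115,
                              lvmi_female_g_m2 = 95
                            ),
                            fisher_enum_limit = 200,
                            mc_draws = 1e5,
                            seed = NULL) {
  dt_method <- match.arg(dt_method)
  ee_mean_mode <- match.arg(ee_mean_mode)
  echo_ratio_mode <- match.arg(echo_ratio_mode)
  if (eprime_window_frac <= 0 || eprime_window_frac > 1) {
    abort("`eprime_window_frac` must be in (0, 1].", class = "lvd_error_argument")
  }
  if (any(unlist(thresholds) <= 0)) {
    abort("All grading thresholds must be positive.", class = "lvd_error_argument")
  }
  structure(
    list(
      smooth = isTRUE(smooth),
      refine_peaks = isTRUE(refine_peaks),
      refine_es = isTRUE(refine_es),
      dt_method = dt_method,
      eprime_window_frac = eprime_window_frac,
      ee_mean_mode = ee_mean_mode,
      echo_ratio_mode = echo_ratio_mode,
      thresholds = thresholds,
      fisher_enum_limit = fisher_enum_limit,
      mc_draws = mc_draws,
      seed = seed
    ),
    class = "lvd_config"
  )
}

#' Read / write an analysis configuration
#'
#' Configurations serialise to YAML (or JSON, by extension) so that command
#' line runs can pin their settings.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config An [analysis_config()].
#' @return `read_config()` returns an [analysis_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Package `yaml` is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  }
  vals$thresholds <- as.list(vals$thresholds)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lvd_config"))
  vals <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, null = "null")
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Package `yaml` is required to write YAML configs.")
    }
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
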