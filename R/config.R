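#' Pipeline configuration
#'
#' Collects the tunable parameters shared across preprocessing, feature
#' extraction and model selection. Defaults follow the study design:
#' 15 s sliding windows with a 7.5 s step (50% overlap), a 3 Hz low-pass and
#' a 0.016-0.5 Hz band-pass on optical density, a held-out test set of 5
#' participants, randomized hyperparameter search over 50 iterations scored
#' by 5-fold cross-validation, and a feature-fraction grid of 1..100%.
#'
#' @param window_s Sliding-window duration in seconds.
#' @param step_s Window step in seconds; must satisfy `0 < step_s <= window_s`.
#' @param lowpass_hz Low-pass cutoff (Hz) applied to optical density.
#' @param bandpass_low_hz,bandpass_high_hz Band-pass edges (Hz);
#'   `bandpass_low_hz < bandpass_high_hz < lowpass_hz`.
#' @param n_test_participants Number of participants held out for testing.
#' @param n_search_iters Randomized-search iterations per model family.
#' @param n_cv_folds Cross-validation folds (grouped by participant).
#' @param feature_fraction_grid Integer percentages of top-ranked features to
#'   sweep (1..100).
#' @param corr_dropout_threshold Absolute Pearson correlation above which the
#'   later feature of a pair is dropped before ANOVA ranking.
#' @param seed Optional default seed used when a function is not given one.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_s = 15,
                            step_s = 7.5,
                            lowpass_hz = 3,
                            bandpass_low_hz = 0.016,
                            bandpass_high_hz = 0.5,
                            n_test_participants = 5L,
                            n_search_iters = 50L,
                            n_cv_folds = 5L,
                            feature_fraction_grid = 1:100,
                            corr_dropout_threshold = 0.95,
                            seed = NULL) {
  cfg <- list(
    window_s = window_s, step_s = step_s,
    lowpass_hz = lowpass_hz,
    bandpass_low_hz = bandpass_low_hz, bandpass_high_hz = bandpass_high_hz,
    n_test_participants = as.integer(n_test_participants),
    n_search_iters = as.integer(n_search_iters),
    n_cv_folds = as.integer(n_cv_folds),
    feature_fraction_grid = as.integer(feature_fraction_grid),
    corr_dropout_threshold = corr_dropout_threshold,
    seed = seed
  )
  if (!(cfg$step_s > 0 && cfg$step_s <= cfg$window_s)) {
    stop_invalid("config", "require 0 < step_s <= window_s")
  }
  if (!(cfg$bandpass_low_hz > 0 &&
        cfg$bandpass_low_hz < cfg$bandpass_high_hz &&
        cfg$bandpass_high_hz < cfg$lowpass_hz)) {
    stop_invalid("config", "require 0 < bandpass low < high < lowpass_hz")
  }
  if (any(cfg$feature_fraction_grid < 1L | cfg$feature_fraction_grid > 100L)) {
    stop_invalid("config", "feature_fraction_grid entries must lie in 1..100")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds a flat key-value mapping of [pipeline_config()] fields;
#' unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_invalid("config", paste("unknown key(s):", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Modified Beer-Lambert parameters
#'
#' Constants of the modified Beer-Lambert law linking optical-density change
#' at the two wavelengths to hemoglobin concentration changes:
#' `dOD(lambda) = (eps_HbO(lambda) * dHbO + eps_HbR(lambda) * dHbR) * d * DPF(lambda)`.
#' Defaults use 760/850 nm with Prahl's compiled extinction spectra
#' (converted to 1/(mM cm)), a differential pathlength factor of 6.0 at both
#' wavelengths, and a 3 cm source-detector separation — the conventional
#' continuous-wave adult-head values.
#'
#' @param wavelengths Two wavelengths in nm.
#' @param extinction 2x2 matrix; rows = wavelengths, columns = c(HbO, HbR),
#'   units 1/(mM cm). Must be invertible.
#' @param dpf Differential pathlength factor per wavelength (unitless, > 0).
#' @param distance Source-detector separation in cm (> 0).
#' @return A `beer_lambert_params` list.
#' @export
beer_lambert_params <- function(wavelengths = c(760, 850),
                                extinction = matrix(
                                  c(1.4866, 3.8437,
                                    2.5264, 1.7986),
                                  nrow = 2, byrow = TRUE,
                                  dimnames = list(NULL, c("HbO", "HbR"))),
                                dpf = c(6.0, 6.0),
                                distance = 3.0) {
  if (length(wavelengths) != 2L) stop_invalid("beer_lambert", "exactly 2 wavelengths required")
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2L, 2L))) {
    stop_invalid("beer_lambert", "extinction must be a 2x2 matrix")
  }
  if (!is.finite(rcond(extinction)) || rcond(extinction) < .Machine$double.eps) {
    stop_invalid("beer_lambert", "extinction matrix is singular")
  }
  if (length(dpf) == 1L) dpf <- rep(dpf, 2L)
  if (any(dpf <= 0)) stop_invalid("beer_lambert", "dpf must be > 0")
  if (distance <= 0) stop_invalid("beer_lambert", "distance must be > 0")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 dpf = dpf, distance = distance),
            class = "beer_lambert_params")
}
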