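#' @include AllClasses.R
NULL

.defaultConfig <- function() {
  list(
    calibration = list(lateral = 18, axial = 18),
    preprocess = list(scale = 0),
    canny = list(sigma = 2, low_q = 0.80, high_q = 0.95),
    sampling = list(step = 10, select = "deepest"),
    corner = list(k = 5, z_thresh = 2, min_angle = 25, refine = TRUE),
    interface = list(min_depth = 8, smooth_tol = 4, max_gap_frac = 0.5, sigma = 2),
    spline = list(spar = NULL),
    volume = list(consistent_units = FALSE)
  )
}

#' Run configuration for the segmentation pipeline
#'
#' Central, validated parameter set: calibration, Canny parameters
#' (\code{canny$sigma} in px; hysteresis thresholds \code{low_q},
#' \code{high_q} as gradient-magnitude quantiles, which survive affine
#' exposure differences across scans), boundary sampling step (default 10
#' px, chosen to suppress interference noise on the extracted boundary),
#' curvature corner-detector window and significance threshold, anterior
#' interface search parameters and spline smoothing. Unknown keys are
#' rejected.
#'
#' @param ... named overrides, e.g. \code{canny = list(sigma = 3)},
#'   \code{sampling = list(step = 5)}. Sub-lists are merged key-wise.
#' @return a named list of class \code{octgraft_config}.
#' @examples
#' cfg <- octConfig(sampling = list(step = 5))
#' cfg$canny$sigma
#' @export
octConfig <- function(...) {
  cfg <- .defaultConfig()
  over <- list(...)
  if (length(over) && is.null(names(over)))
    .octError("configuration overrides must be named", "octgraft_parameter_error")
  for (grp in names(over)) {
    if (!grp %in% names(cfg))
      .octError(sprintf("unknown configuration group '%s'", grp), "octgraft_parameter_error")
    v <- over[[grp]]
    if (!is.list(v)) .octError(sprintf("configuration group '%s' must be a list", grp),
                               "octgraft_parameter_error")
    for (key in names(v)) {
      if (!key %in% names(cfg[[grp]]) && !(grp == "spline" && key == "spar"))
        .octError(sprintf("unknown configuration key '%s$%s'", grp, key),
                  "octgraft_parameter_error")
      cfg[[grp]][key] <- v[key]
    }
  }
  .validateConfig(cfg)
  structure(cfg, class = "octgraft_config")
}

.validateConfig <- function(cfg) {
  with(cfg, {
    if (canny$low_q < 0 || canny$high_q > 1 || canny$low_q > canny$high_q)
      .octError("canny quantile thresholds must satisfy 0 <= low_q <= high_q <= 1",
                "octgraft_parameter_error")
    if (canny$sigma <= 0) .octError("canny sigma must be > 0", "octgraft_parameter_error")
    if (sampling$step < 1) .octError("sampling step must be >= 1", "octgraft_parameter_error")
    if (!sampling$select %in% c("strongest", "deepest", "shallowest"))
      .octError("sampling select must be one of strongest, deepest, shallowest",
                "octgraft_parameter_error")
    if (preprocess$scale < 0) .octError("smoothing scale must be >= 0", "octgraft_parameter_error")
    if (corner$k < 2) .octError("corner support half-window must be >= 2 samples",
                                "octgraft_parameter_error")
    if (interface$max_gap_frac <= 0 || interface$max_gap_frac > 1)
      .octError("interface max_gap_frac must lie in (0, 1]", "octgraft_parameter_error")
    if (calibration$lateral <= 0 || calibration$axial <= 0)
      .octError("calibration factors must be positive", "octgraft_parameter_error")
  })
  invisible(cfg)
}

#' Read a run configuration from a JSON file
#'
#' The file holds the same nested structure as \code{\link{octConfig}};
#' unknown keys are rejected.
#'
#' @param path path to a JSON configuration file.
#' @return a validated \code{octgraft_config}.
#' @export
readConfig <- function(path) {
  if (!file.exists(path))
    .octError(sprintf("configuration file not found: %s", path), "octgraft_io_error")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    .octError(sprintf("malformed configuration JSON: %s", conditionMessage(e)),
                              "octgraft_parse_error"))
  raw <- lapply(raw, as.list)
  do.call(octConfig, raw)
}

.configCalibration <- function(cfg) {
  calibrationSpec(cfg$calibration$lateral, cfg$calibration$axial)
}

.logStage <- function(verbose, stage, t0) {
  if (isTRUE(verbose))
    message(sprintf("[octgraft] %-22s %.3fs", stage,
                    as.numeric(proc.time()["elapsed"]) - t0))
  as.numeric(proc.time()["elapsed"])
}
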