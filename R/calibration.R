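#' @include AllClasses.R
NULL

#' Construct a Calibration
#'
#' @param lateral microns per pixel laterally (columns). Defaults to 18,
#'   the axial resolution class of the time-domain anterior-segment OCT
#'   the package targets; real scans must supply their own pitch.
#' @param axial microns per pixel axially (rows).
#' @return a \code{\linkS4class{Calibration}}.
#' @examples
#' calibrationSpec(10, 10)
#' @export
calibrationSpec <- function(lateral = 18, axial = 18) {
  if (!is.numeric(lateral) || !is.numeric(axial))
    .octError("calibration factors must be numeric", "octgraft_parameter_error")
  new("Calibration", lateral = as.numeric(lateral), axial = as.numeric(axial))
}

#' Construct an OCTImage from a pixel matrix
#'
#' @param pixels numeric matrix of intensities in [0, 1]; rows are axial
#'   depth, columns lateral position.
#' @param calibration a \code{\linkS4class{Calibration}}; required --
#'   metric outputs fail loudly without one.
#' @param imageId identifier string.
#' @param meta optional named list of acquisition metadata.
#' @return an \code{\linkS4class{OCTImage}}.
#' @export
octImage <- function(pixels, calibration, imageId = "image", meta = list()) {
  if (missing(calibration) || !is(calibration, "Calibration"))
    .octError("an OCTImage requires an explicit Calibration", "octgraft_parameter_error")
  new("OCTImage", pixels = pixels, calibration = calibration,
      imageId = as.character(imageId), meta = meta)
}

#' Construct a CornerSet
#'
#' @param leftAnterior,leftPosterior,rightAnterior,rightPosterior numeric
#'   (col, row) pairs.
#' @return a \code{\linkS4class{CornerSet}}.
#' @export
cornerSet <- function(leftAnterior, leftPosterior, rightAnterior, rightPosterior) {
  p <- rbind(leftAnterior, leftPosterior, rightAnterior, rightPosterior)
  dimnames(p) <- list(.CORNER_LABELS, c("col", "row"))
  new("CornerSet", points = p)
}

#' Construct a paired MeasurementSeries
#'
#' @param a,b paired numeric measurement vectors (um^2), length >= 3.
#' @param labels length-2 character vector naming the arms.
#' @return a \code{\linkS4class{MeasurementSeries}}.
#' @export
measurementSeries <- function(a, b, labels = c("A", "B")) {
  if (length(a) != length(b) || length(a) < 3)
    .octError("agreement analysis needs at least 3 complete pairs",
              "octgraft_sample_size_error")
  new("MeasurementSeries", a = as.numeric(a), b = as.numeric(b),
      labels = as.character(labels))
}
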