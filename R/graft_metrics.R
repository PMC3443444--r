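#' @include AllClasses.R graft_segmentation.R
NULL

.segPolygon <- function(seg, perPx = 1) {
  dom <- range(seg@anterior@controlPoints[, 1])
  n <- max(2, ceiling(diff(dom) * perPx) + 1)
  xs <- seq(dom[1], dom[2], length.out = n)
  antY <- .evalCurve(seg@anterior, xs)
  postY <- .evalCurve(seg@posterior, xs)
  if (min(postY - antY) < -1e-6)
    .octError("self-intersecting graft polygon (negative thickness)",
              "octgraft_geometry_error")
  list(x = c(xs, rev(xs)), y = c(antY, rev(postY)))
}

#' Graft cross-sectional area in square microns
#'
#' The closed graft polygon -- anterior curve left to right, posterior
#' curve right to left, densely sampled at >= 1 point per pixel -- is
#' measured by the shoelace formula in px^2 and scaled by the lateral and
#' axial calibration to um^2. Orientation is normalised (absolute value)
#' so traversal direction never flips the sign.
#'
#' @param seg a \code{\linkS4class{GraftSegmentation}}.
#' @param cal a \code{\linkS4class{Calibration}}; required.
#' @return an \code{\linkS4class{AreaMeasurement}}.
#' @export
computeArea <- function(seg, cal) {
  stopifnot(is(seg, "GraftSegmentation"))
  if (missing(cal) || !is(cal, "Calibration"))
    .octError("computeArea requires an explicit Calibration", "octgraft_parameter_error")
  poly <- .segPolygon(seg)
  areaPx2 <- abs(pracma::polyarea(poly$x, poly$y))
  new("AreaMeasurement", areaUm2 = areaPx2 * cal@lateral * cal@axial,
      mode = seg@mode, imageId = seg@imageId)
}

#' Graft thickness profile
#'
#' Thickness (posterior row minus anterior row, scaled by the axial
#' calibration) at evenly spaced lateral positions measured in microns
#' from the left corner. The trapezoidal integral of the profile over the
#' lateral extent reproduces \code{\link{computeArea}} to within about a
#' percent (they discretise the same region differently).
#'
#' @param seg a \code{\linkS4class{GraftSegmentation}}.
#' @param cal a \code{\linkS4class{Calibration}}.
#' @param nSamples number of profile samples, >= 2.
#' @return a data.frame with columns \code{lateral_um} (strictly
#'   increasing) and \code{thickness_um} (non-negative).
#' @export
thicknessProfile <- function(seg, cal, nSamples = 101) {
  stopifnot(is(seg, "GraftSegmentation"))
  if (missing(cal) || !is(cal, "Calibration"))
    .octError("thicknessProfile requires an explicit Calibration", "octgraft_parameter_error")
  if (nSamples < 2)
    .octError("nSamples must be >= 2", "octgraft_parameter_error")
  dom <- range(seg@anterior@controlPoints[, 1])
  xs <- seq(dom[1], dom[2], length.out = nSamples)
  th <- (.evalCurve(seg@posterior, xs) - .evalCurve(seg@anterior, xs)) * cal@axial
  th[th < 0 & th > -1e-9] <- 0
  data.frame(lateral_um = (xs - dom[1]) * cal@lateral, thickness_um = th)
}

#' Trephine-based graft volume estimate
#'
#' Multiplies the cross-sectional area by the trephine diameter that cut
#' the donor graft. By convention the printed figure is
#' \code{area_um2 x diameter_mm} with the factors in those mixed units
#' (e.g. area 20,000 um^2 with an 8.5 mm trephine gives 170,000); set
#' \code{consistentUnits = TRUE} to convert the diameter to microns first
#' and obtain a dimensionally consistent um^3 value.
#'
#' @param area an \code{\linkS4class{AreaMeasurement}} or a bare um^2 value.
#' @param trephineDiameterMm trephine diameter in mm, > 0.
#' @param consistentUnits logical, see above.
#' @return a list with elements \code{value}, \code{trephine_diameter_mm},
#'   \code{convention} ("as-printed" or "um3").
#' @export
estimateVolume <- function(area, trephineDiameterMm, consistentUnits = FALSE) {
  a <- if (is(area, "AreaMeasurement")) area@areaUm2 else as.numeric(area)
  if (!is.finite(a) || a < 0)
    .octError("area must be a finite non-negative value", "octgraft_parameter_error")
  if (!is.finite(trephineDiameterMm) || trephineDiameterMm <= 0)
    .octError("trephine diameter must be > 0", "octgraft_parameter_error")
  d <- if (consistentUnits) trephineDiameterMm * 1000 else trephineDiameterMm
  list(value = a * d, trephine_diameter_mm = trephineDiameterMm,
       convention = if (consistentUnits) "um3" else "as-printed")
}
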