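#' @include AllClasses.R
NULL

#' Accessors for octgraft objects
#'
#' Small accessor generics so that slots are never reached into directly:
#' \code{calibration} and \code{pixels} for images, \code{corners} and
#' \code{segMode} for segmentations, \code{boundaryPoints} for sampled
#' boundaries and curves, \code{areaUm2} for area measurements,
#' \code{truthAreaUm2} for phantom truths, \code{imageId} for anything that
#' carries one.
#'
#' @param x an octgraft object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("corners", function(x) standardGeneric("corners"))
#' @rdname accessors
#' @export
setGeneric("cornerPoints", function(x) standardGeneric("cornerPoints"))
#' @rdname accessors
#' @export
setGeneric("segMode", function(x) standardGeneric("segMode"))
#' @rdname accessors
#' @export
setGeneric("boundaryPoints", function(x) standardGeneric("boundaryPoints"))
#' @rdname accessors
#' @export
setGeneric("areaUm2", function(x) standardGeneric("areaUm2"))
#' @rdname accessors
#' @export
setGeneric("truthAreaUm2", function(x) standardGeneric("truthAreaUm2"))
#' @rdname accessors
#' @export
setGeneric("edgePixels", function(x) standardGeneric("edgePixels"))

setMethod("calibration", "OCTImage", function(x) x@calibration)
setMethod("calibration", "PhantomSpec", function(x) x@calibration)
setMethod("pixels", "OCTImage", function(x) x@pixels)
setMethod("imageId", "OCTImage", function(x) x@imageId)
setMethod("imageId", "GraftSegmentation", function(x) x@imageId)
setMethod("imageId", "AreaMeasurement", function(x) x@imageId)
setMethod("corners", "GraftSegmentation", function(x) x@corners)
setMethod("corners", "PhantomTruth", function(x) x@corners)
setMethod("cornerPoints", "CornerSet", function(x) x@points)
setMethod("segMode", "GraftSegmentation", function(x) x@mode)
setMethod("segMode", "AreaMeasurement", function(x) x@mode)
setMethod("boundaryPoints", "SampledBoundary", function(x) x@points)
setMethod("boundaryPoints", "GraftCurve", function(x) x@controlPoints)
setMethod("areaUm2", "AreaMeasurement", function(x) x@areaUm2)
setMethod("truthAreaUm2", "PhantomTruth", function(x) x@areaUm2)
setMethod("edgePixels", "EdgeMap", function(x) x@edges)

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.4g um/px lateral, %.4g um/px axial\n",
              object@lateral, object@axial))
})

setMethod("show", "OCTImage", function(object) {
  cat(sprintf("OCTImage '%s': %d x %d px, intensities [%.3f, %.3f]\n",
              object@imageId, nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
  show(object@calibration)
})

setMethod("show", "EdgeMap", function(object) {
  cat(sprintf("EdgeMap for '%s': %d x %d px, %d edge pixels\n",
              object@imageId, nrow(object@edges), ncol(object@edges),
              sum(object@edges)))
})

setMethod("show", "SampledBoundary", function(object) {
  p <- object@points
  cat(sprintf("SampledBoundary: %d sampled columns (step %g px), %d gaps, cols %g..%g\n",
              nrow(p), object@step, sum(is.na(p[, 2])),
              min(p[, 1]), max(p[, 1])))
})

setMethod("show", "CornerSet", function(object) {
  cat("CornerSet (col, row):\n")
  print(round(object@points, 2))
})

setMethod("show", "GraftSegmentation", function(object) {
  d <- range(object@anterior@controlPoints[, 1])
  cat(sprintf("GraftSegmentation [%s] of '%s': lateral span %.1f..%.1f px, %d + %d control points\n",
              object@mode, object@imageId, d[1], d[2],
              nrow(object@anterior@controlPoints), nrow(object@posterior@controlPoints)))
})

setMethod("show", "AreaMeasurement", function(object) {
  cat(sprintf("AreaMeasurement [%s] '%s': %.1f um^2\n",
              object@mode, object@imageId, object@areaUm2))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %g x %g px, graft cols %g..%g, central thickness %g px, contrast %g, speckle %g, seed %g\n",
              object@imageWidth, object@imageHeight,
              object@graftLeftCorner[1], object@graftRightCorner[1],
              object@graftCentralThickness, object@interfaceContrast,
              object@speckleSigma, object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: true area %.1f um^2, corners at cols %g and %g\n",
              object@areaUm2, object@corners@points[1, 1], object@corners@points[3, 1]))
})

setMethod("show", "MeasurementSeries", function(object) {
  cat(sprintf("MeasurementSeries '%s' vs '%s': n = %d pairs\n",
              object@labels[1], object@labels[2], length(object@a)))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport '%s' - '%s' (n = %d)\n",
              object@labels[1], object@labels[2], object@n))
  cat(sprintf("  bias %.2f (95%% CI %.2f to %.2f), SD of differences %.2f\n",
              object@bias, object@biasCi[1], object@biasCi[2], object@sdDiff))
  cat(sprintf("  LoA %.2f to %.2f\n", object@loaLower, object@loaUpper))
  if (!is.na(object@icc))
    cat(sprintf("  ICC %.3f (95%% CI %.3f to %.3f)\n", object@icc,
                object@iccCi[1], object@iccCi[2]))
  if (!is.na(object@r)) cat(sprintf("  r %.3f\n", object@r))
  if (!is.na(object@tStat))
    cat(sprintf("  paired t %.3f, p %.4g\n", object@tStat, object@pValue))
})
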