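#' @import methods
NULL

.octError <- function(msg, class) {
  stop(structure(class = c(class, "octgraft_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Pixel-to-micron calibration of a B-scan
#'
#' Holds the lateral (column) and axial (row) pixel pitch in microns per
#' pixel. Every metric output of the package (areas, thicknesses, volumes)
#' goes through a \code{Calibration}; it is never implicit.
#'
#' @slot lateral microns per pixel along the lateral (column) direction.
#' @slot axial microns per pixel along the axial (row/depth) direction.
#' @export
setClass("Calibration",
         representation(lateral = "numeric", axial = "numeric"),
         validity = function(object) {
           ok <- length(object@lateral) == 1 && length(object@axial) == 1 &&
             is.finite(object@lateral) && is.finite(object@axial) &&
             object@lateral > 0 && object@axial > 0
           if (!ok) return("calibration factors must be single, finite, strictly positive numbers")
           TRUE
         })

#' Calibrated 2-D OCT B-scan
#'
#' The pipeline's input container: a matrix of intensities normalised to
#' [0, 1]. Row index increases with axial depth (the anterior corneal
#' surface sits at small row indices); column index increases left to right
#' laterally.
#'
#' @slot pixels numeric matrix of intensities in [0, 1], at least 32 x 32.
#' @slot calibration a \code{\linkS4class{Calibration}}.
#' @slot imageId free-text identifier.
#' @slot meta named list of acquisition metadata (scan time, device, ...).
#' @export
setClass("OCTImage",
         representation(pixels = "matrix", calibration = "Calibration",
                        imageId = "character", meta = "list"),
         validity = function(object) {
           p <- object@pixels
           if (!is.numeric(p)) return("pixels must be numeric")
           if (nrow(p) < 32 || ncol(p) < 32) return("image must be at least 32 x 32 pixels")
           if (anyNA(p) || min(p) < 0 || max(p) > 1)
             return("intensities must lie in [0, 1] with no missing values")
           TRUE
         })

#' Binary edge map produced by the Canny detector
#'
#' Same shape as the source image; \code{edges} holds 0/1, \code{gradient}
#' the gradient magnitude of the smoothed image (kept so that downstream
#' boundary sampling can break ties by edge strength and refine rows to
#' sub-pixel precision).
#'
#' @slot edges 0/1 matrix.
#' @slot gradient gradient-magnitude matrix, same shape.
#' @slot imageId identifier of the source image.
#' @export
setClass("EdgeMap",
         representation(edges = "matrix", gradient = "matrix", imageId = "character"),
         validity = function(object) {
           if (!all(object@edges %in% c(0, 1))) return("edge map values must be 0 or 1")
           if (!identical(dim(object@edges), dim(object@gradient)))
             return("edges and gradient must have the same shape")
           TRUE
         })

#' Boundary polyline sampled at fixed column steps
#'
#' Ordered (col, row) points with strictly increasing columns, one per
#' sampled column; rows may be fractional (sub-pixel refinement) and NA
#' where the sampled column held no edge pixel (an explicit gap -- gaps are
#' recorded, never fabricated).
#'
#' @slot points two-column matrix (col, row).
#' @slot step sampling step in pixels.
#' @export
setClass("SampledBoundary",
         representation(points = "matrix", step = "numeric"),
         validity = function(object) {
           p <- object@points
           if (ncol(p) != 2) return("points must be a two-column (col, row) matrix")
           if (nrow(p) > 1 && any(diff(p[, 1]) <= 0))
             return("columns must be strictly increasing")
           if (anyNA(p[, 1])) return("sampled columns may not be NA")
           TRUE
         })

.CORNER_LABELS <- c("left_anterior", "left_posterior", "right_anterior", "right_posterior")

#' The four graft corner points
#'
#' (col, row) positions of the points where the graft band's anterior and
#' posterior boundaries terminate at its two lateral ends. Row order within
#' each side encodes anatomy: the anterior corner is never below the
#' posterior one.
#'
#' @slot points 4 x 2 matrix (col, row), rows named \code{left_anterior},
#'   \code{left_posterior}, \code{right_anterior}, \code{right_posterior}.
#' @export
setClass("CornerSet",
         representation(points = "matrix"),
         validity = function(object) {
           p <- object@points
           if (!identical(dim(p), c(4L, 2L))) return("corner set must be a 4 x 2 matrix")
           if (!identical(rownames(p), .CORNER_LABELS))
             return("corner rows must be named left_anterior, left_posterior, right_anterior, right_posterior")
           if (anyNA(p)) return("corner coordinates may not be NA")
           if (!(max(p[c(1, 2), 1]) < min(p[c(3, 4), 1])))
             return("left corner columns must be smaller than right corner columns")
           if (p["left_anterior", 2] > p["left_posterior", 2] ||
               p["right_anterior", 2] > p["right_posterior", 2])
             return("anterior corner row must not exceed posterior corner row on either side")
           TRUE
         })

#' A single graft boundary curve
#'
#' Control points plus a natural-cubic-spline interpolant over lateral
#' position; single-valued in column by construction. Endpoints are the two
#' corresponding corner points.
#'
#' @slot controlPoints ordered two-column (col, row) matrix, >= 2 points.
#' @export
setClass("GraftCurve",
         representation(controlPoints = "matrix"),
         validity = function(object) {
           p <- object@controlPoints
           if (ncol(p) != 2) return("control points must be a two-column matrix")
           if (nrow(p) < 2) return("a curve needs at least 2 control points")
           if (anyNA(p)) return("control points may not be NA")
           if (any(diff(p[, 1]) <= 0)) return("control-point columns must be strictly increasing")
           TRUE
         })

#' Closed graft segmentation
#'
#' The package's central object: the host-graft interface (anterior curve)
#' and the endothelial boundary (posterior curve) anchored at the four
#' corners, forming a simple closed region of non-negative thickness.
#'
#' @slot anterior,posterior \code{\linkS4class{GraftCurve}}s sharing the
#'   same lateral domain.
#' @slot corners a \code{\linkS4class{CornerSet}}.
#' @slot mode "automated" or "semi_automated".
#' @slot imageId identifier of the segmented image.
#' @export
setClass("GraftSegmentation",
         representation(anterior = "GraftCurve", posterior = "GraftCurve",
                        corners = "CornerSet", mode = "character",
                        imageId = "character"),
         validity = function(object) {
           if (!object@mode %in% c("automated", "semi_automated"))
             return("mode must be 'automated' or 'semi_automated'")
           a <- object@anterior@controlPoints
           p <- object@posterior@controlPoints
           da <- range(a[, 1]); dp <- range(p[, 1])
           if (max(abs(da - dp)) > 1e-6)
             return("anterior and posterior curves must share the same lateral domain")
           xs <- seq(da[1], da[2], length.out = 257)
           th <- .evalCurve(object@posterior, xs) - .evalCurve(object@anterior, xs)
           if (min(th) < -1e-6)
             return("posterior curve must lie at or below the anterior curve (non-negative thickness)")
           TRUE
         })

#' Graft cross-sectional area in square microns
#'
#' @slot areaUm2 area of the closed segmentation, um^2.
#' @slot mode measurement mode the segmentation carried.
#' @slot imageId source image identifier.
#' @export
setClass("AreaMeasurement",
         representation(areaUm2 = "numeric", mode = "character", imageId = "character"),
         validity = function(object) {
           if (length(object@areaUm2) != 1 || is.na(object@areaUm2) || object@areaUm2 < 0)
             return("area must be a single non-negative number")
           TRUE
         })

#' Specification of a synthetic graft phantom
#'
#' Geometry (in pixels), calibration, contrast and noise parameters of a
#' synthetic high-resolution cornea B-scan with a lens-shaped graft of
#' analytically known area appended to the posterior corneal surface.
#'
#' @slot imageHeight,imageWidth image size in pixels.
#' @slot calibration a \code{\linkS4class{Calibration}}.
#' @slot corneaAnteriorSagitta sagitta (px) of the anterior corneal arc over
#'   the full image width.
#' @slot corneaThickness corneal band thickness, px.
#' @slot graftLeftCorner,graftRightCorner (col, row) of the graft's anterior
#'   corner points.
#' @slot graftCentralThickness graft thickness (px) midway between corners.
#' @slot graftEdgeThickness graft thickness (px) at the two lateral ends.
#' @slot graftAnteriorSagitta sagitta (px) of the host-graft interface arc
#'   over the corner chord; positive bulges anteriorly (towards smaller rows).
#' @slot interfaceContrast intensity step at the host-graft interface as a
#'   fraction of the corneal band intensity, in [0, 1].
#' @slot speckleSigma scale of the multiplicative log-normal speckle, >= 0.
#' @slot backgroundLevel background intensity in [0, 1].
#' @slot seed integer RNG seed for the speckle.
#' @export
setClass("PhantomSpec",
         representation(imageHeight = "numeric", imageWidth = "numeric",
                        calibration = "Calibration",
                        corneaAnteriorSagitta = "numeric", corneaThickness = "numeric",
                        graftLeftCorner = "numeric", graftRightCorner = "numeric",
                        graftCentralThickness = "numeric", graftEdgeThickness = "numeric",
                        graftAnteriorSagitta = "numeric",
                        interfaceContrast = "numeric", speckleSigma = "numeric",
                        backgroundLevel = "numeric", seed = "numeric"),
         validity = function(object) {
           inIm <- function(p) p[1] >= 1 && p[1] <= object@imageWidth &&
             p[2] >= 1 && p[2] <= object@imageHeight
           if (!inIm(object@graftLeftCorner) || !inIm(object@graftRightCorner))
             return("graft corners must lie inside the image")
           if (object@graftLeftCorner[1] >= object@graftRightCorner[1])
             return("left corner must be left of right corner")
           if (object@graftCentralThickness < 1) return("graft central thickness must be >= 1 px")
           if (object@graftEdgeThickness < 0) return("graft edge thickness must be >= 0 px")
           if (object@interfaceContrast < 0 || object@interfaceContrast > 1)
             return("interface contrast must lie in [0, 1]")
           if (object@speckleSigma < 0) return("speckle sigma must be >= 0")
           if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
             return("background level must lie in [0, 1]")
           TRUE
         })

#' Analytic ground truth paired with a generated phantom
#'
#' @slot spec the generating \code{\linkS4class{PhantomSpec}}.
#' @slot corners exact graft \code{\linkS4class{CornerSet}}.
#' @slot anterior,posterior truth curves densely sampled at 1 px (col, row).
#' @slot areaUm2 closed-form graft area, um^2.
#' @slot thicknessProfile matrix (lateral_um, thickness_um).
#' @export
setClass("PhantomTruth",
         representation(spec = "PhantomSpec", corners = "CornerSet",
                        anterior = "matrix", posterior = "matrix",
                        areaUm2 = "numeric", thicknessProfile = "matrix"))

#' Paired measurement series for agreement analysis
#'
#' Two arms of paired area readings (um^2), e.g. repeated readings by one
#' observer, two observers, or automated vs semi-automated.
#'
#' @slot a,b paired numeric vectors, equal length >= 3, no missing pairs.
#' @slot labels length-2 character, names of the two arms.
#' @export
setClass("MeasurementSeries",
         representation(a = "numeric", b = "numeric", labels = "character"),
         validity = function(object) {
           if (length(object@a) != length(object@b)) return("arms must have equal length")
           if (length(object@a) < 3) return("agreement analysis needs at least 3 pairs")
           if (anyNA(object@a) || anyNA(object@b)) return("missing pairs are not allowed")
           if (length(object@labels) != 2) return("exactly two arm labels required")
           TRUE
         })

#' Observer-agreement report
#'
#' Bland-Altman bias and 95\% limits of agreement with confidence
#' intervals, intraclass correlation, Pearson correlation and the paired
#' t-test for one paired series. Fields not yet computed are NA.
#'
#' @slot n number of pairs.
#' @slot bias mean of differences (first arm minus second), um^2.
#' @slot sdDiff sample SD of the differences (n - 1 denominator).
#' @slot loaLower,loaUpper bias -/+ 1.96 x sdDiff.
#' @slot biasCi,loaLowerCi,loaUpperCi 95\% confidence intervals.
#' @slot icc,iccCi intraclass correlation and its 95\% CI.
#' @slot r Pearson correlation.
#' @slot tStat,pValue paired t statistic and two-sided p.
#' @slot labels arm labels.
#' @export
setClass("AgreementReport",
         representation(n = "numeric", bias = "numeric", sdDiff = "numeric",
                        loaLower = "numeric", loaUpper = "numeric",
                        biasCi = "numeric", loaLowerCi = "numeric", loaUpperCi = "numeric",
                        icc = "numeric", iccCi = "numeric", r = "numeric",
                        tStat = "numeric", pValue = "numeric", labels = "character"),
         validity = function(object) {
           if (!is.na(object@icc) && abs(object@icc) > 1 + 1e-9) return("ICC must lie in [-1, 1]")
           if (!is.na(object@r) && abs(object@r) > 1 + 1e-9) return("r must lie in [-1, 1]")
           if (is.finite(object@bias) && is.finite(object@sdDiff)) {
             if (abs(object@loaLower - (object@bias - 1.96 * object@sdDiff)) > 1e-6 ||
                 abs(object@loaUpper - (object@bias + 1.96 * object@sdDiff)) > 1e-6)
               return("limits of agreement must equal bias -/+ 1.96 x sdDiff")
           }
           TRUE
         })
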