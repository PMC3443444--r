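#' @include AllClasses.R calibration.R
NULL

# --- circular-arc geometry -------------------------------------------------
# Arcs are parameterised by their two endpoints and a signed sagitta measured
# perpendicular to the chord; positive sagitta bulges anteriorly (towards
# smaller row indices), matching the dome shape of a cornea in a B-scan.

.circSegArea <- function(chord, s) {
  s <- abs(s)
  if (s < 1e-12) return(0)
  if (s > chord / 2 + 1e-9)
    .octError("arc sagitta may not exceed half the chord length", "octgraft_geometry_error")
  R <- (chord^2 / 4 + s^2) / (2 * s)
  alpha <- asin(min(1, chord / (2 * R)))
  R^2 * (alpha - sin(alpha) * cos(alpha))
}

.arcRowFun <- function(p1, p2, s) {
  v <- p2 - p1
  chord <- sqrt(sum(v^2))
  if (abs(s) < 1e-12) {
    slope <- v[2] / v[1]
    return(function(cols) p1[2] + slope * (cols - p1[1]))
  }
  nUp <- c(v[2], -v[1]) / chord            # unit normal pointing anteriorly
  R <- (chord^2 / 4 + s^2) / (2 * abs(s))
  M <- (p1 + p2) / 2
  ctr <- M - sign(s) * (R - abs(s)) * nUp
  function(cols) {
    d2 <- R^2 - (cols - ctr[1])^2
    d2[d2 < 0] <- 0
    ctr[2] - sign(s) * sqrt(d2)
  }
}

.corneaAnteriorFun <- function(spec) {
  W <- spec@imageWidth
  apexRow <- round(0.18 * spec@imageHeight)
  edgeRow <- apexRow + spec@corneaAnteriorSagitta
  .arcRowFun(c(1, edgeRow), c(W, edgeRow), spec@corneaAnteriorSagitta)
}

.graftArcFuns <- function(spec) {
  pa1 <- spec@graftLeftCorner
  pa2 <- spec@graftRightCorner
  e <- spec@graftEdgeThickness
  sA <- spec@graftAnteriorSagitta
  sP <- sA - (spec@graftCentralThickness - e)
  list(anterior = .arcRowFun(pa1, pa2, sA),
       posterior = .arcRowFun(pa1 + c(0, e), pa2 + c(0, e), sP),
       sA = sA, sP = sP,
       chord = sqrt(sum((pa2 - pa1)^2)))
}

.truthAreaPx2 <- function(spec) {
  g <- .graftArcFuns(spec)
  w <- spec@graftRightCorner[1] - spec@graftLeftCorner[1]
  segA <- if (abs(g$sA) < 1e-12) 0 else sign(g$sA) * .circSegArea(g$chord, g$sA)
  segP <- if (abs(g$sP) < 1e-12) 0 else sign(g$sP) * .circSegArea(g$chord, g$sP)
  spec@graftEdgeThickness * w + segA - segP
}

# --- public constructors ---------------------------------------------------

#' Specify a synthetic graft phantom
#'
#' Builds a \code{\linkS4class{PhantomSpec}} describing a synthetic
#' high-resolution cornea B-scan: a bright corneal band (intensity 0.8) on a
#' dark background, with a lens-shaped graft -- the region between two
#' circular arcs sharing the corner endpoints -- appended to the posterior
#' corneal surface. The host-graft interface carries an intensity step of
#' \code{interfaceContrast} times the band intensity, and multiplicative
#' log-normal speckle of scale \code{speckleSigma} is applied under
#' \code{seed}. Defaults emulate a time-domain anterior-segment scan at
#' 18 um/px with a graft spanning 300 px (~5.4 mm), 24 px (~430 um) thick
#' centrally and 10 px (~180 um) at the ends.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param corneaAnteriorSagitta sagitta (px) of the anterior corneal arc
#'   over the full width.
#' @param corneaThickness corneal band thickness, px.
#' @param graftLeftCorner,graftRightCorner (col, row) anterior corner
#'   points; \code{NULL} places them on the posterior corneal surface at
#'   columns spanning the central ~60\% of the image.
#' @param graftCentralThickness,graftEdgeThickness graft thickness (px) at
#'   the centre and at the lateral ends; equal values with zero sagitta give
#'   a rectangular band.
#' @param graftAnteriorSagitta sagitta (px) of the interface arc over the
#'   corner chord; \code{NULL} matches the posterior corneal curvature.
#' @param interfaceContrast interface intensity step fraction in [0, 1].
#' @param speckleSigma multiplicative speckle scale, >= 0.
#' @param backgroundLevel background intensity.
#' @param seed integer RNG seed.
#' @return a validated \code{\linkS4class{PhantomSpec}}.
#' @examples
#' spec <- phantomSpec(seed = 7)
#' ph <- generatePhantom(spec)
#' truthAreaUm2(ph$truth)
#' @export
phantomSpec <- function(imageHeight = 384, imageWidth = 512,
                        calibration = calibrationSpec(18, 18),
                        corneaAnteriorSagitta = 80, corneaThickness = 30,
                        graftLeftCorner = NULL, graftRightCorner = NULL,
                        graftCentralThickness = 24, graftEdgeThickness = 10,
                        graftAnteriorSagitta = NULL,
                        interfaceContrast = 0.5, speckleSigma = 0.1,
                        backgroundLevel = 0.05, seed = 1) {
  protoFields <- list(imageHeight = imageHeight, imageWidth = imageWidth,
                      calibration = calibration,
                      corneaAnteriorSagitta = corneaAnteriorSagitta,
                      corneaThickness = corneaThickness)
  antFun <- .corneaAnteriorFun(do.call(new, c(list("PhantomSpec"), protoFields,
    list(graftLeftCorner = c(2, 2), graftRightCorner = c(3, 2),
         graftCentralThickness = 1, graftEdgeThickness = 0, graftAnteriorSagitta = 0,
         interfaceContrast = interfaceContrast, speckleSigma = speckleSigma,
         backgroundLevel = backgroundLevel, seed = seed))))
  if (is.null(graftLeftCorner) || is.null(graftRightCorner)) {
    x1 <- round(0.21 * imageWidth); x2 <- round(0.79 * imageWidth)
    graftLeftCorner <- c(x1, antFun(x1) + corneaThickness)
    graftRightCorner <- c(x2, antFun(x2) + corneaThickness)
  }
  if (is.null(graftAnteriorSagitta)) {
    # match the posterior corneal curvature over the corner chord
    mid <- (graftLeftCorner + graftRightCorner) / 2
    apex <- antFun(mid[1]) + corneaThickness
    graftAnteriorSagitta <- max(0, mid[2] - apex)
  }
  new("PhantomSpec", imageHeight = as.numeric(imageHeight),
      imageWidth = as.numeric(imageWidth), calibration = calibration,
      corneaAnteriorSagitta = as.numeric(corneaAnteriorSagitta),
      corneaThickness = as.numeric(corneaThickness),
      graftLeftCorner = as.numeric(graftLeftCorner),
      graftRightCorner = as.numeric(graftRightCorner),
      graftCentralThickness = as.numeric(graftCentralThickness),
      graftEdgeThickness = as.numeric(graftEdgeThickness),
      graftAnteriorSagitta = as.numeric(graftAnteriorSagitta),
      interfaceContrast = as.numeric(interfaceContrast),
      speckleSigma = as.numeric(speckleSigma),
      backgroundLevel = as.numeric(backgroundLevel), seed = as.numeric(seed))
}

#' Evaluate a phantom's exact truth curves
#'
#' @param truth a \code{\linkS4class{PhantomTruth}} (or the spec itself).
#' @param which "anterior" (host-graft interface) or "posterior".
#' @param cols columns at which to evaluate, within the corner span.
#' @return exact row positions (possibly fractional).
#' @export
truthCurveRow <- function(truth, which = c("anterior", "posterior"), cols) {
  which <- match.arg(which)
  spec <- if (is(truth, "PhantomTruth")) truth@spec else truth
  .graftArcFuns(spec)[[which]](cols)
}

#' Generate a synthetic B-scan with known graft geometry
#'
#' Renders the phantom described by \code{spec} (pixel centres at integer
#' coordinates; a pixel belongs to a structure when its centre falls inside
#' the structure's region) and returns it together with the analytic ground
#' truth: exact corner points, exact boundary curves, the closed-form graft
#' area and the true thickness profile. Identical spec and seed give a
#' bit-identical image.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return list with elements \code{image} (\code{\linkS4class{OCTImage}})
#'   and \code{truth} (\code{\linkS4class{PhantomTruth}}).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  H <- spec@imageHeight; W <- spec@imageWidth
  cols <- seq_len(W); rows <- seq_len(H)
  antFun <- .corneaAnteriorFun(spec)
  g <- .graftArcFuns(spec)
  band <- 0.8
  graftLevel <- band * (1 - spec@interfaceContrast)

  rowGrid <- matrix(rows, H, W)
  corneaTop <- matrix(antFun(cols), H, W, byrow = TRUE)
  img <- matrix(spec@backgroundLevel, H, W)
  img[rowGrid >= corneaTop & rowGrid < corneaTop + spec@corneaThickness] <- band

  x1 <- spec@graftLeftCorner[1]; x2 <- spec@graftRightCorner[1]
  inSpan <- cols >= x1 & cols <= x2
  gAnt <- rep(Inf, W); gPost <- rep(-Inf, W)
  gAnt[inSpan] <- g$anterior(cols[inSpan])
  gPost[inSpan] <- g$posterior(cols[inSpan])
  gAntM <- matrix(gAnt, H, W, byrow = TRUE)
  gPostM <- matrix(gPost, H, W, byrow = TRUE)
  img[rowGrid >= gAntM & rowGrid <= gPostM] <- graftLevel

  if (spec@speckleSigma > 0) {
    s <- spec@speckleSigma
    img <- withr::with_seed(as.integer(spec@seed), {
      img * exp(stats::rnorm(H * W, mean = -s^2 / 2, sd = s))
    })
    img[img > 1] <- 1
    img[img < 0] <- 0
  }

  truth <- .phantomTruth(spec)
  image <- octImage(img, spec@calibration,
                    imageId = sprintf("phantom_seed%d", as.integer(spec@seed)),
                    meta = list(generator = "octgraft phantom"))
  list(image = image, truth = truth)
}

.phantomTruth <- function(spec) {
  g <- .graftArcFuns(spec)
  x1 <- spec@graftLeftCorner[1]; x2 <- spec@graftRightCorner[1]
  e <- spec@graftEdgeThickness
  cs <- cornerSet(spec@graftLeftCorner, spec@graftLeftCorner + c(0, e),
                  spec@graftRightCorner, spec@graftRightCorner + c(0, e))
  xs <- unique(c(seq(x1, x2, by = 1), x2))
  ant <- cbind(col = xs, row = g$anterior(xs))
  post <- cbind(col = xs, row = g$posterior(xs))
  cal <- spec@calibration
  areaUm2 <- .truthAreaPx2(spec) * cal@lateral * cal@axial
  prof <- cbind(lateral_um = (xs - x1) * cal@lateral,
                thickness_um = (post[, 2] - ant[, 2]) * cal@axial)
  new("PhantomTruth", spec = spec, corners = cs, anterior = ant,
      posterior = post, areaUm2 = areaUm2, thicknessProfile = prof)
}

#' Draw a randomised phantom geometry
#'
#' Samples a plausible graft geometry under the given seed: lateral span
#' 40--70\% of the image width, central thickness 16--34 px, edge
#' thickness 6--14 px, corneal sagitta 60--100 px. Used for property
#' checks that should not depend on one fixed geometry.
#'
#' @param seed integer seed driving both the geometry draw and the
#'   phantom's speckle.
#' @param ... further arguments passed to \code{\link{phantomSpec}}
#'   (e.g. \code{speckleSigma}, \code{interfaceContrast}, \code{calibration}).
#' @return a \code{\linkS4class{PhantomSpec}}.
#' @export
randomPhantomSpec <- function(seed, ...) {
  withr::with_seed(as.integer(seed), {
    frac <- stats::runif(1, 0.40, 0.70)
    centre <- stats::runif(1, 0.42, 0.58)
    phantomSpec(
      corneaAnteriorSagitta = stats::runif(1, 60, 100),
      graftLeftCorner = NULL, graftRightCorner = NULL,
      graftCentralThickness = stats::runif(1, 16, 34),
      graftEdgeThickness = stats::runif(1, 6, 14),
      seed = seed, ...) -> sp
    # re-place the corners at the drawn span on the posterior cornea
    W <- sp@imageWidth
    x1 <- round((centre - frac / 2) * W); x2 <- round((centre + frac / 2) * W)
    antFun <- .corneaAnteriorFun(sp)
    sp@graftLeftCorner <- c(x1, antFun(x1) + sp@corneaThickness)
    sp@graftRightCorner <- c(x2, antFun(x2) + sp@corneaThickness)
    mid <- (sp@graftLeftCorner + sp@graftRightCorner) / 2
    sp@graftAnteriorSagitta <- max(0, mid[2] - (antFun(mid[1]) + sp@corneaThickness))
    validObject(sp)
    sp
  })
}

#' Derive a thin-graft stress spec
#'
#' Returns a spec whose true graft area lies below 80,000 um^2 at the given
#' calibration -- the regime in which the automated mode is expected to
#' overestimate because the host-graft interface stops being discernible.
#' The graft thickness is shrunk first (keeping the centre/edge shape,
#' central thickness never below 1 px); if that is not enough the lateral
#' span is reduced, down to a 40 px minimum.
#'
#' @param base a valid \code{\linkS4class{PhantomSpec}}.
#' @param thresholdUm2 thin-graft area threshold (default 80,000 um^2).
#' @return a \code{\linkS4class{PhantomSpec}} with true area below the
#'   threshold; \code{base} unchanged if it already qualifies.
#' @export
thinGraftSpec <- function(base, thresholdUm2 = 80000) {
  stopifnot(is(base, "PhantomSpec"))
  validObject(base)
  cal <- base@calibration
  areaOf <- function(sp) .truthAreaPx2(sp) * cal@lateral * cal@axial
  if (areaOf(base) < thresholdUm2) return(base)

  target <- 0.9 * thresholdUm2
  rho <- target / areaOf(base)
  shrink <- function(sp, f) {
    sp@graftCentralThickness <- max(1, f * base@graftCentralThickness)
    sp@graftEdgeThickness <- max(1, f * base@graftEdgeThickness)
    # keep the lens proportions: scale the interface sagitta with thickness
    sp@graftAnteriorSagitta <- f * base@graftAnteriorSagitta
    sp
  }
  # shrink span and thickness together (span never below 40 px) so the
  # thin graft keeps a resolvable end step rather than a 1 px sliver
  spanMin <- 40 / (base@graftRightCorner[1] - base@graftLeftCorner[1])
  for (gSpan in sort(unique(pmax(spanMin, c(sqrt(rho), seq(1, spanMin, by = -0.1)))),
                     decreasing = TRUE)) {
    sp <- base
    if (gSpan < 1) {
      mid <- (base@graftLeftCorner + base@graftRightCorner) / 2
      half <- (base@graftRightCorner - base@graftLeftCorner) / 2 * gSpan
      sp@graftLeftCorner <- mid - half
      sp@graftRightCorner <- mid + half
      sp@graftAnteriorSagitta <- base@graftAnteriorSagitta * gSpan^2
    }
    for (f in seq(1, 0.02, by = -0.02)) {
      cand <- shrink(sp, f)
      if (gSpan < 1) cand@graftAnteriorSagitta <- sp@graftAnteriorSagitta * f
      if (validObject(cand, test = TRUE) != TRUE) next
      if (areaOf(cand) < target) return(cand)
    }
  }
  .octError(sprintf(
    "no thin-graft spec below %g um^2 is feasible at %g x %g um/px with thickness >= 1 px",
    thresholdUm2, cal@lateral, cal@axial), "octgraft_spec_error")
}
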