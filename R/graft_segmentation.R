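#' @include AllClasses.R calibration.R boundary_extraction.R
NULL

.evalCurve <- function(curve, xs) {
  p <- curve@controlPoints
  if (nrow(p) == 2) return(stats::approx(p[, 1], p[, 2], xout = xs, rule = 2)$y)
  stats::splinefun(p[, 1], p[, 2], method = "natural")(xs)
}

#' Construct a graft boundary curve from control points
#'
#' @param controlPoints two-column (col, row) matrix with strictly
#'   increasing columns.
#' @return a \code{\linkS4class{GraftCurve}}; evaluate it with
#'   \code{\link{evalCurve}}.
#' @export
graftCurve <- function(controlPoints) {
  controlPoints <- as.matrix(controlPoints)
  colnames(controlPoints) <- c("col", "row")
  new("GraftCurve", controlPoints = controlPoints)
}

#' Evaluate a graft curve at lateral positions
#'
#' Natural cubic spline interpolation through the control points.
#'
#' @param curve a \code{\linkS4class{GraftCurve}}.
#' @param cols columns at which to evaluate.
#' @return row positions.
#' @export
evalCurve <- function(curve, cols) .evalCurve(curve, cols)

# --- corner detection ------------------------------------------------------

.kCosine <- function(P, k) {
  n <- nrow(P)
  curv <- rep(NA_real_, n)
  turn <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ki <- min(k, i - 1L, n - i)
    if (ki < 2) next
    v1 <- P[i - ki, ] - P[i, ]
    v2 <- P[i + ki, ] - P[i, ]
    d <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
    if (d < 1e-12) next
    ct <- sum(v1 * v2) / d
    ct <- max(-1, min(1, ct))
    curv[i] <- 1 + ct                       # 0 straight .. 2 full reversal
    turn[i] <- 180 - acos(ct) * 180 / pi    # turn angle in degrees
  }
  list(curv = curv, turn = turn)
}

.deepTrace <- function(edges, colsW, band) {
  E <- edges@edges; G <- edges@gradient; H <- nrow(E)
  lo <- max(1L, floor(band[1])); hi <- min(H, ceiling(band[2]))
  vapply(colsW, function(cc) {
    rowsE <- which(E[lo:hi, cc] > 0) + lo - 1L
    if (!length(rowsE)) return(NA_real_)
    r <- max(rowsE)
    if (r > 1 && r < H) {
      g1 <- G[r - 1, cc]; g2 <- G[r, cc]; g3 <- G[r + 1, cc]
      den <- g1 - 2 * g2 + g3
      if (abs(den) > 1e-12) r <- r + max(-0.5, min(0.5, 0.5 * (g1 - g3) / den))
    }
    r
  }, numeric(1))
}

.refineCornerPair <- function(edges, coarse, side, step) {
  W <- ncol(edges@edges)
  ant <- coarse$ant; post <- coarse$post
  colsW <- seq(max(1, floor(min(ant[1], post[1]) - 2 * step)),
               min(W, ceiling(max(ant[1], post[1]) + 2 * step)))
  band <- c(min(ant[2], post[2]) - 2 * step, max(ant[2], post[2]) + 2 * step)
  tr <- .deepTrace(edges, colsW, band)
  ok <- !is.na(tr)
  if (sum(ok) < 3) return(coarse)
  colsW <- colsW[ok]; tr <- tr[ok]
  d <- diff(tr)
  if (!length(d)) return(coarse)
  j <- if (side == "left") which.max(d) else which.min(d)
  if (abs(d[j]) < 2) return(coarse)          # no clear step; keep coarse corners
  cc <- if (side == "left") colsW[j + 1] else colsW[j]
  # corner rows by linear extrapolation of the trace from >= 3 px outside
  # the corner zone: edge localisation right at the corner is perturbed by
  # the 2-D blur of the vertical graft end
  extrap <- function(mask, fallback) {
    xs <- colsW[mask]; ys <- tr[mask]
    if (length(xs) >= 3)
      unname(stats::predict(stats::lm(ys ~ xs), data.frame(xs = cc)))
    else if (length(xs) >= 1) stats::median(ys)
    else fallback
  }
  beforeMask <- seq_along(colsW) <= j & colsW <= cc - 3
  afterMask <- seq_along(colsW) > j & colsW >= cc + 3
  if (side == "left")
    list(ant = c(cc, extrap(beforeMask, coarse$ant[2])),
         post = c(cc, extrap(afterMask, coarse$post[2])))
  else
    list(ant = c(cc, extrap(afterMask, coarse$ant[2])),
         post = c(cc, extrap(beforeMask, coarse$post[2])))
}

#' Locate the four graft corner points
#'
#' Computes a discrete curvature (k-cosine over a support half-window of
#' \code{k} samples) along the boundary polyline; candidate corners are
#' local curvature maxima whose z-score exceeds a global significance
#' threshold and whose turn angle is non-trivial. Candidates cluster at the
#' two lateral ends of the graft band; within the strongest left and right
#' clusters the anterior (upper) and posterior (lower) curvature peaks
#' become the labelled corners. When an \code{\linkS4class{EdgeMap}} is
#' supplied, each corner pair is refined to single-pixel resolution by
#' re-tracing the boundary at step 1 around the coarse corner and locating
#' the row jump of the graft end.
#'
#' @param boundary a \code{\linkS4class{SampledBoundary}} (gap columns are
#'   ignored), or a bare two-column (col, row) matrix.
#' @param edges optional \code{\linkS4class{EdgeMap}} for sub-sample corner
#'   refinement.
#' @param k support half-window in samples (>= 2).
#' @param zThresh curvature z-score significance threshold.
#' @param minAngle minimum turn angle in degrees.
#' @return a \code{\linkS4class{CornerSet}}.
#' @export
detectCorners <- function(boundary, edges = NULL, k = 5, zThresh = 2,
                          minAngle = 25) {
  P <- if (is(boundary, "SampledBoundary")) boundary@points else as.matrix(boundary)
  step <- if (is(boundary, "SampledBoundary")) boundary@step else
    stats::median(diff(P[, 1]))
  P <- P[!is.na(P[, 2]), , drop = FALSE]
  if (nrow(P) < 5)
    .octError("corner detection needs a boundary with at least 5 points",
              "octgraft_corner_error")
  kc <- .kCosine(P, k)
  valid <- which(!is.na(kc$curv))
  # robust z-score: corners are extreme outliers of the curvature
  # distribution, so median/MAD keeps them significant when boundary
  # jitter inflates the ordinary standard deviation
  mu <- stats::median(kc$curv[valid])
  spread <- max(stats::mad(kc$curv[valid]), 0.02)
  z <- rep(NA_real_, nrow(P))
  z[valid] <- if (max(kc$curv[valid]) - mu < 1e-9) 0 else (kc$curv[valid] - mu) / spread
  candAngle <- !is.na(z) & z > zThresh & kc$turn > minAngle
  # complementary local test: the discrete second difference of the rows
  # in pixels. A shallow graft end deflects the polyline by only a few
  # pixels -- far below any angular threshold at this support -- yet is
  # still a sharp local curvature event relative to the smooth cornea
  n <- nrow(P)
  jmp <- rep(0, n)
  if (n >= 4) {
    d <- diff(P[, 2])
    sec <- abs(d[-1] - d[-length(d)])              # at points 2..n-1
    jmpThr <- max(3 * stats::mad(sec), 2)
    jmp[2:(n - 1)] <- sec / jmpThr
  }
  score <- pmax(ifelse(is.na(z), 0, z / zThresh), jmp)
  cand <- which(candAngle | jmp > 1)
  if (length(cand) < 2)
    .octError(sprintf("corner detection failed: %d significant curvature maxima found (need the 4 graft corners)",
                      length(cand)), "octgraft_corner_error")
  clusters <- unname(split(cand, cumsum(c(0, diff(cand) > 2))))
  if (length(clusters) < 2)
    .octError(sprintf("corner detection failed: %d significant curvature maxima in a single region (need both graft ends)",
                      length(cand)), "octgraft_corner_error")
  peak <- vapply(clusters, function(ix) max(score[ix]), numeric(1))
  keep <- clusters[order(-peak)[1:2]]
  keep <- keep[order(vapply(keep, function(ix) mean(P[ix, 1]), numeric(1)))]

  pickPair <- function(ix) {
    rowsC <- P[ix, 2]
    midrow <- (min(rowsC) + max(rowsC)) / 2
    upper <- ix[rowsC <= midrow]; lower <- ix[rowsC > midrow]
    pick <- function(sub) sub[order(-score[sub], -jmp[sub])][1]
    if (!length(lower)) {
      best <- pick(ix)
      return(list(ant = P[best, ], post = P[best, ]))
    }
    list(ant = P[pick(upper), ], post = P[pick(lower), ])
  }
  left <- pickPair(keep[[1]])
  right <- pickPair(keep[[2]])
  if (!is.null(edges)) {
    left <- .refineCornerPair(edges, left, "left", step)
    right <- .refineCornerPair(edges, right, "right", step)
  }
  fix <- function(p) list(ant = c(p$ant[1], min(p$ant[2], p$post[2])),
                          post = c(p$post[1], max(p$ant[2], p$post[2])))
  left <- fix(left); right <- fix(right)
  cornerSet(unname(left$ant), unname(left$post), unname(right$ant), unname(right$post))
}

# --- anterior interface ----------------------------------------------------

# algebraic (Kasa) circle fit; returns an evaluator row(col) on the branch
# nearest the data, or NULL when the fit is degenerate
.fitCircleRow <- function(x, y) {
  if (length(x) < 6) return(NULL)
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  co <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(co) || anyNA(co)) return(NULL)
  cx <- -co[1] / 2; cy <- -co[2] / 2
  R2 <- cx^2 + cy^2 - co[3]
  if (!is.finite(R2) || R2 <= 0) return(NULL)
  sgn <- if (stats::median(y) <= cy) -1 else 1
  function(cols) {
    d2 <- R2 - (cols - cx)^2
    out <- rep(NA_real_, length(cols))
    ok <- d2 >= 0
    out[ok] <- cy + sgn * sqrt(d2[ok])
    out
  }
}

#' Extract the low-contrast host-graft interface
#'
#' For each sampled column between the two anterior corners, a band above
#' the posterior boundary is searched for the strongest anterior-directed
#' intensity drop (the most negative axial gradient of the smoothed image).
#' The expected interface position is the continuation of the recipient
#' posterior corneal surface, estimated by a circle fit to the boundary
#' trace outside the graft span; the band reaches at most 1.5x the local
#' band-thickness estimate above the posterior boundary, but never less
#' than \code{minDepth} pixels. A column becomes an explicit gap when no negative axial gradient
#' exists in its band, or when its pick is inconsistent with a smooth path
#' joining the two anterior corners. When more than \code{maxGapFrac} of
#' the columns are gaps the interface is declared undetectable -- the
#' thin-graft, low-contrast regime in which automated readings are
#' unreliable.
#'
#' @param image the (preferably pre-smoothed) \code{\linkS4class{OCTImage}}.
#' @param corners a \code{\linkS4class{CornerSet}}.
#' @param posterior the sampled posterior boundary.
#' @param minDepth minimum search depth above the posterior boundary, px.
#' @param smoothTol residual (px) beyond which a pick is marked a gap.
#' @param maxGapFrac gap fraction above which extraction fails.
#' @param sigma Gaussian scale for the axial gradient.
#' @return a \code{\linkS4class{SampledBoundary}} of interface points (gaps
#'   as NA rows).
#' @export
extractAnteriorInterface <- function(image, corners, posterior,
                                     minDepth = 8, smoothTol = 4,
                                     maxGapFrac = 0.5, sigma = 2) {
  stopifnot(is(image, "OCTImage"), is(corners, "CornerSet"),
            is(posterior, "SampledBoundary"))
  cp <- corners@points
  la <- cp["left_anterior", ]; ra <- cp["right_anterior", ]
  pp <- posterior@points
  pp <- pp[!is.na(pp[, 2]), , drop = FALSE]
  if (!nrow(pp))
    .octError("posterior boundary holds no usable points", "octgraft_boundary_error")
  cols <- pp[pp[, 1] > la[1] & pp[, 1] < ra[1], 1]
  if (length(cols) < 2)
    .octError("fewer than two sampled columns between the anterior corners",
              "octgraft_geometry_error")
  postRow <- stats::approx(pp[, 1], pp[, 2], xout = cols, rule = 2)$y
  # expected interface position: the host-graft interface is the
  # continuation of the recipient posterior corneal surface, so fit a
  # circle to the boundary trace outside the graft span and interpolate it
  # across the span; fall back to the corner chord when no outside-span
  # trace is available
  outside <- pp[pp[, 1] <= la[1] | pp[, 1] >= ra[1], , drop = FALSE]
  estFun <- .fitCircleRow(outside[, 1], outside[, 2])
  chord <- function(z) la[2] + (z - la[1]) / (ra[1] - la[1]) * (ra[2] - la[2])
  est <- if (is.null(estFun)) chord(cols) else estFun(cols)
  est[is.na(est)] <- chord(cols[is.na(est)])
  tLoc <- pmax(postRow - est, 0)
  depth <- pmax(1.5 * tLoc, minDepth)

  sm <- .gaussBlur(image@pixels, sigma)
  H <- nrow(sm)
  gy <- (.shiftRows(sm, -1L) - .shiftRows(sm, 1L)) / 2
  rows <- vapply(seq_along(cols), function(i) {
    cc <- cols[i]
    rHi <- floor(postRow[i] - 2)
    rLo <- max(2, ceiling(postRow[i] - depth[i]))
    if (rHi < rLo) return(NA_real_)
    rowsB <- rLo:rHi
    gseg <- gy[rowsB, cc]
    # a usable pick is a local maximum of the anterior-directed drop
    # (checked against the full column): the monotone blur tail of the
    # posterior edge itself never qualifies
    isMax <- gseg < 0 &
      gseg <= gy[pmax(rowsB - 1, 1), cc] &
      gseg <= gy[pmin(rowsB + 1, H), cc]
    if (!any(isMax)) return(NA_real_)
    j <- rowsB[isMax][which.min(gseg[isMax])] - rLo + 1L
    r <- rLo + j - 1L
    if (r > 1 && r < H) {
      g1 <- -gy[r - 1, cc]; g2 <- -gy[r, cc]; g3 <- -gy[r + 1, cc]
      den <- g1 - 2 * g2 + g3
      if (abs(den) > 1e-12) r <- r + max(-0.5, min(0.5, 0.5 * (g1 - g3) / den))
    }
    r
  }, numeric(1))

  usable <- !is.na(rows)
  if (sum(usable) >= 4) {
    xs <- c(la[1], cols[usable], ra[1])
    ys <- c(la[2], rows[usable], ra[2])
    w <- c(10, rep(1, sum(usable)), 10)
    fit <- tryCatch(stats::smooth.spline(xs, ys, w = w), error = function(e) NULL)
    if (!is.null(fit)) {
      resid <- abs(rows[usable] - stats::predict(fit, cols[usable])$y)
      drop <- which(usable)[resid > smoothTol]
      rows[drop] <- NA_real_
    }
  }
  gapFrac <- mean(is.na(rows))
  if (gapFrac > maxGapFrac)
    .octError(sprintf(
      "low-contrast host-graft interface: %.0f%% of sampled columns have no consistent gradient (thin-graft regime)",
      100 * gapFrac), "octgraft_lowcontrast_error")
  new("SampledBoundary", points = cbind(col = cols, row = rows),
      step = posterior@step)
}

# --- curve fitting ---------------------------------------------------------

.fitCurveThroughCorners <- function(pts, c1, c2, spar = NULL, cornerMargin = 5) {
  p <- pts[!is.na(pts[, 2]), , drop = FALSE]
  # samples within the corner blur zone carry corner-perturbed edge
  # positions; the corners themselves anchor the fit there
  p <- p[p[, 1] > c1[1] + cornerMargin & p[, 1] < c2[1] - cornerMargin, , drop = FALSE]
  if (nrow(p) < 2)
    p <- pts[!is.na(pts[, 2]) & pts[, 1] > c1[1] & pts[, 1] < c2[1], , drop = FALSE]
  if (nrow(p) < 2)
    .octError("curve fitting needs at least 2 non-gap boundary points",
              "octgraft_geometry_error")
  x <- p[, 1]; y <- p[, 2]
  predFun <- if (length(unique(x)) >= 4) {
    fit <- if (is.null(spar)) stats::smooth.spline(x, y)
           else stats::smooth.spline(x, y, spar = spar)
    function(z) stats::predict(fit, z)$y
  } else {
    function(z) stats::approx(x, y, xout = z, rule = 2)$y
  }
  # anchor exactly at the corners with a tapered correction: each corner
  # residual is blended out over ~15% of the span so a sub-pixel corner
  # error stays local instead of biasing the whole curve
  r1 <- c1[2] - predFun(c1[1]); r2 <- c2[2] - predFun(c2[1])
  L <- max(20, 0.15 * (c2[1] - c1[1]))
  taper <- function(u) ifelse(u >= 1, 0, 0.5 * (1 + cos(pi * pmin(u, 1))))
  corr <- function(z) r1 * taper((z - c1[1]) / L) + r2 * taper((c2[1] - z) / L)
  ctrlX <- sort(unique(c(c1[1], x, c2[1])))
  ctrlX <- ctrlX[c(TRUE, diff(ctrlX) > 1e-6)]
  graftCurve(cbind(ctrlX, predFun(ctrlX) + corr(ctrlX)))
}

#' Fit corner-anchored boundary curves into a closed segmentation
#'
#' Least-squares cubic smoothing splines (smoothing parameter chosen by
#' generalised cross-validation unless \code{spar} is given) are fitted
#' through the anterior and posterior boundary points, constrained by a
#' linear correction to pass exactly through the corresponding corner
#' points; gap columns are bridged by the spline.
#'
#' @param anteriorPts,posteriorPts \code{\linkS4class{SampledBoundary}}s
#'   (or bare (col, row) matrices) with >= 2 non-gap points each.
#' @param corners a \code{\linkS4class{CornerSet}}.
#' @param spar optional fixed smoothing parameter for
#'   \code{\link[stats]{smooth.spline}}.
#' @param imageId identifier stored in the segmentation.
#' @return a \code{\linkS4class{GraftSegmentation}} with mode
#'   \code{"automated"}.
#' @export
fitGraft <- function(anteriorPts, posteriorPts, corners, spar = NULL,
                     imageId = "image") {
  stopifnot(is(corners, "CornerSet"))
  getPts <- function(b) if (is(b, "SampledBoundary")) b@points else as.matrix(b)
  cp <- corners@points
  if (cp["right_anterior", 1] - cp["left_anterior", 1] < 10)
    .octError("degenerate lateral span (< 10 px) between the anterior corners",
              "octgraft_geometry_error")
  ant <- .fitCurveThroughCorners(getPts(anteriorPts),
                                 cp["left_anterior", ], cp["right_anterior", ], spar)
  post <- .fitCurveThroughCorners(getPts(posteriorPts),
                                  cp["left_posterior", ], cp["right_posterior", ], spar)
  # both curves must cover the same lateral domain: the corner span
  dom <- range(cp[, 1])
  extend <- function(curve) {
    p <- curve@controlPoints
    xs <- sort(unique(c(dom[1], p[, 1], dom[2])))
    xs <- xs[c(TRUE, diff(xs) > 1e-6)]
    graftCurve(cbind(xs, .evalCurve(curve, xs)))
  }
  ant <- extend(ant); post <- extend(post)
  xs <- seq(dom[1], dom[2], length.out = 257)
  if (min(.evalCurve(post, xs) - .evalCurve(ant, xs)) < -1e-6)
    .octError("fitted curves cross: posterior must lie at or below anterior (negative thickness)",
              "octgraft_geometry_error")
  new("GraftSegmentation", anterior = ant, posterior = post,
      corners = corners, mode = "automated", imageId = imageId)
}

# --- semi-automated refinement --------------------------------------------

#' Adjust segmentation control points (semi-automated mode)
#'
#' Applies manual control-point edits -- the semi-automated protocol in
#' which the observer readjusts the corner points and points on the
#' anterior and posterior margins. Each edit names a curve, a control-point
#' index and a new (col, row) position; endpoint edits move the
#' corresponding corner. Edits that break single-valuedness, produce
#' negative thickness, or leave the image are rejected with the violated
#' invariant named. The returned segmentation has mode
#' \code{"semi_automated"} even for an empty edit list.
#'
#' @param seg a \code{\linkS4class{GraftSegmentation}}.
#' @param edits list of \code{list(curve = "anterior"|"posterior",
#'   index = i, point = c(col, row))}.
#' @param imageSize optional c(nrow, ncol) bound check for new positions.
#' @return the edited \code{\linkS4class{GraftSegmentation}}.
#' @export
adjustControlPoints <- function(seg, edits = list(), imageSize = NULL) {
  stopifnot(is(seg, "GraftSegmentation"))
  for (ed in edits) {
    if (!is.list(ed) || is.null(ed$curve) || is.null(ed$index) || is.null(ed$point))
      .octError("each edit needs fields curve, index and point", "octgraft_edit_error")
    if (!ed$curve %in% c("anterior", "posterior"))
      .octError(sprintf("unknown curve '%s' in edit", ed$curve), "octgraft_edit_error")
    cp <- slot(seg, ed$curve)@controlPoints
    i <- ed$index
    if (i < 1 || i > nrow(cp))
      .octError(sprintf("edit index %d out of range for the %s curve", i, ed$curve),
                "octgraft_edit_error")
    pt <- as.numeric(ed$point)
    if (length(pt) != 2 || !all(is.finite(pt)))
      .octError("edit point must be a finite (col, row) pair", "octgraft_edit_error")
    if (!is.null(imageSize) &&
        (pt[1] < 1 || pt[1] > imageSize[2] || pt[2] < 1 || pt[2] > imageSize[1]))
      .octError("edit rejected: new position lies outside the image", "octgraft_edit_error")
    cp[i, ] <- pt
    if (any(diff(cp[, 1]) <= 0))
      .octError("edit rejected: violates single-valuedness in column", "octgraft_edit_error")
    curve <- graftCurve(cp)
    slot(seg, ed$curve) <- curve
    # endpoint edits move the corresponding corner
    cpts <- seg@corners@points
    if (i == 1) cpts[if (ed$curve == "anterior") "left_anterior" else "left_posterior", ] <- pt
    if (i == nrow(cp)) cpts[if (ed$curve == "anterior") "right_anterior" else "right_posterior", ] <- pt
    seg@corners <- new("CornerSet", points = cpts)
  }
  seg@mode <- "semi_automated"
  v <- validObject(seg, test = TRUE)
  if (!isTRUE(v))
    .octError(paste0("edit rejected: ", v), "octgraft_edit_error")
  v2 <- validObject(seg@corners, test = TRUE)
  if (!isTRUE(v2))
    .octError(paste0("edit rejected: ", v2), "octgraft_edit_error")
  seg
}

#' Snap a segmentation's control points onto phantom truth curves
#'
#' The idealised semi-automated protocol on synthetic data: the observer
#' drags the four corners onto the true corner points and every control
#' point onto the visible true boundary. Control columns are mapped
#' affinely onto the truth's corner span, rows taken from the exact truth
#' curves.
#'
#' @param seg a \code{\linkS4class{GraftSegmentation}}.
#' @param truth the matching \code{\linkS4class{PhantomTruth}}.
#' @return a \code{\linkS4class{GraftSegmentation}} with mode
#'   \code{"semi_automated"} lying on the truth geometry.
#' @export
snapSegmentationToTruth <- function(seg, truth) {
  stopifnot(is(seg, "GraftSegmentation"), is(truth, "PhantomTruth"))
  tc <- truth@corners@points
  x1 <- tc["left_anterior", 1]; x2 <- tc["right_anterior", 1]
  remap <- function(curve, which) {
    p <- curve@controlPoints
    old <- range(p[, 1])
    xs <- x1 + (p[, 1] - old[1]) / diff(old) * (x2 - x1)
    xs <- sort(unique(xs))
    graftCurve(cbind(xs, truthCurveRow(truth, which, xs)))
  }
  ant <- remap(seg@anterior, "anterior")
  post <- remap(seg@posterior, "posterior")
  new("GraftSegmentation", anterior = ant, posterior = post,
      corners = truth@corners, mode = "semi_automated", imageId = seg@imageId)
}

# --- full automated pipeline ----------------------------------------------

.stage <- function(name, expr) {
  tryCatch(expr, octgraft_error = function(e) {
    .octError(sprintf("stage '%s': %s", name, conditionMessage(e)),
              class(e)[1])
  })
}

#' Fully automated graft segmentation
#'
#' The four-step pipeline: (1) filter the image and extract its boundary
#' with the Canny detector, sampling the output at fixed column steps;
#' (2) locate the four graft corner points from local curvature of the
#' posterior boundary trace; (3) extract the low-contrast host-graft
#' interface; (4) fit corner-anchored best-fit curves to close the graft
#' segmentation. All parameters come from the configuration. Stage
#' failures are re-raised with the stage name.
#'
#' @param image an \code{\linkS4class{OCTImage}}.
#' @param config an \code{\link{octConfig}} configuration.
#' @param verbose log per-stage timings to stderr.
#' @return a \code{\linkS4class{GraftSegmentation}} with mode
#'   \code{"automated"}.
#' @export
segmentAutomated <- function(image, config = octConfig(), verbose = FALSE) {
  stopifnot(is(image, "OCTImage"))
  t0 <- as.numeric(proc.time()["elapsed"])
  pre <- .stage("preprocess", preprocessImage(image, config$preprocess$scale))
  t0 <- .logStage(verbose, "preprocess", t0)
  edges <- .stage("edge_detection",
                  detectEdges(pre, config$canny$low_q, config$canny$high_q,
                              config$canny$sigma))
  t0 <- .logStage(verbose, "edge_detection", t0)
  boundary <- .stage("boundary_sampling",
                     sampleBoundary(edges, step = config$sampling$step,
                                    select = config$sampling$select))
  t0 <- .logStage(verbose, "boundary_sampling", t0)
  cs <- .stage("corner_detection",
               detectCorners(boundary, edges, k = config$corner$k,
                             zThresh = config$corner$z_thresh,
                             minAngle = config$corner$min_angle))
  t0 <- .logStage(verbose, "corner_detection", t0)
  cp <- cs@points
  bp <- boundary@points
  sel <- bp[, 1] >= cp["left_posterior", 1] & bp[, 1] <= cp["right_posterior", 1]
  posterior <- new("SampledBoundary", points = bp[sel, , drop = FALSE],
                   step = boundary@step)
  anterior <- .stage("anterior_interface",
                     extractAnteriorInterface(pre, cs, boundary,
                                              minDepth = config$interface$min_depth,
                                              smoothTol = config$interface$smooth_tol,
                                              maxGapFrac = config$interface$max_gap_frac,
                                              sigma = config$interface$sigma))
  t0 <- .logStage(verbose, "anterior_interface", t0)
  seg <- .stage("curve_fitting",
                fitGraft(anterior, posterior, cs, spar = config$spline$spar,
                         imageId = image@imageId))
  .logStage(verbose, "curve_fitting", t0)
  seg
}
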