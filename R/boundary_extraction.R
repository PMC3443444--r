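#' @include AllClasses.R calibration.R
NULL

# separable Gaussian convolution with replicated edges (no wrap-around:
# the corneal band must not bleed across image borders)
.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

.shiftRows <- function(M, by) {
  H <- nrow(M)
  idx <- pmin(pmax(seq_len(H) - by, 1L), H)
  M[idx, , drop = FALSE]
}

.shiftCols <- function(M, by) {
  W <- ncol(M)
  idx <- pmin(pmax(seq_len(W) - by, 1L), W)
  M[, idx, drop = FALSE]
}

.gaussBlur <- function(M, sigma) {
  if (sigma <= 0) return(M)
  k <- .gaussKernel(sigma)
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(M), ncol(M))
  for (j in seq_along(k)) out <- out + k[j] * .shiftRows(M, j - r - 1L)
  M2 <- out
  out <- matrix(0, nrow(M), ncol(M))
  for (j in seq_along(k)) out <- out + k[j] * .shiftCols(M2, j - r - 1L)
  out
}

#' Smooth a B-scan before edge extraction
#'
#' Gaussian filtering; a scale of 0 returns the input unchanged, and a
#' constant image is unchanged at any scale. Intensities remain in [0, 1].
#'
#' @param image an \code{\linkS4class{OCTImage}}.
#' @param smoothingScale Gaussian sigma in pixels, >= 0.
#' @return the smoothed \code{\linkS4class{OCTImage}}.
#' @export
preprocessImage <- function(image, smoothingScale = 2) {
  stopifnot(is(image, "OCTImage"))
  if (!is.numeric(smoothingScale) || length(smoothingScale) != 1 || smoothingScale < 0)
    .octError("smoothing scale must be a single number >= 0", "octgraft_parameter_error")
  if (smoothingScale == 0) return(image)
  p <- .gaussBlur(image@pixels, smoothingScale)
  p[p < 0] <- 0; p[p > 1] <- 1
  image@pixels <- p
  image
}

.sobelGradients <- function(M) {
  # smoothed central differences (Sobel): gx lateral (columns), gy axial (rows)
  sx <- .shiftCols(M, -1L) - .shiftCols(M, 1L)
  gx <- (.shiftRows(sx, -1L) + 2 * sx + .shiftRows(sx, 1L)) / 8
  sy <- .shiftRows(M, -1L) - .shiftRows(M, 1L)
  gy <- (.shiftCols(sy, -1L) + 2 * sy + .shiftCols(sy, 1L)) / 8
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

.nonMaxSuppress <- function(mag, gx, gy) {
  theta <- atan2(gy, gx)
  sector <- (round(theta / (pi / 4)) %% 4)
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  neigh <- list(
    `0` = list(.shiftCols(mag, 1L), .shiftCols(mag, -1L)),            # gradient along columns
    `1` = list(.shiftRows(.shiftCols(mag, 1L), 1L),
               .shiftRows(.shiftCols(mag, -1L), -1L)),
    `2` = list(.shiftRows(mag, 1L), .shiftRows(mag, -1L)),            # gradient along rows
    `3` = list(.shiftRows(.shiftCols(mag, 1L), -1L),
               .shiftRows(.shiftCols(mag, -1L), 1L)))
  for (s in 0:3) {
    sel <- sector == s
    nb <- neigh[[as.character(s)]]
    keep[sel] <- mag[sel] >= nb[[1]][sel] & mag[sel] >= nb[[2]][sel]
  }
  keep & mag > 0
}

.hysteresis <- function(weak, strong) {
  if (!any(strong)) return(strong)
  H <- nrow(weak); W <- ncol(weak)
  idx <- which(weak)
  node <- match(seq_len(H * W), idx)          # pixel index -> weak node id
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  edges <- NULL
  for (i in seq_len(nrow(offs))) {
    r2 <- r + offs$dr[i]; c2 <- cc + offs$dc[i]
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    j <- (c2[ok] - 1L) * H + r2[ok]
    nb <- node[j]
    src <- seq_along(idx)[ok]
    keep <- !is.na(nb)
    edges <- rbind(edges, cbind(src[keep], nb[keep]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  strongComp <- unique(comp[node[which(strong)]])
  out <- matrix(FALSE, H, W)
  out[idx[comp %in% strongComp]] <- TRUE
  out
}

#' Canny edge detection
#'
#' Standard Canny: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression to one-pixel ridges, and hysteresis linking. Hysteresis
#' thresholds are expressed as quantiles of the positive gradient
#' magnitude, making the edge map invariant to affine rescaling of the
#' image intensities.
#'
#' @param image an \code{\linkS4class{OCTImage}}.
#' @param lowThreshold,highThreshold hysteresis thresholds as quantiles in
#'   [0, 1] of the positive gradient magnitudes, low <= high.
#' @param sigma Gaussian scale in pixels, > 0.
#' @return an \code{\linkS4class{EdgeMap}} (which also carries the gradient
#'   magnitude for downstream tie-breaking and sub-pixel refinement).
#' @export
detectEdges <- function(image, lowThreshold = 0.80, highThreshold = 0.95, sigma = 2) {
  stopifnot(is(image, "OCTImage"))
  if (!(lowThreshold >= 0 && lowThreshold <= highThreshold && highThreshold <= 1))
    .octError("thresholds must satisfy 0 <= low <= high <= 1", "octgraft_parameter_error")
  if (sigma <= 0) .octError("Canny sigma must be > 0", "octgraft_parameter_error")
  sm <- .gaussBlur(image@pixels, sigma)
  gr <- .sobelGradients(sm)
  nms <- .nonMaxSuppress(gr$mag, gr$gx, gr$gy)
  lo <- stats::quantile(gr$mag, lowThreshold, names = FALSE)
  hi <- stats::quantile(gr$mag, highThreshold, names = FALSE)
  if (hi <= 0)                      # (near-)constant image: no edges
    return(new("EdgeMap", edges = matrix(0, nrow(sm), ncol(sm)),
               gradient = gr$mag, imageId = image@imageId))
  lo <- max(lo, 1e-12)
  weak <- nms & gr$mag >= lo
  strong <- nms & gr$mag >= hi
  linked <- .hysteresis(weak, strong)
  new("EdgeMap", edges = linked + 0, gradient = gr$mag, imageId = image@imageId)
}

#' Sample an edge map into a boundary polyline
#'
#' Every \code{step} columns across the edge support (within the optional
#' row \code{band}), one edge pixel is selected; sampling the noisy edge
#' output at a coarse step reduces the effect of interference noise on the
#' extracted boundary. Columns with no edge pixel are recorded as explicit
#' gaps (NA row), never fabricated. The selected row is refined to
#' sub-pixel precision by a parabolic fit of the gradient magnitude.
#'
#' @param edges an \code{\linkS4class{EdgeMap}}.
#' @param step sampling step in pixels (default 10).
#' @param band optional c(rowMin, rowMax) restricting the search.
#' @param select rule when a column holds several edge pixels:
#'   \code{"strongest"} (greatest gradient magnitude, ties towards the
#'   smaller row), \code{"deepest"} (largest row -- the posterior-most
#'   boundary), or \code{"shallowest"}.
#' @param refine logical; sub-pixel refinement of the selected rows.
#' @return a \code{\linkS4class{SampledBoundary}}.
#' @export
sampleBoundary <- function(edges, step = 10, band = NULL,
                           select = c("strongest", "deepest", "shallowest"),
                           refine = TRUE) {
  stopifnot(is(edges, "EdgeMap"))
  select <- match.arg(select)
  if (step < 1) .octError("sampling step must be >= 1", "octgraft_parameter_error")
  E <- edges@edges
  H <- nrow(E)
  if (is.null(band)) band <- c(1, H)
  if (band[1] < 1 || band[2] > H || band[1] > band[2])
    .octError("band must lie within the image rows", "octgraft_parameter_error")
  Eb <- E
  if (band[1] > 1) Eb[seq_len(band[1] - 1), ] <- 0
  if (band[2] < H) Eb[seq(band[2] + 1, H), ] <- 0
  support <- which(colSums(Eb) > 0)
  if (!length(support))
    .octError("no edge pixels in the sampled band (empty boundary)",
              "octgraft_boundary_error")
  colsS <- seq(min(support), max(support), by = step)
  G <- edges@gradient
  pts <- vapply(colsS, function(cc) {
    rowsE <- which(Eb[, cc] > 0)
    if (!length(rowsE)) return(NA_real_)
    r <- switch(select,
                strongest = rowsE[order(-G[rowsE, cc], rowsE)][1],
                deepest = max(rowsE),
                shallowest = min(rowsE))
    if (refine && r > 1 && r < H) {
      g1 <- G[r - 1, cc]; g2 <- G[r, cc]; g3 <- G[r + 1, cc]
      den <- g1 - 2 * g2 + g3
      if (abs(den) > 1e-12) {
        d <- 0.5 * (g1 - g3) / den
        r <- r + max(-0.5, min(0.5, d))
      }
    }
    r
  }, numeric(1))
  new("SampledBoundary", points = cbind(col = colsS, row = pts),
      step = as.numeric(step))
}
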