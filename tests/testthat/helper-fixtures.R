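# shared fixtures and independent oracles, built in code

cal10 <- calibrationSpec(10, 10)

# a rectangular band segmentation: width x thickness px, anterior at `top`
rectSegmentation <- function(width = 200, thickness = 50, left = 20, top = 40,
                             nCtrl = 5) {
  xs <- seq(left, left + width, length.out = nCtrl)
  ant <- graftCurve(cbind(xs, rep(top, nCtrl)))
  post <- graftCurve(cbind(xs, rep(top + thickness, nCtrl)))
  cs <- cornerSet(c(left, top), c(left, top + thickness),
                  c(left + width, top), c(left + width, top + thickness))
  new("GraftSegmentation", anterior = ant, posterior = post, corners = cs,
      mode = "automated", imageId = "rect")
}

# brute-force rasterisation area oracle: counts sub-pixel cells (quarter
# pixel by default) whose centre falls between the two curves --
# independent of the shoelace path
rasterAreaPx2 <- function(antFun, postFun, x1, x2, res = 0.25) {
  cols <- seq(ceiling(x1 / res) * res, floor(x2 / res) * res, by = res)
  a <- antFun(cols); p <- postFun(cols)
  sum(pmax(0, floor(p / res) - ceiling(a / res) + 1)) * res^2
}

# independent circular-segment area (geometry textbook closed form),
# written against the central angle rather than the sagitta
segmentAreaFromChord <- function(chord, sagitta) {
  if (abs(sagitta) < 1e-12) return(0)
  s <- abs(sagitta)
  R <- s / 2 + chord^2 / (8 * s)
  theta <- 2 * asin(min(1, chord / (2 * R)))
  R^2 / 2 * (theta - sin(theta))
}

# posterior-trace polyline of a rectangular graft end-step profile:
# flat at row y0, drops to y1 between columns cl..cr, back up after
stepTrace <- function(cols, y0, y1, cl, cr) {
  rows <- ifelse(cols >= cl & cols <= cr, y1, y0)
  cbind(col = cols, row = rows)
}
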