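test_that("corners of a rectangular end-step trace sit on its vertices", {
  # finely sampled trace: vertices recovered within 1 px
  tr1 <- stepTrace(0:300, y0 = 80, y1 = 120, cl = 100, cr = 200)
  cp1 <- cornerPoints(detectCorners(tr1))
  expect_lte(max(abs(cp1["left_anterior", ] - c(100, 80))), 1)
  expect_lte(max(abs(cp1["left_posterior", ] - c(100, 120))), 1)
  expect_lte(max(abs(cp1["right_anterior", ] - c(200, 80))), 1)
  expect_lte(max(abs(cp1["right_posterior", ] - c(200, 120))), 1)

  # coarsely sampled trace: still found, localised to the sampling step
  cols <- seq(0, 300, by = 10)
  cp <- cornerPoints(detectCorners(stepTrace(cols, 80, 120, 100, 200)))
  expect_lte(max(abs(cp[, 1] - c(100, 100, 200, 200))), 10)
  expect_equal(unname(cp[c(1, 3), 2]), c(80, 80))
  expect_equal(unname(cp[c(2, 4), 2]), c(120, 120))
})

test_that("constant-curvature contours yield a corner-detection failure", {
  th <- seq(-1, 1, length.out = 60)
  arc <- cbind(col = 200 * th + 200, row = 150 - 80 * cos(th))
  expect_error(detectCorners(arc), "curvature maxima",
               class = "octgraft_corner_error")
  line <- cbind(col = seq(0, 300, 10), row = seq(50, 80, length.out = 31))
  expect_error(detectCorners(line), class = "octgraft_corner_error")
})

test_that("phantom corners are recovered within 3 px of the true arc endpoints", {
  ph <- generatePhantom(phantomSpec(seed = 2, speckleSigma = 0))
  em <- detectEdges(ph$image)
  b <- sampleBoundary(em, step = 10, select = "deepest")
  cs <- detectCorners(b, em)
  d <- abs(cornerPoints(cs) - cornerPoints(corners(ph$truth)))
  expect_lte(max(d), 3)
})

test_that("corner detection is equivariant to horizontal flips", {
  ph <- generatePhantom(phantomSpec(seed = 6, speckleSigma = 0.1))
  img <- ph$image
  W <- ncol(pixels(img))
  flipped <- octImage(pixels(img)[, W:1], calibration(img))
  getCorners <- function(im) {
    em <- detectEdges(im)
    detectCorners(sampleBoundary(em, 10, select = "deepest"), em)
  }
  cp <- cornerPoints(getCorners(img))
  cf <- cornerPoints(getCorners(flipped))
  # mirror: labels swap left/right, columns reflect about the image centre
  expect_equal(unname(cf["left_anterior", ]),
               unname(c(W + 1 - cp["right_anterior", 1], cp["right_anterior", 2])),
               tolerance = 1.5)
  expect_equal(unname(cf["right_posterior", ]),
               unname(c(W + 1 - cp["left_posterior", 1], cp["left_posterior", 2])),
               tolerance = 1.5)
})

test_that("the host-graft interface is recovered where contrast allows", {
  ph <- generatePhantom(phantomSpec(seed = 3, speckleSigma = 0, interfaceContrast = 0.5))
  em <- detectEdges(ph$image)
  b <- sampleBoundary(em, 10, select = "deepest")
  cs <- detectCorners(b, em)
  ant <- extractAnteriorInterface(ph$image, cs, b)
  ap <- boundaryPoints(ant)
  ok <- !is.na(ap[, 2])
  expect_gte(mean(ok), 0.9)
  err <- abs(ap[ok, 2] - truthCurveRow(ph$truth, "anterior", ap[ok, 1]))
  expect_gte(mean(err <= 2), 0.9)
})

test_that("zero interface contrast raises the low-contrast failure", {
  ph <- generatePhantom(phantomSpec(seed = 3, speckleSigma = 0, interfaceContrast = 0))
  em <- detectEdges(ph$image)
  b <- sampleBoundary(em, 10, select = "deepest")
  # corners cannot come from curvature here (no interface step); place them
  # on the known geometry to isolate the interface stage
  cs <- corners(ph$truth)
  expect_error(extractAnteriorInterface(ph$image, cs, b),
               class = "octgraft_lowcontrast_error")
})

test_that("a shifted-posterior interface recovers the constructed band thickness", {
  # graft band exactly k px thick everywhere: interface = posterior - k
  k <- 12
  spec <- phantomSpec(seed = 5, speckleSigma = 0,
                      graftCentralThickness = k, graftEdgeThickness = k)
  ph <- generatePhantom(spec)
  em <- detectEdges(ph$image)
  b <- sampleBoundary(em, 10, select = "deepest")
  cs <- detectCorners(b, em)
  ant <- extractAnteriorInterface(ph$image, cs, b)
  ap <- boundaryPoints(ant)
  ok <- !is.na(ap[, 2])
  p <- boundaryPoints(b)
  postRow <- approx(p[!is.na(p[, 2]), 1], p[!is.na(p[, 2]), 2], xout = ap[ok, 1])$y
  expect_equal(median(postRow - ap[ok, 2]), k, tolerance = 0.15)
})

test_that("curve fitting reproduces lines and arcs through the corners", {
  xs <- seq(20, 220, by = 10)
  pts <- cbind(xs, 100 + 0.2 * xs)
  c1 <- c(15, 100 + 0.2 * 15); c2 <- c(225, 100 + 0.2 * 225)
  post <- cbind(xs, 150 + 0.2 * xs)
  cs <- cornerSet(c1, c(15, 150 + 0.2 * 15), c2, c(225, 150 + 0.2 * 225))
  seg <- fitGraft(pts, post, cs)
  zz <- seq(15, 225, length.out = 101)
  expect_lt(max(abs(evalCurve(seg@anterior, zz) - (100 + 0.2 * zz))), 1e-6)

  # points on a circular arc plus exact corners: deviation < 0.5 px
  R <- 400; cx <- 120; cy <- 500
  arcRow <- function(x) cy - sqrt(R^2 - (x - cx)^2)
  ptsA <- cbind(xs, arcRow(xs))
  csA <- cornerSet(c(15, arcRow(15)), c(15, arcRow(15) + 40),
                   c(225, arcRow(225)), c(225, arcRow(225) + 40))
  segA <- fitGraft(ptsA, cbind(xs, arcRow(xs) + 40), csA)
  expect_lt(max(abs(evalCurve(segA@anterior, zz) - arcRow(zz))), 0.5)

  # posterior above anterior violates the thickness invariant
  expect_error(fitGraft(cbind(xs, 150 + 0 * xs), cbind(xs, 100 + 0 * xs),
                        cornerSet(c(15, 150), c(15, 151), c(225, 150), c(225, 151))),
               class = "octgraft_geometry_error")
  expect_error(fitGraft(pts, post,
                        cornerSet(c(15, 100), c(15, 150), c(20, 100), c(20, 150))),
               class = "octgraft_geometry_error")  # degenerate span
})

test_that("control-point edits re-interpolate and re-check invariants", {
  seg <- rectSegmentation(width = 200, thickness = 50, left = 20, top = 40)
  cal <- cal10

  # identity edit: geometry unchanged, mode flips to semi_automated
  s2 <- adjustControlPoints(seg, list())
  expect_identical(segMode(s2), "semi_automated")
  expect_equal(s2@posterior@controlPoints, seg@posterior@controlPoints)

  # moving one posterior control point down increases the area by the
  # quadrature of the induced spline bump (independent numeric oracle)
  d <- 8
  cp <- seg@posterior@controlPoints
  i <- 3
  s3 <- adjustControlPoints(seg, list(list(curve = "posterior", index = i,
                                           point = cp[i, ] + c(0, d))))
  a0 <- areaUm2(computeArea(seg, cal))
  a1 <- areaUm2(computeArea(s3, cal))
  expect_gt(a1, a0)
  f0 <- splinefun(cp[, 1], cp[, 2], method = "natural")
  cpNew <- cp; cpNew[i, 2] <- cp[i, 2] + d
  f1 <- splinefun(cpNew[, 1], cpNew[, 2], method = "natural")
  bump <- integrate(function(x) f1(x) - f0(x), min(cp[, 1]), max(cp[, 1]),
                    subdivisions = 500)$value
  expect_equal(a1 - a0, bump * 100, tolerance = 0.01 * abs(bump * 100))

  # edits that break the contract are rejected with the invariant named
  expect_error(adjustControlPoints(seg, list(list(curve = "posterior", index = 2,
                                                  point = c(500, 95))),
                                   imageSize = c(384, 512)),
               "single-valuedness", class = "octgraft_edit_error")
  expect_error(adjustControlPoints(seg, list(list(curve = "posterior", index = 2,
                                                  point = c(70, 10))) ),
               class = "octgraft_edit_error")      # negative thickness
  expect_error(adjustControlPoints(seg, list(list(curve = "anterior", index = 1,
                                                  point = c(-10, 40))),
                                   imageSize = c(384, 512)),
               "outside the image", class = "octgraft_edit_error")
})

test_that("automated segmentation recovers phantom area within tolerance", {
  spec <- phantomSpec(seed = 8, speckleSigma = 0)
  ph <- generatePhantom(spec)
  seg <- segmentAutomated(ph$image)
  expect_identical(segMode(seg), "automated")
  a <- areaUm2(computeArea(seg, calibration(spec)))
  expect_lt(abs(a - truthAreaUm2(ph$truth)) / truthAreaUm2(ph$truth), 0.02)
})

test_that("a blank image fails the pipeline with a stage-tagged error", {
  blank <- octImage(matrix(0.5, 128, 128), calibrationSpec())
  err <- tryCatch(segmentAutomated(blank), octgraft_error = function(e) e)
  expect_s3_class(err, "octgraft_error")
  expect_match(conditionMessage(err), "stage '")
})

test_that("thickness is non-negative at every column of accepted segmentations", {
  for (seed in c(4, 14)) {
    ph <- generatePhantom(randomPhantomSpec(seed, speckleSigma = 0.15))
    seg <- segmentAutomated(ph$image)
    prof <- thicknessProfile(seg, calibration(ph$image), nSamples = 257)
    expect_true(all(prof$thickness_um >= 0))
  }
})

test_that("snapping control points onto truth recovers the area within 1%", {
  # the refinement API is sufficient to correct any automated error
  for (seed in c(5, 15)) {
    ph <- generatePhantom(randomPhantomSpec(seed, speckleSigma = 0.15))
    seg <- segmentAutomated(ph$image)
    segS <- snapSegmentationToTruth(seg, ph$truth)
    expect_identical(segMode(segS), "semi_automated")
    a <- areaUm2(computeArea(segS, calibration(ph$image)))
    expect_lt(abs(a - truthAreaUm2(ph$truth)) / truthAreaUm2(ph$truth), 0.01)
  }
})
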