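test_that("a 200 x 50 px rectangle at 10 x 10 um/px measures 1,000,000 um^2", {
  seg <- rectSegmentation(width = 200, thickness = 50)
  expect_equal(areaUm2(computeArea(seg, cal10)), 1e6, tolerance = 1e-9)
})

test_that("truth-snapped segmentations match the analytic lens area to 0.1%", {
  ph <- generatePhantom(phantomSpec(seed = 4, speckleSigma = 0))
  seg <- segmentAutomated(ph$image)
  segS <- snapSegmentationToTruth(seg, ph$truth)
  a <- areaUm2(computeArea(segS, calibration(ph$image)))
  expect_lt(abs(a - truthAreaUm2(ph$truth)) / truthAreaUm2(ph$truth), 1e-3)
})

test_that("shoelace area agrees with brute-force pixel rasterisation", {
  # independent oracle: count pixel centres inside the truth region
  for (seed in c(1, 11, 21, 31, 41)) {
    spec <- randomPhantomSpec(seed, speckleSigma = 0)
    tr <- generatePhantom(spec)$truth
    x1 <- tr@corners@points["left_anterior", 1]
    x2 <- tr@corners@points["right_anterior", 1]
    rastPx <- rasterAreaPx2(function(z) truthCurveRow(tr, "anterior", z),
                            function(z) truthCurveRow(tr, "posterior", z),
                            x1, x2)
    cal <- calibration(spec)
    expect_lt(abs(rastPx * cal@lateral * cal@axial - truthAreaUm2(tr)) /
                truthAreaUm2(tr), 0.005)
  }
})

test_that("thickness profiles have the stated units, shape and integral", {
  # uniform 50 px band at 10 um/px axial -> constant 500 um
  seg <- rectSegmentation(width = 200, thickness = 50)
  prof <- thicknessProfile(seg, cal10, nSamples = 51)
  expect_equal(unique(round(prof$thickness_um, 9)), 500)
  expect_true(all(diff(prof$lateral_um) > 0))
  expect_error(thicknessProfile(seg, cal10, nSamples = 1),
               class = "octgraft_parameter_error")

  # lens phantom: thickness peaks at the apex column
  ph <- generatePhantom(phantomSpec(seed = 2, speckleSigma = 0))
  segT <- snapSegmentationToTruth(segmentAutomated(ph$image), ph$truth)
  profT <- thicknessProfile(segT, calibration(ph$image), nSamples = 201)
  apexAt <- profT$lateral_um[which.max(profT$thickness_um)]
  expect_lt(abs(apexAt - max(profT$lateral_um) / 2), 0.2 * max(profT$lateral_um))

  # trapezoidal integral of the profile reproduces the area within 1%
  a <- areaUm2(computeArea(segT, calibration(ph$image)))
  integ <- pracma::trapz(profT$lateral_um, profT$thickness_um)
  expect_lt(abs(integ - a) / a, 0.01)
})

test_that("area is invariant under horizontal flips of the segmentation", {
  ph <- generatePhantom(randomPhantomSpec(3, speckleSigma = 0))
  seg <- snapSegmentationToTruth(segmentAutomated(ph$image), ph$truth)
  W <- ncol(pixels(ph$image))
  flip <- function(curve) {
    p <- curve@controlPoints
    graftCurve(cbind(rev(W + 1 - p[, 1]), rev(p[, 2])))
  }
  cp <- cornerPoints(corners(seg))
  m <- function(l) c(W + 1 - cp[l, 1], cp[l, 2])
  segF <- new("GraftSegmentation", anterior = flip(seg@anterior),
              posterior = flip(seg@posterior),
              corners = cornerSet(m("right_anterior"), m("right_posterior"),
                                  m("left_anterior"), m("left_posterior")),
              mode = seg@mode, imageId = "flip")
  expect_equal(areaUm2(computeArea(segF, cal10)),
               areaUm2(computeArea(seg, cal10)), tolerance = 1e-9)
})

test_that("areas and thicknesses follow the dimensional scaling law", {
  seg <- rectSegmentation(width = 150, thickness = 30)
  a1 <- areaUm2(computeArea(seg, calibrationSpec(10, 12)))
  a2 <- areaUm2(computeArea(seg, calibrationSpec(20, 24)))
  expect_equal(a2, 4 * a1, tolerance = 1e-12)
  t1 <- thicknessProfile(seg, calibrationSpec(10, 12), 11)$thickness_um
  t2 <- thicknessProfile(seg, calibrationSpec(10, 24), 11)$thickness_um
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("volume estimates reproduce the printed mixed-unit convention", {
  expect_equal(estimateVolume(20000, 8.5)$value, 170000)
  expect_equal(estimateVolume(0, 8.5)$value, 0)
  a <- 123456.7
  expect_equal(estimateVolume(a, 1)$value, a)
  expect_equal(estimateVolume(20000, 8.5, consistentUnits = TRUE)$value, 1.7e8)
  expect_error(estimateVolume(20000, 0), class = "octgraft_parameter_error")
  expect_error(estimateVolume(20000, -2), class = "octgraft_parameter_error")
})
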