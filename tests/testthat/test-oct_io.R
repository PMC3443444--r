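test_that("image loading rescales by the bit-depth maximum", {
  cal <- calibrationSpec(18, 18)
  f8 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 40, 40), f8)              # all pixels at 8-bit max
  img <- loadImage(f8, cal)
  expect_true(all(pixels(img) == 1))

  f0 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 40, 40), f0, bits.per.sample = 16)
  img0 <- loadImage(f0, cal)
  expect_true(all(pixels(img0) == 0))
})

test_that("colour images are rejected naming the channel count", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(40, 40, 3)), f)
  expect_error(loadImage(f, calibrationSpec()), "3 channels",
               class = "octgraft_format_error")
  expect_error(loadImage("no/such/file.png", calibrationSpec()),
               class = "octgraft_io_error")
})

test_that("a saved phantom image loads back pixel-identically", {
  ph <- generatePhantom(phantomSpec(seed = 11))
  img <- quantiseImage(ph$image)
  f <- withr::local_tempfile(fileext = ".png")
  saveImage(img, f)
  back <- loadImage(f, calibration(img))
  expect_identical(dim(pixels(back)), dim(pixels(img)))
  expect_equal(max(abs(pixels(back) - pixels(img))), 0)
})

test_that("an OCTImage always carries an explicit calibration", {
  expect_error(octImage(matrix(0.5, 40, 40)), class = "octgraft_parameter_error")
  expect_error(computeArea(rectSegmentation()), class = "octgraft_parameter_error")
})

test_that("segmentation records round-trip losslessly through JSON", {
  seg <- rectSegmentation()
  f <- withr::local_tempfile(fileext = ".json")
  saveSegmentation(seg, f)
  back <- loadSegmentation(f)
  expect_equal(back@anterior@controlPoints, seg@anterior@controlPoints)
  expect_equal(back@posterior@controlPoints, seg@posterior@controlPoints)
  expect_equal(cornerPoints(corners(back)), cornerPoints(corners(seg)))
  expect_identical(segMode(back), segMode(seg))
  expect_identical(imageId(back), imageId(seg))

  # property: random 20-control-point segmentations survive with full precision
  for (seed in 1:5) {
    withr::with_seed(seed, {
      xs <- 10 + cumsum(runif(20, 8, 22))
      top <- 50 + cumsum(rnorm(20, 0, 0.3))
      thick <- runif(20, 20, 30)
      ant <- graftCurve(cbind(xs, top))
      post <- graftCurve(cbind(xs, top + thick))
      cs <- cornerSet(cbind(xs[1], top[1]), cbind(xs[1], top[1] + thick[1]),
                      cbind(xs[20], top[20]), cbind(xs[20], top[20] + thick[20]))
      seg <- new("GraftSegmentation", anterior = ant, posterior = post,
                 corners = cs, mode = "semi_automated", imageId = "prop")
    })
    f2 <- withr::local_tempfile(fileext = ".json")
    saveSegmentation(seg, f2)
    back <- loadSegmentation(f2)
    expect_equal(back@anterior@controlPoints, seg@anterior@controlPoints,
                 tolerance = 1e-12)
    expect_equal(back@posterior@controlPoints, seg@posterior@controlPoints,
                 tolerance = 1e-12)
  }
})

test_that("malformed or incomplete segmentation files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"image_id": "x", "mode": "automated", "anterior": [], "posterior": []}', f)
  expect_error(loadSegmentation(f), "corners", class = "octgraft_parse_error")
  writeLines('{not valid json', f)
  expect_error(loadSegmentation(f), class = "octgraft_parse_error")
})

test_that("configuration validates and rejects unknown keys", {
  cfg <- octConfig(sampling = list(step = 5), canny = list(sigma = 3))
  expect_equal(cfg$sampling$step, 5)
  expect_equal(cfg$canny$sigma, 3)
  expect_equal(cfg$sampling$select, "deepest")
  expect_error(octConfig(nonsense = list(a = 1)), class = "octgraft_parameter_error")
  expect_error(octConfig(canny = list(bogus_key = 1)), class = "octgraft_parameter_error")
  expect_error(octConfig(canny = list(low_q = 0.99, high_q = 0.5)),
               class = "octgraft_parameter_error")

  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"sampling": {"step": 4}}', f)
  expect_equal(readConfig(f)$sampling$step, 4)
})
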