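test_that("identical arms give a degenerate-exact agreement report", {
  s <- measurementSeries(c(10, 20, 30, 40), c(10, 20, 30, 40), c("M1", "M2"))
  rep <- agreementReport(s)
  expect_equal(rep@bias, 0)
  expect_equal(rep@sdDiff, 0)
  expect_equal(c(rep@loaLower, rep@loaUpper), c(0, 0))
  expect_equal(rep@icc, 1)
  expect_equal(rep@r, 1)
  expect_equal(rep@tStat, 0)
  expect_true(is.na(rep@pValue))     # p undefined, flagged
})

test_that("Bland-Altman reproduces the hand formulas", {
  # differences {-1, 0, 1}: bias 0, sd 1, LoA (-1.96, 1.96)
  s <- measurementSeries(c(5, 6, 7), c(6, 6, 6))
  ba <- blandAltman(s)
  expect_equal(ba@bias, 0)
  expect_equal(ba@sdDiff, 1)
  expect_equal(c(ba@loaLower, ba@loaUpper), c(-1.96, 1.96))
  tq <- qt(0.975, 2)
  expect_equal(ba@biasCi, c(-1, 1) * tq / sqrt(3))
  expect_equal(ba@loaUpperCi, 1.96 + c(-1, 1) * tq * sqrt(3 / 3))
  expect_error(blandAltman(measurementSeries(1:2, 2:1)),
               class = "octgraft_sample_size_error")
})

test_that("limits of agreement are symmetric about the bias", {
  # loa_lower = 2 * bias - loa_upper, checked over random series
  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- rnorm(30, 150000, 40000); b <- a + rnorm(30, -500, 9000)
    })
    ba <- blandAltman(measurementSeries(a, b))
    expect_equal(ba@loaLower, 2 * ba@bias - ba@loaUpper, tolerance = 1e-12)
  }
})

test_that("swapping the arms mirrors the Bland-Altman signs", {
  withr::with_seed(42, {
    a <- rnorm(25, 150000, 40000); b <- a + rnorm(25, 2000, 8000)
  })
  f <- blandAltman(measurementSeries(a, b))
  g <- blandAltman(measurementSeries(b, a))
  expect_equal(g@bias, -f@bias)
  expect_equal(g@loaLower, -f@loaUpper)
  expect_equal(g@loaUpperCi, -rev(f@loaLowerCi))
})

test_that("two-way ICC matches an independent ANOVA decomposition", {
  # 6-pair toy table; oracle mean squares from stats::aov, ICC by the
  # textbook formulas
  a <- c(9, 6, 8, 7, 10, 6); b <- c(2, 1, 4, 1, 5, 2)
  s <- measurementSeries(a, b)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(1:6, 2)),
                   meth = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + meth, df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 6; k <- 2
  expect_equal(iccTwoWay(s, "agreement")$icc,
               (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE)),
               tolerance = 1e-12)
  expect_equal(iccTwoWay(s, "consistency")$icc,
               (MSR - MSE) / (MSR + (k - 1) * MSE), tolerance = 1e-12)
})

test_that("a constant offset lowers absolute agreement but not consistency", {
  a <- c(10, 14, 18, 26, 30)
  s <- measurementSeries(a, a + 6)
  expect_lt(iccTwoWay(s, "agreement")$icc, 1)
  expect_equal(iccTwoWay(s, "consistency")$icc, 1)
  expect_equal(pearsonR(s), 1)
  expect_error(iccTwoWay(measurementSeries(rep(3, 4), rep(3, 4))),
               class = "octgraft_degenerate_error")
})

test_that("ICC confidence intervals bracket the estimate and behave sanely", {
  withr::with_seed(7, {
    truth <- rnorm(40, 150000, 40000)
    s <- measurementSeries(truth + rnorm(40, 0, 8000), truth + rnorm(40, 0, 8000))
  })
  res <- iccTwoWay(s)
  expect_true(res$ci[1] < res$icc && res$icc < res$ci[2])
  expect_true(all(res$ci >= -1 & res$ci <= 1))
})

test_that("Pearson r and the paired t follow their definitions", {
  expect_equal(pearsonR(measurementSeries(1:5, (1:5) + 3)), 1)
  tt <- pairedT(measurementSeries(c(5, 6, 7), c(6, 6, 6)))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  # 5-pair toy against the textbook computation
  a <- c(12, 15, 11, 18, 14); b <- c(10, 14, 13, 15, 11)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(5))
  tt2 <- pairedT(measurementSeries(a, b))
  expect_equal(tt2$t, tHand, tolerance = 1e-12)
  expect_equal(tt2$p, 2 * pt(-abs(tHand), 4), tolerance = 1e-12)
  rHand <- sum(scale(a) * scale(b)) / 4
  expect_equal(pearsonR(measurementSeries(a, b)), rHand, tolerance = 1e-12)
  expect_error(pearsonR(measurementSeries(c(1, 1, 1), c(1, 2, 3))),
               class = "octgraft_degenerate_error")
})

test_that("simulated observers recover their noise level", {
  # two observers reading the same objects with independent N(0, sigma)
  # noise: bias ~ 0 and sd of differences -> sigma * sqrt(2)
  sigma <- 5000; n <- 200
  withr::with_seed(11, {
    truth <- rnorm(n, 150000, 40000)
    s <- measurementSeries(truth + rnorm(n, 0, sigma),
                           truth + rnorm(n, 0, sigma),
                           c("obs1", "obs2"))
  })
  ba <- blandAltman(s)
  expect_lt(abs(ba@bias), 3 * sigma / sqrt(n))
  expect_lt(abs(ba@sdDiff - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.1)
})

test_that("agreement tables mirror the published layout and round-trip as CSV", {
  withr::with_seed(3, {
    truth <- rnorm(30, 150000, 40000)
    s1 <- measurementSeries(truth + rnorm(30, 0, 5000),
                            truth + rnorm(30, 0, 5000), c("M1", "M2"))
  })
  s2 <- measurementSeries(truth, truth, c("B1", "B1bis"))
  tab <- agreementTable(list(s1, s2))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("mean_a", "sd_a", "p_value", "r", "icc", "bias",
                    "loa_upper", "loa_lower") %in% names(tab)))
  expect_equal(tab$loa_lower, 2 * tab$bias - tab$loa_upper, tolerance = 1e-9)
  # identical arms row: flagged p, exact agreement statistics
  expect_true(is.na(tab$p_value[2]))
  expect_equal(tab$r[2], 1)
  expect_equal(tab$icc[2], 1)
  expect_equal(c(tab$loa_lower[2], tab$loa_upper[2]), c(0, 0))

  f <- withr::local_tempfile(fileext = ".csv")
  writeMeasurementCsv(tab, f)
  back <- read.csv(f)
  expect_equal(back$bias, tab$bias, tolerance = 1e-9)
  expect_equal(back$arm_a, tab$arm_a)
})
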