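test_that("threshold resolution in absolute and fraction-of-max modes", {
  expect_identical(computeThreshold("fraction_of_max", 0.4, iReference = 250),
                   100)
  expect_identical(computeThreshold("fraction_of_max", 1.0, iReference = 187),
                   187)
  expect_identical(computeThreshold("absolute", 100), 100)
  expect_error(computeThreshold("fraction_of_max", 1.5, iReference = 250),
               "\\(0, 1\\]")
  expect_error(computeThreshold("fraction_of_max", 0.4), "iReference")
  expect_error(computeThreshold("absolute", 300, bitMax = 250), "\\[0, 250\\]")
  expect_error(computeThreshold("absolute", -1), "\\[0, 250\\]")
})

test_that("BAF on constructed ROIs: uniform, checkerboard, boundary", {
  n <- 20
  roi <- matrix(TRUE, n, n)
  bright <- ChannelImage(matrix(150, n, n), "calcein", 1)
  expect_equal(baf(binaryAreaFraction(bright, roi, 100)), 1)

  chk <- matrix(rep_len(c(40, 160), n * n), n, n)
  sig <- binaryAreaFraction(ChannelImage(chk, "calcein", 1), roi, 100)
  expect_equal(baf(sig), 0.5)
  expect_equal(roiArea(sig), n * n)
  expect_equal(binaryArea(sig), n * n / 2)
  expect_equal(iMax(sig), 160)

  # strict inequality: pixels exactly at the threshold are excluded
  flat <- ChannelImage(matrix(100, n, n), "calcein", 1)
  expect_equal(baf(binaryAreaFraction(flat, roi, 100)), 0)

  expect_error(binaryAreaFraction(bright, matrix(FALSE, n, n), 100), "empty")
})

test_that("BAF equals brute-force per-pixel counting on random ROIs", {
  set.seed(7)
  for (i in 1:5) {
    px <- matrix(sample(0:250, 40 * 40, TRUE), 40, 40)
    roi <- matrix(runif(40 * 40) < 0.6, 40, 40)
    roi[1] <- TRUE  # never empty
    thr <- runif(1, 0, 250)
    img <- ChannelImage(px, "calcein", 1.3)
    sig <- binaryAreaFraction(img, roi, thr)
    # independent loop over pixels
    num <- 0; den <- 0; mx <- -Inf
    for (r in 1:40) for (c in 1:40) if (roi[r, c]) {
      den <- den + 1
      if (px[r, c] > thr) num <- num + 1
      mx <- max(mx, px[r, c])
    }
    expect_equal(baf(sig), num / den)
    expect_equal(binaryArea(sig), num * 1.3^2)
    expect_equal(iMax(sig), mx)
  }
})

test_that("BAF is monotone non-increasing in the threshold", {
  set.seed(8)
  px <- matrix(sample(0:250, 900, TRUE), 30, 30)
  img <- ChannelImage(px, "calcein", 1)
  roi <- matrix(TRUE, 30, 30)
  bafs <- vapply(seq(0, 250, by = 10),
                 function(t) baf(binaryAreaFraction(img, roi, t)), numeric(1))
  expect_true(all(diff(bafs) <= 0))
})

test_that("BAF is invariant under joint monotone intensity transforms", {
  set.seed(9)
  px <- matrix(sample(0:200, 625, TRUE), 25, 25)
  roi <- matrix(runif(625) < 0.7, 25, 25); roi[1] <- TRUE
  thr <- 90
  g <- function(x) 1.7 * x^1.3 + 5  # strictly increasing
  b1 <- baf(binaryAreaFraction(ChannelImage(px, "calcein", 1), roi, thr))
  b2 <- baf(binaryAreaFraction(
    ChannelImage(g(px), "calcein", 1, bitMax = g(250)), roi, g(thr)))
  expect_equal(b1, b2)
})

test_that("measured BAF matches ground truth on a noise-free rendered disk", {
  p <- noiseFree(scenePreset("baf", nSpheroids = 1, trueDiameterMean = 300,
                             intensityProfileKnee = sqrt(0.5), seed = 5),
                 sd = 0)
  sc <- generateScene(p, rowLayout(1))
  cal <- sc$images$calcein
  # oracle ROI: the exact rendered disk (pixel centers within the radius)
  ps <- pixelSize(cal)
  ctr <- wellCenters(rowLayout(1))[1, ] / ps
  nr <- nrow(pixels(cal)); nc <- ncol(pixels(cal))
  roi <- outer(0:(nr - 1), 0:(nc - 1), function(y, x)
    (x - ctr[1])^2 + (y - ctr[2])^2 <= (150 / ps)^2)
  sig <- binaryAreaFraction(cal, roi, 100)
  expect_lt(abs(baf(sig) - 0.5), 0.01)
})
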