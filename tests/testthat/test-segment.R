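mkImage <- function(px, channel = "brightfield", ps = 1)
  ChannelImage(px, channel, ps, bitMax = 250)

test_that("uniform images yield no detections", {
  flat <- mkImage(matrix(200, 120, 120))
  expect_length(segmentBrightfield(flat), 0)
  zero <- mkImage(matrix(0, 120, 120), "calcein")
  expect_length(segmentCalcein(zero), 0)
})

test_that("a dark disk is recovered with its analytic area", {
  n <- 256
  disk <- diskMask(n, 100)
  px <- matrix(200, n, n); px[disk] <- 80
  masks <- segmentBrightfield(mkImage(px))
  expect_length(masks, 1)
  expect_lt(abs(sum(masks[[1]]) - pi * 100^2) / (pi * 100^2), 0.03)
})

test_that("objects below the size filter are discarded", {
  n <- 256
  px <- matrix(200, n, n)
  px[diskMask(n, 80)] <- 80
  px[diskMask(n, 10, cx = 220, cy = 220)] <- 80  # area ~314 um^2 at 1 um/px
  masks <- segmentBrightfield(mkImage(px))  # default filter: 50 um disk
  expect_length(masks, 1)
  expect_gt(sum(masks[[1]]), 15000)
})

test_that("calcein segmentation excludes the dead rim", {
  p <- noiseFree(dxrPreset("OS", 10, nSpheroids = 1, seed = 9), sd = 0)
  sc <- generateScene(p, rowLayout(1))
  masks <- segmentCalcein(sc$images$calcein)
  expect_length(masks, 1)
  f <- feretDiameters(masks[[1]], pixelSize(sc$images$calcein))
  dMean <- meanDiameter(f["dMin"], f["dMax"])
  expect_lt(abs(dMean - sc$truth$true_viable_diameter) /
              sc$truth$true_viable_diameter, 0.03)
  # far from the full (brightfield) diameter
  expect_lt(dMean, 0.7 * sc$truth$true_diameter)
})

test_that("detached satellite aggregates are filtered by size", {
  p <- noiseFree(dxrPreset("CS", 0, nSpheroids = 3, seed = 10), sd = 0)
  p@satellites <- TRUE
  sc <- generateScene(p, rowLayout(3))
  # satellite diameter is 15% of the spheroid (~49 um); a filter above its
  # area keeps exactly one mask per well
  masks <- segmentCalcein(sc$images$calcein, minArea = pi * 30^2)
  expect_length(masks, 3)
  # with a permissive filter the satellites appear as extra components
  expect_gt(length(segmentCalcein(sc$images$calcein, minArea = 100)), 3)
})

test_that("segmentation tolerates a global intensity shift", {
  p <- noiseFree(dxrPreset("CS", 0, nSpheroids = 2, seed = 12))
  sc <- generateScene(p, rowLayout(2))
  bf <- sc$images$brightfield
  shifted <- ChannelImage(pmin(pixels(bf) + 20, 250), "brightfield",
                          pixelSize(bf), bitMax(bf))
  m1 <- segmentBrightfield(bf)
  m2 <- segmentBrightfield(shifted)
  expect_equal(length(m1), length(m2))
  u1 <- Reduce(`|`, m1); u2 <- Reduce(`|`, m2)
  expect_lt(sum(xor(u1, u2)) / length(u1), 0.01)
})

test_that("masks are assigned to their nearest wells", {
  lay <- rowLayout(3)
  ps <- 2
  ctr <- wellCenters(lay) / ps
  n <- ceiling((max(ctr[, 1]) + 150) / 1)
  blank <- matrix(FALSE, 400, n)
  mk <- function(cx, r) {
    m <- blank
    idx <- which(outer(0:(nrow(m) - 1), 0:(ncol(m) - 1), function(y, x)
      (x - cx)^2 + (y - ctr[1, 2])^2 <= r^2))
    m[idx] <- TRUE
    m
  }
  masks <- list(mk(ctr[1, 1], 60), mk(ctr[2, 1], 55), mk(ctr[3, 1], 50))
  asg <- assignWells(masks, lay, ps)
  expect_length(asg$detections, 3)
  expect_identical(vapply(asg$detections, wellId, integer(1)), 1:3)
  expect_length(asg$missingWells, 0)

  # no masks at all: everything is missing
  asg0 <- suppressWarnings(assignWells(list(), lay, ps))
  expect_length(asg0$detections, 0)
  expect_identical(asg0$missingWells, 1:3)

  # two masks near one well: largest kept, duplicate flagged
  masks2 <- c(masks, list(mk(ctr[2, 1] + 40, 20)))
  asg2 <- suppressWarnings(assignWells(masks2, lay, ps))
  expect_length(asg2$detections, 3)
  expect_identical(asg2$duplicateWells, 2L)
  kept <- asg2$detections[[2]]
  expect_equal(sum(bfMask(kept)), sum(masks[[2]]))  # the big one survived
})
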