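test_that("scene generation is deterministic for a fixed preset and seed", {
  lay <- rowLayout(2)
  p <- scenePreset("det", nSpheroids = 2, seed = 7)
  s1 <- generateScene(p, lay)
  s2 <- generateScene(p, lay)
  expect_identical(lapply(s1$images, pixels), lapply(s2$images, pixels))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the raster
  s3 <- generateScene(p, lay, seed = 8)
  expect_false(identical(pixels(s1$images$calcein), pixels(s3$images$calcein)))
})

test_that("degenerate preset reproduces the nominal diameter exactly", {
  p <- noiseFree(scenePreset("exact", nSpheroids = 3, trueDiameterMean = 300,
                             deadRimFraction = 0, seed = 2), sd = 0)
  sc <- generateScene(p, rowLayout(3))
  expect_identical(sc$truth$true_diameter, rep(300, 3))
  expect_identical(sc$truth$true_viable_diameter, rep(300, 3))
})

test_that("the profile knee controls the true and rendered BAF", {
  p <- noiseFree(scenePreset("knee", nSpheroids = 1, trueDiameterMean = 300,
                             intensityProfileKnee = sqrt(0.5), seed = 5),
                 sd = 0)
  sc <- generateScene(p, rowLayout(1))
  expect_equal(sc$truth$true_baf, 0.5)
  # brute-force pixel count on the rendered raster over the exact disk
  cal <- pixels(sc$images$calcein)
  ps <- pixelSize(sc$images$calcein)
  ctr <- wellCenters(rowLayout(1))[1, ] / ps
  inDisk <- outer(0:(nrow(cal) - 1), 0:(ncol(cal) - 1), function(y, x)
    (x - ctr[1])^2 + (y - ctr[2])^2 <= (150 / ps)^2)
  frac <- sum(cal[inDisk] > 100) / sum(inDisk)
  expect_lt(abs(frac - 0.5), 0.01)  # ~214 px disk: rasterization only
})

test_that("ground truth is self-consistent with the scoring equations", {
  sc <- generateScene(dxrPreset("OS", 10, nSpheroids = 5, seed = 13),
                      rowLayout(5))
  with(sc$truth, {
    expect_true(all(true_viable_diameter <= true_diameter))
    expect_equal(true_imvis, (pi / 6) * true_viable_diameter^3 * true_baf)
  })
})

test_that("stronger read noise moves the render further from noise-free", {
  lay <- rowLayout(1)
  base <- noiseFree(scenePreset("nf", nSpheroids = 1, seed = 3), sd = 0)
  ref <- pixels(generateScene(base, lay)$images$calcein)
  mads <- vapply(c(1, 4, 12), function(s) {
    p <- base; p@gaussianNoiseSd <- s
    mean(abs(pixels(generateScene(p, lay)$images$calcein) - ref))
  }, numeric(1))
  expect_true(all(diff(mads) > 0))
})

test_that("dose presets carry the calibrated phenotypes", {
  expect_equal(dxrPreset("CS", 0)@trueDiameterMean, 327)
  expect_equal(dxrPreset("OS", 0)@trueDiameterMean, 285)
  # 10 uM: group-mean true IMVIS falls to a quarter of untreated, both types
  for (ct in c("OS", "CS")) {
    ratio <- presetTrueImvis(dxrPreset(ct, 10)) /
      presetTrueImvis(dxrPreset(ct, 0))
    expect_equal(ratio, 0.25, tolerance = 1e-10)
  }
  # OS keeps its BAF but grows a dead rim; CS loses intensity instead
  expect_equal(dxrPreset("OS", 10)@intensityProfileKnee,
               dxrPreset("OS", 0)@intensityProfileKnee)
  expect_gt(dxrPreset("OS", 10)@deadRimFraction, 0.3)
  expect_equal(dxrPreset("CS", 10)@deadRimFraction, 0)
  expect_lt(dxrPreset("CS", 10)@coreIntensity,
            dxrPreset("CS", 0)@coreIntensity)
  # off-grid doses interpolate; beyond 10 uM the phenotype saturates
  expect_true(dxrPreset("CS", 7.5)@coreIntensity <
                dxrPreset("CS", 5)@coreIntensity)
  expect_equal(dxrPreset("CS", 20)@intensityProfileKnee,
               dxrPreset("CS", 10)@intensityProfileKnee)
  expect_error(dxrPreset("OS", -1), "non-negative")
})

test_that("invalid presets and overfull layouts are rejected", {
  expect_error(scenePreset(deadRimFraction = 1.2), "deadRimFraction")
  expect_error(scenePreset(intensityProfileKnee = 0), "intensityProfileKnee")
  expect_error(scenePreset(looseningFactor = 0.5), "looseningFactor")
  expect_error(generateScene(scenePreset(nSpheroids = 5), rowLayout(3)),
               "5 spheroids")
})
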