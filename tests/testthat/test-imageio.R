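test_that("multichannel TIFF round trip is pixel-identical", {
  sc <- generateScene(scenePreset("io", nSpheroids = 2, seed = 19),
                      rowLayout(2))
  tf <- tempfile(fileext = ".tif")
  writeImageSet(sc$images, tf)
  back <- readImageSet(tf)
  expect_length(back, 3)
  expect_identical(names(back), c("brightfield", "calcein", "hoechst"))
  for (ch in names(back)) {
    expect_identical(pixels(back[[ch]]), pixels(sc$images[[ch]]))
    expect_equal(pixelSize(back[[ch]]), pixelSize(sc$images[[ch]]))
    expect_equal(bitMax(back[[ch]]), 250)
  }
})

test_that("bare single-page TIFFs use overrides and dtype inference", {
  px <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  tf <- tempfile(fileext = ".tif")
  tiff::writeTIFF(px / 255, tf, bits.per.sample = 8)
  imgs <- readImageSet(tf, pixelSize = 1.0)
  expect_length(imgs, 1)
  expect_equal(bitMax(imgs[[1]]), 255)  # inferred from 8-bit dtype
  expect_identical(channelName(imgs[[1]]), "brightfield")  # page-order dialect
  expect_identical(pixels(imgs[[1]]), matrix(as.numeric(px), 64, 64))

  # calibration must come from somewhere
  expect_error(readImageSet(tf), "pixel_size")
  expect_error(readImageSet(tempfile(fileext = ".tif")), "cannot read")
})

test_that("per-spheroid records serialize to a stable CSV", {
  rec <- data.frame(
    spheroid_id = sprintf("sph%02d", 1:20), cell_type = "CS", dose = 10,
    timepoint = 48, D_min = runif(20, 250, 300), D_max = runif(20, 300, 350),
    D_mean = 300, V = sphereVolume(300), roi_area = 7e4, binary_area = 3.5e4,
    BAF = 0.5, I_max = 163, IMVIS = sphereVolume(300) / 2,
    stringsAsFactors = FALSE
  )
  tf <- tempfile(fileext = ".csv")
  writeResults(rec, tf)
  lines <- readLines(tf)
  expect_length(lines, 21)  # header + one row per spheroid (20-well device)
  expect_match(lines[1], "^spheroid_id,cell_type,dose,timepoint,D_min,D_max")
  back <- readResults(tf)
  expect_equal(back$D_min, rec$D_min, tolerance = 1e-12)
  expect_equal(back$IMVIS, rec$IMVIS, tolerance = 1e-12)
  expect_identical(back$spheroid_id, rec$spheroid_id)

  expect_error(writeResults(rec[0, ], tf), "non-empty")
  expect_error(writeResults(rec[, -5], tf), "D_min")

  # single record: header + 1 row
  writeResults(rec[1, ], tf)
  expect_length(readLines(tf), 2)
})

test_that("ground-truth sidecars round trip through JSON", {
  sc <- generateScene(scenePreset("gt", nSpheroids = 2, seed = 23),
                      rowLayout(2))
  tf <- tempfile(fileext = ".json")
  writeGroundTruth(sc$truth, tf)
  back <- readGroundTruth(tf)
  expect_equal(back$true_imvis, sc$truth$true_imvis)
})

test_that("condition tables validate their invariants", {
  ct <- conditionTable(sprintf("s%d", 1:6), rep(c("OS", "CS"), 3),
                       rep(c(0, 5, 10), 2))
  expect_equal(nrow(ct), 6)
  expect_error(conditionTable(c("a", "a"), "OS", 0), "unique")
  expect_error(conditionTable("a", "OS", -2), "dose")
})

test_that("device layouts enforce their geometry", {
  lay <- defaultLayout()
  expect_equal(totalWells(lay), 20)
  expect_equal(lay@wellsPerChamber, 10L)
  expect_equal(nrow(wellCenters(lay)), 20)
  expect_gt(min(dist(wellCenters(lay))), lay@wellWidth)
  # overlapping wells are rejected
  expect_error(deviceLayout(1, 2, wellWidth = 500, pitch = 400), "overlap")
})

test_that("pipeline configuration merges user keys over defaults", {
  cfg0 <- readPipelineConfig()
  expect_equal(cfg0$threshold_value, 100)
  expect_identical(cfg0$threshold_mode, "absolute")
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("pixel_size: 0.9", "threshold_value: 80"), tf)
  cfg <- readPipelineConfig(tf)
  expect_equal(cfg$pixel_size, 0.9)
  expect_equal(cfg$threshold_value, 80)
  expect_identical(cfg$reference, "bit_max")
})
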