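#' @import methods
NULL

.CHANNELS <- c("brightfield", "calcein", "hoechst")

#' Calibrated single-channel microscopy image
#'
#' One 2D intensity raster for one channel of one field of view, on the
#' detector's relative-fluorescence-unit (RFU) scale. Pixel coordinates are
#' 0-based, row-major, and refer to pixel centers; physical position in
#' micrometres is index times \code{pixelSize}.
#'
#' @slot pixels numeric matrix of intensities in \code{[0, bitMax]} (RFU).
#' @slot channel one of \code{"brightfield"}, \code{"calcein"}, \code{"hoechst"}.
#' @slot pixelSize micrometres per pixel, strictly positive.
#' @slot bitMax maximum representable intensity (RFU). Synthetic scenes use
#'   250 so that 40\% of maximum corresponds to the 100 RFU binary threshold.
#'
#' @exportClass ChannelImage
setClass("ChannelImage",
  representation(
    pixels = "matrix",
    channel = "character",
    pixelSize = "numeric",
    bitMax = "numeric"
  )
)

setValidity("ChannelImage", function(object) {
  msg <- character()
  if (length(object@channel) != 1L || !object@channel %in% .CHANNELS)
    msg <- c(msg, sprintf("'channel' must be one of: %s",
                          paste(.CHANNELS, collapse = ", ")))
  if (!is.numeric(object@pixels) || length(object@pixels) == 0L)
    msg <- c(msg, "'pixels' must be a non-empty numeric matrix")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (um/px)")
  if (length(object@bitMax) != 1L || !is.finite(object@bitMax) ||
      object@bitMax <= 0)
    msg <- c(msg, "'bitMax' must be a single positive number (RFU)")
  if (is.numeric(object@pixels) && length(object@pixels) &&
      length(object@bitMax) == 1L && is.finite(object@bitMax)) {
    rng <- range(object@pixels)
    if (rng[1] < 0 || rng[2] > object@bitMax)
      msg <- c(msg, sprintf("pixel values must lie in [0, %g]", object@bitMax))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelImage
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param channel channel name: \code{"brightfield"}, \code{"calcein"} or
#'   \code{"hoechst"}.
#' @param pixelSize micrometres per pixel.
#' @param bitMax maximum representable intensity in RFU (default 250, the
#'   scale on which the 100 RFU threshold equals 40\% of maximum).
#' @return a \code{ChannelImage}.
#' @examples
#' img <- ChannelImage(matrix(0, 16, 16), "calcein", pixelSize = 1)
#' pixelSize(img)
#' @export
ChannelImage <- function(pixels, channel, pixelSize, bitMax = 250) {
  new("ChannelImage", pixels = pixels, channel = channel,
      pixelSize = as.numeric(pixelSize), bitMax = as.numeric(bitMax))
}

#' Microwell device layout
#'
#' Geometry of the spheroid-culture device: chambers, microwells per chamber,
#' well width/depth, and physical well-center positions used both for scene
#' synthesis and for assigning detected spheroids to wells.
#'
#' @slot nChambers number of parallel culture chambers.
#' @slot wellsPerChamber number of microwells per chamber.
#' @slot wellWidth microwell width in micrometres.
#' @slot wellDepth microwell depth in micrometres.
#' @slot wellCenters numeric matrix (totalWells x 2) of (x, y) positions, um.
#'
#' @exportClass DeviceLayout
setClass("DeviceLayout",
  representation(
    nChambers = "integer",
    wellsPerChamber = "integer",
    wellWidth = "numeric",
    wellDepth = "numeric",
    wellCenters = "matrix"
  )
)

setValidity("DeviceLayout", function(object) {
  msg <- character()
  tot <- object@nChambers * object@wellsPerChamber
  if (object@nChambers < 1L || object@wellsPerChamber < 1L)
    msg <- c(msg, "chamber and well counts must be >= 1")
  if (object@wellWidth <= 0 || object@wellDepth <= 0)
    msg <- c(msg, "well width and depth must be positive (um)")
  if (nrow(object@wellCenters) != tot || ncol(object@wellCenters) != 2L)
    msg <- c(msg, sprintf("'wellCenters' must be a %d x 2 matrix", tot))
  else if (tot > 1L) {
    d <- stats::dist(object@wellCenters)
    if (min(d) <= object@wellWidth)
      msg <- c(msg, "well centers overlap: pairwise distance must exceed wellWidth")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a device layout
#'
#' Well centers default to one row of wells per chamber on a regular grid:
#' column pitch \code{pitch} within a chamber and row pitch
#' \code{chamberGap} between chambers.
#'
#' @param nChambers number of chambers.
#' @param wellsPerChamber microwells per chamber.
#' @param wellWidth,wellDepth microwell width and depth, um.
#' @param pitch center-to-center spacing of wells within a chamber, um; must
#'   exceed \code{wellWidth}.
#' @param chamberGap spacing between chamber rows, um (default \code{pitch}).
#' @param wellCenters optional explicit (totalWells x 2) matrix of centers, um.
#' @return a \code{DeviceLayout}.
#' @examples
#' totalWells(defaultLayout())
#' @export
deviceLayout <- function(nChambers = 2L, wellsPerChamber = 10L,
                         wellWidth = 2000, wellDepth = 2000,
                         pitch = wellWidth * 1.1, chamberGap = pitch,
                         wellCenters = NULL) {
  nChambers <- as.integer(nChambers)
  wellsPerChamber <- as.integer(wellsPerChamber)
  if (is.null(wellCenters)) {
    cx <- (seq_len(wellsPerChamber) - 0.5) * pitch
    cy <- (seq_len(nChambers) - 0.5) * chamberGap
    wellCenters <- cbind(
      x = rep(cx, times = nChambers),
      y = rep(cy, each = wellsPerChamber)
    )
  }
  new("DeviceLayout", nChambers = nChambers, wellsPerChamber = wellsPerChamber,
      wellWidth = wellWidth, wellDepth = wellDepth,
      wellCenters = as.matrix(wellCenters))
}

#' The physical device preset
#'
#' Two parallel chambers of ten cone-shaped agarose microwells, 2 mm wide and
#' deep, yielding 20 spheroid wells per device.
#'
#' @return a \code{DeviceLayout} with 20 wells.
#' @export
defaultLayout <- function() {
  deviceLayout(2L, 10L, wellWidth = 2000, wellDepth = 2000, pitch = 2200)
}

#' A compact layout for synthetic scenes
#'
#' Same chamber/well topology as the physical device but with tighter well
#' spacing, so a full synthetic field of view stays a few megapixels at
#' micron-scale pixel sizes. Spheroids up to ~450 um still fit without
#' touching neighbouring wells.
#'
#' @param nChambers,wellsPerChamber layout counts (default 2 x 10).
#' @return a \code{DeviceLayout}.
#' @export
compactLayout <- function(nChambers = 2L, wellsPerChamber = 10L) {
  deviceLayout(nChambers, wellsPerChamber,
               wellWidth = 450, wellDepth = 450, pitch = 620)
}

#' Generative preset for a synthetic spheroid scene
#'
#' Ground-truth parameters of a synthetic microwell scene: spheroid size
#' distribution, dead-rim geometry, calcein intensity profile, drug-induced
#' loosening, and the noise model (Poisson shot noise plus Gaussian read
#' noise) on a 0--250 RFU scale.
#'
#' @slot name preset label.
#' @slot nSpheroids number of spheroids to place (one per well).
#' @slot trueDiameterMean mean spheroid diameter before loosening, um.
#' @slot trueDiameterSd between-spheroid diameter standard deviation, um.
#' @slot deadRimFraction fraction of the radius in [0, 1) that is
#'   calcein-negative (peripheral cell death).
#' @slot coreIntensity calcein intensity of the viable core, RFU.
#' @slot intensityProfileKnee fraction of the viable radius at which the
#'   calcein profile crosses the binary threshold; the true binary area
#'   fraction equals its square.
#' @slot looseningFactor multiplicative diameter factor >= 1 (drug-induced
#'   decompaction).
#' @slot backgroundLevel calcein background, RFU.
#' @slot gaussianNoiseSd read-noise standard deviation, RFU (0 disables).
#' @slot poissonScale photons per RFU for shot noise (0 disables).
#' @slot satellites logical; render small detached aggregates next to each
#'   spheroid (exercises the size filter).
#' @slot seed integer seed making generation reproducible.
#'
#' @exportClass ScenePreset
setClass("ScenePreset",
  representation(
    name = "character",
    nSpheroids = "integer",
    trueDiameterMean = "numeric",
    trueDiameterSd = "numeric",
    deadRimFraction = "numeric",
    coreIntensity = "numeric",
    intensityProfileKnee = "numeric",
    looseningFactor = "numeric",
    backgroundLevel = "numeric",
    gaussianNoiseSd = "numeric",
    poissonScale = "numeric",
    satellites = "logical",
    seed = "integer"
  )
)

setValidity("ScenePreset", function(object) {
  msg <- character()
  if (object@nSpheroids < 1L) msg <- c(msg, "'nSpheroids' must be >= 1")
  if (object@trueDiameterMean <= 0)
    msg <- c(msg, "'trueDiameterMean' must be > 0")
  if (object@trueDiameterSd < 0) msg <- c(msg, "'trueDiameterSd' must be >= 0")
  if (object@deadRimFraction < 0 || object@deadRimFraction >= 1)
    msg <- c(msg, "'deadRimFraction' must lie in [0, 1)")
  if (object@intensityProfileKnee <= 0 || object@intensityProfileKnee > 1)
    msg <- c(msg, "'intensityProfileKnee' must lie in (0, 1]")
  if (object@looseningFactor < 1)
    msg <- c(msg, "'looseningFactor' must be >= 1")
  if (object@backgroundLevel < 0 || object@gaussianNoiseSd < 0 ||
      object@poissonScale < 0)
    msg <- c(msg, "background and noise parameters must be >= 0")
  if (object@coreIntensity <= object@backgroundLevel)
    msg <- c(msg, "'coreIntensity' must exceed 'backgroundLevel'")
  if (length(msg)) msg else TRUE
})

#' Construct a scene preset
#'
#' @param name preset label.
#' @param nSpheroids number of spheroids (default 20, one device's worth).
#' @param trueDiameterMean,trueDiameterSd diameter distribution, um.
#' @param deadRimFraction calcein-negative fraction of the radius, [0, 1).
#' @param coreIntensity viable-core calcein intensity, RFU.
#' @param intensityProfileKnee radius fraction where the calcein profile
#'   crosses the binary threshold; true BAF = knee^2.
#' @param looseningFactor diameter multiplier >= 1.
#' @param backgroundLevel calcein background, RFU.
#' @param gaussianNoiseSd,poissonScale noise model (0 disables each part).
#' @param satellites render small detached aggregates (default FALSE).
#' @param seed integer seed.
#' @return a \code{ScenePreset}.
#' @examples
#' p <- scenePreset("demo", trueDiameterMean = 300, trueDiameterSd = 0)
#' @export
scenePreset <- function(name = "custom", nSpheroids = 20L,
                        trueDiameterMean = 300, trueDiameterSd = 10,
                        deadRimFraction = 0, coreIntensity = 250,
                        intensityProfileKnee = sqrt(0.85),
                        looseningFactor = 1, backgroundLevel = 5,
                        gaussianNoiseSd = 2, poissonScale = 4,
                        satellites = FALSE, seed = 1L) {
  new("ScenePreset", name = name, nSpheroids = as.integer(nSpheroids),
      trueDiameterMean = trueDiameterMean, trueDiameterSd = trueDiameterSd,
      deadRimFraction = deadRimFraction, coreIntensity = coreIntensity,
      intensityProfileKnee = intensityProfileKnee,
      looseningFactor = looseningFactor, backgroundLevel = backgroundLevel,
      gaussianNoiseSd = gaussianNoiseSd, poissonScale = poissonScale,
      satellites = satellites, seed = as.integer(seed))
}

#' Per-well spheroid detection
#'
#' Binary masks for one well: the bright-field spheroid extent and the
#' calcein-positive region of interest (ROI). The two masks are independent —
#' the calcein mask may extend beyond or lie within the bright-field mask.
#'
#' @slot wellId integer well index (1-based, row of the layout's centers).
#' @slot bfMask logical matrix; bright-field mask (0 x 0 if absent).
#' @slot calceinMask logical matrix; calcein ROI mask (0 x 0 if absent).
#' @slot centroid numeric (x, y) centroid in micrometres.
#' @slot pixelSize micrometres per pixel of the source images.
#'
#' @exportClass SpheroidDetection
setClass("SpheroidDetection",
  representation(
    wellId = "integer",
    bfMask = "matrix",
    calceinMask = "matrix",
    centroid = "numeric",
    pixelSize = "numeric"
  )
)

setValidity("SpheroidDetection", function(object) {
  msg <- character()
  if (length(object@centroid) != 2L)
    msg <- c(msg, "'centroid' must be (x, y)")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Calcein intensity readout of one spheroid
#'
#' Binary-threshold quantification within the calcein ROI: the area above the
#' threshold (binary area), its fraction of the ROI (BAF), and the maximum
#' intensity.
#'
#' @slot roiArea ROI area, um^2.
#' @slot binaryArea above-threshold area, um^2.
#' @slot baf binary area fraction in [0, 1].
#' @slot iMax maximum intensity over the ROI, RFU.
#' @slot thresholdUsed threshold applied, RFU.
#' @slot thresholdMode \code{"absolute"} or \code{"fraction_of_max"}.
#'
#' @exportClass ViabilitySignal
setClass("ViabilitySignal",
  representation(
    roiArea = "numeric",
    binaryArea = "numeric",
    baf = "numeric",
    iMax = "numeric",
    thresholdUsed = "numeric",
    thresholdMode = "character"
  )
)

setValidity("ViabilitySignal", function(object) {
  msg <- character()
  if (object@binaryArea < 0 || object@binaryArea > object@roiArea)
    msg <- c(msg, "binary area must lie in [0, roiArea]")
  if (object@baf < 0 || object@baf > 1)
    msg <- c(msg, "BAF must lie in [0, 1]")
  if (object@baf > 0 && object@thresholdUsed > object@iMax)
    msg <- c(msg, "threshold exceeds I_max although BAF > 0")
  if (!object@thresholdMode %in% c("absolute", "fraction_of_max"))
    msg <- c(msg, "'thresholdMode' must be 'absolute' or 'fraction_of_max'")
  if (length(msg)) msg else TRUE
})
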