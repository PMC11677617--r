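#' @describeIn ChannelImage-class pixel matrix accessor
#' @param x object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
setMethod("pixels", "ChannelImage", function(x) x@pixels)

#' @describeIn ChannelImage-class channel name accessor
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
setMethod("channelName", "ChannelImage", function(x) x@channel)

#' @describeIn ChannelImage-class pixel size (um/px) accessor
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
setMethod("pixelSize", "ChannelImage", function(x) x@pixelSize)
setMethod("pixelSize", "SpheroidDetection", function(x) x@pixelSize)

#' @describeIn ChannelImage-class maximum representable intensity accessor
#' @export
setGeneric("bitMax", function(x) standardGeneric("bitMax"))
setMethod("bitMax", "ChannelImage", function(x) x@bitMax)

#' @describeIn DeviceLayout-class well-center matrix accessor
#' @param x object.
#' @export
setGeneric("wellCenters", function(x) standardGeneric("wellCenters"))
setMethod("wellCenters", "DeviceLayout", function(x) x@wellCenters)

#' @describeIn DeviceLayout-class total number of microwells
#' @export
setGeneric("totalWells", function(x) standardGeneric("totalWells"))
setMethod("totalWells", "DeviceLayout",
          function(x) x@nChambers * x@wellsPerChamber)

#' @describeIn SpheroidDetection-class well index accessor
#' @param x object.
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))
setMethod("wellId", "SpheroidDetection", function(x) x@wellId)

#' @describeIn SpheroidDetection-class bright-field mask accessor
#' @export
setGeneric("bfMask", function(x) standardGeneric("bfMask"))
setMethod("bfMask", "SpheroidDetection", function(x) x@bfMask)

#' @describeIn SpheroidDetection-class calcein ROI mask accessor
#' @export
setGeneric("calceinMask", function(x) standardGeneric("calceinMask"))
setMethod("calceinMask", "SpheroidDetection", function(x) x@calceinMask)

#' @describeIn ViabilitySignal-class binary area fraction accessor
#' @param x object.
#' @export
setGeneric("baf", function(x) standardGeneric("baf"))
setMethod("baf", "ViabilitySignal", function(x) x@baf)

#' @describeIn ViabilitySignal-class maximum ROI intensity accessor
#' @export
setGeneric("iMax", function(x) standardGeneric("iMax"))
setMethod("iMax", "ViabilitySignal", function(x) x@iMax)

#' @describeIn ViabilitySignal-class ROI area accessor (um^2)
#' @export
setGeneric("roiArea", function(x) standardGeneric("roiArea"))
setMethod("roiArea", "ViabilitySignal", function(x) x@roiArea)

#' @describeIn ViabilitySignal-class above-threshold area accessor (um^2)
#' @export
setGeneric("binaryArea", function(x) standardGeneric("binaryArea"))
setMethod("binaryArea", "ViabilitySignal", function(x) x@binaryArea)

setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage [%s]: %d x %d px, %.3g um/px, range %.4g-%.4g of %g RFU\n",
              object@channel, nrow(object@pixels), ncol(object@pixels),
              object@pixelSize, min(object@pixels), max(object@pixels),
              object@bitMax))
})

setMethod("show", "DeviceLayout", function(object) {
  cat(sprintf(
    "DeviceLayout: %d chamber(s) x %d wells (%d total), well %g x %g um\n",
    object@nChambers, object@wellsPerChamber, totalWells(object),
    object@wellWidth, object@wellDepth))
})

setMethod("show", "ScenePreset", function(object) {
  cat(sprintf("ScenePreset '%s': n=%d, diameter %g +/- %g um (x%.3g loosening)\n",
              object@name, object@nSpheroids, object@trueDiameterMean,
              object@trueDiameterSd, object@looseningFactor))
  cat(sprintf("  dead rim %.3g of radius | core %g RFU | knee %.4g (true BAF %.4g)\n",
              object@deadRimFraction, object@coreIntensity,
              object@intensityProfileKnee, object@intensityProfileKnee^2))
  cat(sprintf("  background %g RFU, noise: gaussian sd %g, poisson %g ph/RFU, seed %d\n",
              object@backgroundLevel, object@gaussianNoiseSd,
              object@poissonScale, object@seed))
})

setMethod("show", "SpheroidDetection", function(object) {
  cat(sprintf(
    "SpheroidDetection well %d: bf %d px, calcein %d px, centroid (%.1f, %.1f) um\n",
    object@wellId, sum(object@bfMask), sum(object@calceinMask),
    object@centroid[1], object@centroid[2]))
})

setMethod("show", "ViabilitySignal", function(object) {
  cat(sprintf(
    "ViabilitySignal: ROI %.4g um^2, binary %.4g um^2, BAF %.4f, I_max %g RFU (threshold %g, %s)\n",
    object@roiArea, object@binaryArea, object@baf, object@iMax,
    object@thresholdUsed, object@thresholdMode))
})
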