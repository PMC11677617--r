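#' Resolve the binary intensity threshold
#'
#' The binary threshold can be stated in absolute RFU (the calibrated default
#' is 100 RFU on a 250 RFU scale) or as a fraction of a reference maximum
#' ("40\% of maximum"), in which case it is \code{value * iReference}.
#'
#' @param mode \code{"absolute"} or \code{"fraction_of_max"}.
#' @param value absolute mode: threshold in RFU, in \code{[0, bitMax]};
#'   fraction mode: fraction in (0, 1].
#' @param iReference reference maximum intensity (RFU); required in fraction
#'   mode. Either the detector maximum (\code{bitMax}) or a per-image ROI
#'   maximum, depending on the chosen convention.
#' @param bitMax detector maximum used to validate absolute thresholds.
#' @return threshold in RFU.
#' @examples
#' computeThreshold("fraction_of_max", 0.4, iReference = 250)  # 100 RFU
#' @export
computeThreshold <- function(mode = c("absolute", "fraction_of_max"),
                             value, iReference = NULL, bitMax = 250) {
  mode <- match.arg(mode)
  if (length(value) != 1L || !is.finite(value))
    stop("'value' must be a single finite number")
  if (mode == "fraction_of_max") {
    if (value <= 0 || value > 1)
      stop("fraction-of-max threshold must lie in (0, 1]")
    if (is.null(iReference) || !is.finite(iReference) || iReference < 0)
      stop("'iReference' (reference maximum, RFU) is required in fraction mode")
    value * iReference
  } else {
    if (value < 0 || value > bitMax)
      stop(sprintf("absolute threshold must lie in [0, %g] RFU", bitMax))
    value
  }
}

#' Binary area fraction of a calcein ROI
#'
#' Within the detected calcein region of interest, pixels with intensity
#' strictly above the threshold form the binary area; the binary area
#' fraction (BAF) is the binary area divided by the ROI area. The maximum
#' intensity over the ROI is reported alongside.
#'
#' @param img a calcein \code{ChannelImage}.
#' @param roiMask logical matrix, same shape as the image, with at least one
#'   TRUE pixel (the spheroid's calcein-positive region).
#' @param threshold binary threshold in RFU (default 100, the calibration at
#'   40\% of a 250 RFU maximum).
#' @param thresholdMode provenance label stored in the result.
#' @return a \code{ViabilitySignal}.
#' @examples
#' img <- ChannelImage(matrix(150, 10, 10), "calcein", pixelSize = 1)
#' baf(binaryAreaFraction(img, matrix(TRUE, 10, 10)))  # 1
#' @export
binaryAreaFraction <- function(img, roiMask, threshold = 100,
                               thresholdMode = "absolute") {
  stopifnot(is(img, "ChannelImage"))
  if (channelName(img) != "calcein")
    stop("binary area fraction is defined on the calcein channel")
  if (!is.matrix(roiMask) || !all(dim(roiMask) == dim(pixels(img))))
    stop("'roiMask' must be a matrix with the same shape as the image")
  if (threshold < 0) stop("'threshold' must be >= 0 RFU")
  roi <- roiMask != 0
  nRoi <- sum(roi)
  if (nRoi == 0L) stop("empty ROI: BAF is undefined")
  ps2 <- pixelSize(img)^2
  vals <- pixels(img)[roi]
  nBin <- sum(vals > threshold)
  new("ViabilitySignal",
      roiArea = nRoi * ps2,
      binaryArea = nBin * ps2,
      baf = nBin / nRoi,
      iMax = max(vals),
      thresholdUsed = threshold,
      thresholdMode = thresholdMode)
}
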