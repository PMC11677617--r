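#' Measure every spheroid in a multichannel field of view
#'
#' Runs the full per-scene pipeline: bright-field and calcein segmentation,
#' well assignment, Feret morphometry on both masks, the binary area
#' fraction within the calcein ROI, and the viability scores. The volume and
#' IMVIS are computed from the calcein-mask diameters (the calcein-positive,
#' i.e. viable, portion); bright-field diameters are reported alongside in
#' \code{bf_D_min}/\code{bf_D_max}/\code{bf_D_mean} columns.
#'
#' @param images named list of \code{ChannelImage}s containing at least
#'   \code{brightfield} and \code{calcein} (e.g. from
#'   \code{\link{generateScene}} or \code{\link{readImageSet}}).
#' @param layout the \code{DeviceLayout} the field of view covers.
#' @param conditions optional condition table (see
#'   \code{\link{conditionTable}}); row i annotates well i. Defaults to
#'   untreated, unknown cell type.
#' @param thresholdMode \code{"absolute"} (default) or
#'   \code{"fraction_of_max"}.
#' @param thresholdValue threshold in RFU (absolute mode, default 100) or as
#'   a fraction of the reference maximum.
#' @param reference for fraction mode: \code{"bit_max"} (detector scale) or
#'   \code{"per_image_max"} (each spheroid's observed ROI maximum).
#' @param minArea segmentation size filter, um^2.
#' @return data.frame with one row per measured spheroid: identifiers and
#'   conditions, calcein diameters (\code{D_min}, \code{D_max},
#'   \code{D_mean}), volume \code{V} (um^3), \code{roi_area},
#'   \code{binary_area} (um^2), \code{BAF}, \code{I_max}, \code{IMVIS}
#'   (um^3), and the bright-field diameters.
#' @export
measureScene <- function(images, layout, conditions = NULL,
                         thresholdMode = c("absolute", "fraction_of_max"),
                         thresholdValue = 100,
                         reference = c("bit_max", "per_image_max"),
                         minArea = .defaultMinArea()) {
  thresholdMode <- match.arg(thresholdMode)
  reference <- match.arg(reference)
  bf <- images$brightfield
  cal <- images$calcein
  if (is.null(bf) || is.null(cal))
    stop("'images' must contain 'brightfield' and 'calcein' channels")
  bfMasks <- segmentBrightfield(bf, minArea)
  calMasks <- segmentCalcein(cal, minArea)
  asg <- assignWells(bfMasks, layout, pixelSize(bf), calceinMasks = calMasks)
  ps <- pixelSize(cal)
  rows <- list()
  for (det in asg$detections) {
    cm <- calceinMask(det)
    if (!length(cm)) next  # no calcein signal in this well
    fer <- feretDiameters(cm, ps)
    dMean <- meanDiameter(fer["dMin"], fer["dMax"])
    V <- sphereVolume(dMean)
    thr <- if (thresholdMode == "absolute") {
      computeThreshold("absolute", thresholdValue, bitMax = bitMax(cal))
    } else {
      iRef <- if (reference == "bit_max") bitMax(cal)
              else max(pixels(cal)[cm])
      computeThreshold("fraction_of_max", thresholdValue, iReference = iRef)
    }
    vs <- binaryAreaFraction(cal, cm, thr, thresholdMode = thresholdMode)
    bm <- bfMask(det)
    bfFer <- if (length(bm)) feretDiameters(bm, ps) else
      c(dMax = NA_real_, dMin = NA_real_)
    w <- wellId(det)
    cond <- if (!is.null(conditions) && w <= nrow(conditions))
      conditions[w, ] else
      data.frame(spheroid_id = sprintf("well_%02d", w), cell_type = NA,
                 dose = 0, timepoint = NA, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      spheroid_id = cond$spheroid_id, cell_type = cond$cell_type,
      dose = cond$dose, timepoint = cond$timepoint,
      well_id = w,
      D_min = unname(fer["dMin"]), D_max = unname(fer["dMax"]),
      D_mean = unname(dMean), V = unname(V),
      roi_area = roiArea(vs), binary_area = binaryArea(vs),
      BAF = baf(vs), I_max = iMax(vs),
      IMVIS = imvis(unname(V), baf(vs)),
      bf_D_min = unname(bfFer["dMin"]), bf_D_max = unname(bfFer["dMax"]),
      bf_D_mean = if (is.na(bfFer["dMin"])) NA_real_ else
        unname(meanDiameter(bfFer["dMin"], bfFer["dMax"])),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
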