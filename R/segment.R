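# Default size filter: the area of a 50 um disk. Detached small aggregates
# fall below it; spheroids (>= ~200 um) are three orders of magnitude larger.
.defaultMinArea <- function() pi * 25^2

# Separable Gaussian smoothing with replicate-edge padding (compiled).
.gaussianSmooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  .sepConvolve2D(m, k / sum(k))
}

# Triangle threshold on a 256-bin histogram: the threshold is the bin
# farthest from the chord joining the histogram peak to the end of its
# bright tail. Suited to background-dominated fluorescence histograms where
# the foreground spans a wide intensity range.
.triangleThreshold <- function(x, bitMax, bins = 256L) {
  b <- pmin(pmax(floor(x / bitMax * (bins - 1)), 0), bins - 1) + 1L
  h <- tabulate(b, nbins = bins)
  pk <- which.max(h)
  last <- max(which(h > 0))
  if (last <= pk) return(bitMax * pk / bins)
  xs <- pk:last
  d <- abs((h[last] - h[pk]) * (xs - pk) - (last - pk) * (h[xs] - h[pk]))
  ti <- xs[which.max(d)]
  (ti - 0.5) / (bins - 1) * bitMax
}

# Shared machinery: Gaussian smoothing, automatic global threshold, hole
# filling, connected components, size filter. Bright-field images (dark
# objects on a bright background, a bimodal histogram) are thresholded by
# Otsu's criterion; fluorescence ROIs use the triangle method, which anchors
# the cut just above the background peak and so keeps dim-but-positive
# spheroid rims inside the ROI regardless of the intensity profile.
.segmentGlobal <- function(img, minArea, dark, sigma = 2) {
  px <- pixels(img)
  if (diff(range(px)) == 0) return(list())  # uniform image: nothing to find
  sm <- .gaussianSmooth(px, sigma)
  sm <- pmin(pmax(sm, 0), bitMax(img))
  if (dark) {
    th <- EBImage::otsu(EBImage::as.Image(sm / bitMax(img)),
                        range = c(0, 1), levels = 256) * bitMax(img)
    fg <- sm < th
  } else {
    # Two-pass background-anchored threshold. The triangle cut separates the
    # background peak from the signal tail but sits low on the smoothed
    # object edge, which would dilate the ROI; re-cutting at half the height
    # of the faintest object edge (background median to a low foreground
    # quantile) centers the boundary on the intensity step. The 25% quantile
    # sits above the smoothed-edge skirt for disk-like objects, so the cut
    # lands at half the true edge height and the boundary is unbiased.
    th0 <- .triangleThreshold(sm, bitMax(img))
    fg <- sm > th0
    if (any(fg) && !all(fg)) {
      bg <- stats::median(sm[!fg])
      edge <- stats::quantile(sm[fg], 0.25, names = FALSE)
      th <- (bg + edge) / 2
      if (th > th0) fg <- sm > th
    }
  }
  fg <- EBImage::fillHull(fg)
  lbl <- EBImage::bwlabel(fg)
  nObj <- max(lbl)
  if (nObj == 0) return(list())
  idx <- which(lbl > 0)
  byObj <- split(idx, lbl[idx])
  areas <- lengths(byObj) * pixelSize(img)^2
  byObj <- byObj[areas >= minArea]
  lapply(byObj, function(ii) {
    m <- matrix(FALSE, nrow(lbl), ncol(lbl))
    m[ii] <- TRUE
    m
  })
}

#' Segment spheroids in a bright-field image
#'
#' Spheroids appear as objects darker than the background. The image is
#' Gaussian-smoothed (sigma = 2 px), globally thresholded by Otsu's
#' criterion, holes are filled, and connected components smaller than
#' \code{minArea} are discarded. Each returned mask is one connected
#' component.
#'
#' @param img a bright-field \code{ChannelImage}.
#' @param minArea minimum object area in um^2 (default: area of a 50 um
#'   disk, which removes detached small aggregates).
#' @param sigma smoothing bandwidth in pixels.
#' @return list of logical matrices (possibly empty).
#' @export
segmentBrightfield <- function(img, minArea = .defaultMinArea(), sigma = 2) {
  stopifnot(is(img, "ChannelImage"))
  if (channelName(img) != "brightfield")
    stop("'img' must be the brightfield channel")
  .segmentGlobal(img, minArea, dark = TRUE, sigma = sigma)
}

#' Segment the calcein-positive region of each spheroid
#'
#' Detects the green-fluorescent region of interest (ROI): pixels above an
#' automatic global threshold on the smoothed calcein channel, chosen by the
#' triangle method so the cut sits just above the background peak. This
#' detection threshold is distinct from the binary threshold used for the
#' binary area fraction — it separates spheroid from background, not bright
#' from dim viable signal. Size filtering and hole filling as in
#' \code{\link{segmentBrightfield}}.
#'
#' @inheritParams segmentBrightfield
#' @param img a calcein \code{ChannelImage}.
#' @return list of logical matrices (possibly empty).
#' @export
segmentCalcein <- function(img, minArea = .defaultMinArea(), sigma = 2) {
  stopifnot(is(img, "ChannelImage"))
  if (channelName(img) != "calcein")
    stop("'img' must be the calcein channel")
  .segmentGlobal(img, minArea, dark = FALSE, sigma = sigma)
}

.maskCentroid <- function(mask, pixelSize) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2] - 1) * pixelSize, y = mean(idx[, 1] - 1) * pixelSize)
}

.nearestWell <- function(centroid, centers) {
  which.min((centers[, 1] - centroid[1])^2 + (centers[, 2] - centroid[2])^2)
}

# Assign one channel's masks to wells; keep the largest mask per well.
.assignChannel <- function(masks, centers, pixelSize) {
  wellOf <- integer(0); areas <- numeric(0)
  for (m in masks) {
    cen <- .maskCentroid(m, pixelSize)
    wellOf <- c(wellOf, .nearestWell(cen, centers))
    areas <- c(areas, sum(m))
  }
  kept <- rep(FALSE, length(masks))
  for (w in unique(wellOf)) {
    cand <- which(wellOf == w)
    kept[cand[which.max(areas[cand])]] <- TRUE
  }
  list(wellOf = wellOf, kept = kept)
}

#' Assign segmented masks to microwells
#'
#' Each mask is assigned to the nearest well center (by mask centroid). When
#' several masks map to the same well, the largest is kept and the others are
#' flagged; wells with no mask are reported as missing. Neither situation is
#' fatal. When calcein masks are supplied, they are assigned independently
#' and paired with the bright-field mask of the same well.
#'
#' @param masks list of logical matrices from one field of view (typically
#'   bright-field masks).
#' @param layout the \code{DeviceLayout} the field of view covers.
#' @param pixelSize micrometres per pixel of the source image.
#' @param calceinMasks optional list of calcein ROI masks from the same field
#'   of view.
#' @return list with \code{detections} (list of
#'   \code{\link{SpheroidDetection-class}} objects, ordered by well),
#'   \code{missingWells} (integer well ids with no mask in any channel) and
#'   \code{duplicateWells} (well ids that attracted more than one mask).
#' @export
assignWells <- function(masks, layout, pixelSize, calceinMasks = NULL) {
  stopifnot(is(layout, "DeviceLayout"), pixelSize > 0)
  centers <- wellCenters(layout)
  nW <- totalWells(layout)
  emptyMask <- matrix(logical(0), 0, 0)
  bfA <- .assignChannel(masks, centers, pixelSize)
  calA <- .assignChannel(calceinMasks %||% list(), centers, pixelSize)
  dets <- list()
  dup <- integer(0)
  for (w in seq_len(nW)) {
    bi <- which(bfA$wellOf == w & bfA$kept)
    ci <- which(calA$wellOf == w & calA$kept)
    if (sum(bfA$wellOf == w) > 1L || sum(calA$wellOf == w) > 1L)
      dup <- c(dup, w)
    if (!length(bi) && !length(ci)) next
    refMask <- if (length(bi)) masks[[bi]] else calceinMasks[[ci]]
    dets[[length(dets) + 1L]] <- new("SpheroidDetection",
      wellId = w,
      bfMask = if (length(bi)) masks[[bi]] else emptyMask,
      calceinMask = if (length(ci)) calceinMasks[[ci]] else emptyMask,
      centroid = unname(.maskCentroid(refMask, pixelSize)),
      pixelSize = pixelSize)
  }
  filled <- vapply(dets, wellId, integer(1))
  missing <- setdiff(seq_len(nW), filled)
  if (length(missing))
    warning(sprintf("%d well(s) without a detected spheroid: %s",
                    length(missing), paste(missing, collapse = ", ")))
  if (length(dup))
    warning(sprintf("multiple masks mapped to well(s) %s; kept the largest",
                    paste(dup, collapse = ", ")))
  list(detections = dets, missingWells = missing, duplicateWells = dup)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
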