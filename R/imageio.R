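.sidecarPath <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Read a calibrated multichannel image set from TIFF
#'
#' Reads a single- or multi-page TIFF into one \code{ChannelImage} per page.
#' Channel names, pixel size and intensity scale come from the JSON sidecar
#' written by \code{\link{writeImageSet}} when present; otherwise channels
#' follow the page-order dialect (page 1 = brightfield, 2 = calcein,
#' 3 = hoechst), the pixel size must be supplied explicitly, and the
#' intensity scale is inferred from the TIFF bit depth.
#'
#' @param path TIFF file path.
#' @param pixelSize micrometres per pixel; overrides the sidecar.
#' @param channels character vector of channel names per page; overrides the
#'   sidecar and the page-order dialect.
#' @param bitMax maximum representable intensity; overrides sidecar/bit depth.
#' @return named list of \code{ChannelImage}s.
#' @export
readImageSet <- function(path, pixelSize = NULL, channels = NULL,
                         bitMax = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains zero pages")
  meta <- NULL
  sc <- .sidecarPath(path)
  if (file.exists(sc)) meta <- jsonlite::fromJSON(sc)
  if (is.null(pixelSize)) pixelSize <- meta$pixel_size
  if (is.null(pixelSize))
    stop("missing field 'pixel_size': supply it or provide a JSON sidecar")
  if (is.null(bitMax)) bitMax <- meta$bit_max
  if (is.null(bitMax)) {
    bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
    bitMax <- 2^bits - 1
  }
  if (is.null(channels)) channels <- meta$channels
  if (is.null(channels))
    channels <- .CHANNELS[seq_len(min(length(pages), 3L))]
  if (length(channels) < length(pages))
    channels <- c(channels,
                  paste0("channel", seq(length(channels) + 1, length(pages))))
  imgs <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]  # drop replicate samples
    m <- matrix(as.numeric(m), nrow(m), ncol(m))  # plain numeric raster
    ch <- if (channels[i] %in% .CHANNELS) channels[i] else "calcein"
    ChannelImage(m, ch, pixelSize, bitMax)
  })
  names(imgs) <- channels[seq_along(imgs)]
  imgs
}

#' Write a multichannel image set as TIFF plus JSON sidecar
#'
#' Writes one page per channel (8-bit when every \code{bitMax} is <= 255,
#' 16-bit otherwise) and a JSON sidecar recording pixel size, channel names
#' and the intensity scale, so \code{\link{readImageSet}} can restore the
#' set without overrides. Integer intensities round-trip exactly.
#'
#' @param images list of \code{ChannelImage}s sharing shape and calibration.
#' @param path output TIFF path; the sidecar lands next to it with a
#'   \code{.json} extension.
#' @return \code{path}, invisibly.
#' @export
writeImageSet <- function(images, path) {
  if (length(images) == 0L) stop("'images' must be non-empty")
  stopifnot(all(vapply(images, is, logical(1), "ChannelImage")))
  ps <- unique(vapply(images, pixelSize, numeric(1)))
  if (length(ps) != 1L) stop("all channels must share one pixel size")
  bm <- max(vapply(images, bitMax, numeric(1)))
  bits <- if (bm <= 255) 8L else 16L
  denom <- 2^bits - 1
  tiff::writeTIFF(lapply(images, function(im) pixels(im) / denom),
                  path, bits.per.sample = bits)
  jsonlite::write_json(
    list(pixel_size = ps, bit_max = bm,
         channels = vapply(images, channelName, character(1))),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-spheroid ground truth as JSON
#'
#' @param truth ground-truth data.frame from \code{\link{generateScene}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON file
#'
#' @param path JSON path written by \code{\link{writeGroundTruth}}.
#' @return data.frame.
#' @export
readGroundTruth <- function(path) jsonlite::fromJSON(path)

.RESULT_COLUMNS <- c("spheroid_id", "cell_type", "dose", "timepoint",
                     "D_min", "D_max", "D_mean", "V", "roi_area",
                     "binary_area", "BAF", "I_max", "IMVIS")

#' Write per-spheroid viability records to CSV
#'
#' One row per spheroid with a fixed leading column order
#' (\code{spheroid_id, cell_type, dose, timepoint, D_min, D_max, D_mean, V,
#' roi_area, binary_area, BAF, I_max, IMVIS}); any extra columns (e.g. the
#' bright-field diameters) follow. Numbers are serialized at full precision.
#'
#' @param records non-empty data.frame of viability records.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame")
  miss <- setdiff(.RESULT_COLUMNS, names(records))
  if (length(miss))
    stop(sprintf("records lack required column(s): %s",
                 paste(miss, collapse = ", ")))
  ord <- c(.RESULT_COLUMNS, setdiff(names(records), .RESULT_COLUMNS))
  utils::write.csv(format(records[, ord], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-spheroid results CSV
#'
#' @param path CSV written by \code{\link{writeResults}}.
#' @return data.frame.
#' @export
readResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a condition table
#'
#' Maps each spheroid to its cell type, drug dose and timepoint.
#'
#' @param spheroid_id unique identifiers (one per spheroid).
#' @param cell_type \code{"OS"} or \code{"CS"}, recycled if scalar.
#' @param dose doxorubicin dose in uM (>= 0), recycled if scalar.
#' @param timepoint hours post treatment (>= 0), recycled if scalar.
#' @return data.frame with one row per spheroid.
#' @export
conditionTable <- function(spheroid_id, cell_type, dose, timepoint = 48) {
  df <- data.frame(spheroid_id = spheroid_id, cell_type = cell_type,
                   dose = dose, timepoint = timepoint,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$spheroid_id))
    stop("'spheroid_id' must be unique")
  if (any(df$dose < 0)) stop("'dose' must be >= 0")
  if (any(df$timepoint < 0)) stop("'timepoint' must be >= 0")
  df
}

#' Read a pipeline configuration file
#'
#' YAML configuration covering the knobs the pipeline exposes: layout
#' geometry, channel-order dialect, pixel-size calibration, binary threshold
#' (mode and value), segmentation size filter and seeds. Missing keys fall
#' back to the package defaults.
#'
#' @param path YAML file path (or \code{NULL} for pure defaults).
#' @return named list of settings.
#' @export
readPipelineConfig <- function(path = NULL) {
  defaults <- list(
    pixel_size = 1.4,
    channels = .CHANNELS,
    bit_max = 250,
    threshold_mode = "absolute",
    threshold_value = 100,
    reference = "bit_max",
    min_area = .defaultMinArea(),
    seed = 1L,
    layout = list(n_chambers = 2L, wells_per_chamber = 10L,
                  well_width = 450, well_depth = 450, pitch = 620)
  )
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  utils::modifyList(defaults, cfg)
}

#' Save a quick-look mask overlay as PNG
#'
#' Renders the image in grey with mask outlines filled in green, for visual
#' QC of segmentation.
#'
#' @param img a \code{ChannelImage}.
#' @param masks list of logical mask matrices.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMaskOverlay <- function(img, masks, path) {
  g <- pixels(img) / bitMax(img)
  rgb <- array(g, c(dim(g), 3))
  for (m in masks) rgb[, , 2][m] <- pmin(rgb[, , 2][m] + 0.4, 1)
  png::writePNG(rgb, path)
  invisible(path)
}
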