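# Rendering constants for the non-calcein channels. Bright-field spheroids
# are dark disks on a bright background; Hoechst covers the whole aggregate
# (live core and dead rim alike).
.BF_BACKGROUND <- 200
.BF_OBJECT <- 80
.HOECHST_BACKGROUND <- 2
.HOECHST_OBJECT <- 160
# In-disk floor of the calcein profile: above background (so automatic ROI
# detection captures the whole viable disk) but below the 100 RFU binary
# threshold (so it never inflates the binary area).
.CALCEIN_FLOOR <- 60

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Calibrated doxorubicin presets. Dose-0 diameters are the 24 h means (285 um
# osteosarcoma, 327 um chondrosarcoma). The 10 uM presets are solved so that
# (viable-diameter ratio)^3 x (BAF ratio) = 0.25, i.e. a 75% drop in the
# group-mean viability index. OS carries the effect as a calcein-negative
# dead rim with unchanged BAF; CS as an intensity loss (lower core intensity
# and BAF) with no rim.
.dxrTable <- function(cellType) {
  bafCtl <- 0.85
  if (cellType == "OS") {
    loos <- c(`0` = 1, `5` = 1.05, `10` = 1.10)
    rim <- c(`0` = 0, `5` = 1 - 1 / 1.05, `10` = 1 - 0.25^(1 / 3) / 1.10)
    bafv <- c(`0` = bafCtl, `5` = bafCtl, `10` = bafCtl)
    core <- c(`0` = 250, `5` = 250, `10` = 250)
    dia <- 285
  } else {
    loos <- c(`0` = 1, `5` = 1.10, `10` = 1.10)
    rim <- c(`0` = 0, `5` = 0, `10` = 0)
    bafv <- c(`0` = bafCtl, `5` = 0.80, `10` = 0.25 * bafCtl / 1.10^3)
    core <- c(`0` = 250, `5` = 220, `10` = 140)
    dia <- 327
  }
  list(doses = c(0, 5, 10), loos = loos, rim = rim, baf = bafv, core = core,
       dia = dia)
}

#' Doxorubicin dose-response scene presets
#'
#' Returns the generative preset for one cell type and dose. Untreated
#' presets reproduce the 24 h diameter means (285 um for osteosarcoma, 327 um
#' for chondrosarcoma). The 10 uM presets are calibrated so the group-mean
#' ground-truth viability index falls to 25\% of the untreated mean for both
#' cell types; osteosarcoma expresses the effect as a peripheral
#' calcein-negative dead rim with unchanged binary area fraction, while
#' chondrosarcoma keeps a fully calcein-positive (loosened, enlarged) disk
#' whose core intensity and above-threshold fraction drop. Doses between the
#' calibrated points \{0, 5, 10\} uM interpolate linearly; doses above 10 uM
#' reuse the 10 uM phenotype.
#'
#' @param cellType \code{"OS"} (osteosarcoma) or \code{"CS"} (chondrosarcoma).
#' @param dose doxorubicin dose in uM (>= 0).
#' @param nSpheroids spheroids per scene (default 20).
#' @param seed integer seed stored in the preset.
#' @return a \code{ScenePreset}.
#' @examples
#' dxrPreset("CS", 0)@trueDiameterMean  # 327
#' @export
dxrPreset <- function(cellType = c("OS", "CS"), dose, nSpheroids = 20L,
                      seed = 1L) {
  cellType <- match.arg(cellType)
  if (length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("'dose' must be a single non-negative value (uM)")
  tb <- .dxrTable(cellType)
  d <- min(dose, 10)
  ip <- function(v) stats::approx(tb$doses, v, xout = d, rule = 2)$y
  bafTrue <- ip(tb$baf)
  scenePreset(
    name = sprintf("%s_DXR_%guM", cellType, dose),
    nSpheroids = nSpheroids,
    trueDiameterMean = tb$dia,
    trueDiameterSd = 10,
    deadRimFraction = ip(tb$rim),
    coreIntensity = ip(tb$core),
    intensityProfileKnee = sqrt(bafTrue),
    looseningFactor = ip(tb$loos),
    backgroundLevel = 5,
    gaussianNoiseSd = 2,
    poissonScale = 4,
    satellites = FALSE,
    seed = seed
  )
}

# Radial calcein profile at normalized radius u = rho / viable radius.
# Flat core at coreIntensity out to half the knee, then a linear falloff that
# crosses `threshold` exactly at u = knee, clamped below at the floor.
.calceinProfile <- function(u, core, knee, threshold) {
  half <- knee / 2
  v <- ifelse(u <= half, core,
              core + (threshold - core) * (u - half) / half)
  pmax(v, .CALCEIN_FLOOR)
}

.renderDisk <- function(mat, cx, cy, rPx, valueFun) {
  nr <- nrow(mat); nc <- ncol(mat)
  c0 <- max(1L, floor(cx - rPx)); c1 <- min(nc, ceiling(cx + rPx + 2))
  r0 <- max(1L, floor(cy - rPx)); r1 <- min(nr, ceiling(cy + rPx + 2))
  if (c0 > c1 || r0 > r1) return(mat)
  xs <- (c0:c1) - 1  # 0-based pixel-center coordinates
  ys <- (r0:r1) - 1
  rho <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov <- pmin(pmax(rPx - rho + 0.5, 0), 1)  # 1-px soft edge
  patch <- mat[r0:r1, c0:c1]
  val <- valueFun(rho)
  mat[r0:r1, c0:c1] <- patch + (val - patch) * cov
  mat
}

#' Generate a synthetic multichannel microwell scene
#'
#' Renders one spheroid per microwell (first \code{nSpheroids} wells of the
#' layout) into bright-field, calcein and Hoechst channels, and returns the
#' exact per-spheroid ground truth. The bright-field channel shows dark disks
#' with a soft edge on a bright background; the calcein channel shows the
#' viable disk with a flat-core, monotone-falloff radial profile constructed
#' so that the fraction of the disk above \code{binaryThreshold} equals the
#' preset's true binary area fraction (the squared profile knee); the Hoechst
#' channel covers the full disk including any calcein-negative dead rim.
#' Poisson shot noise and Gaussian read noise are applied per the preset, and
#' intensities are quantized to integers in \code{[0, 250]}. A pixel belongs
#' to a disk when its center lies inside the circle; identical preset,
#' layout and seed give bit-identical output.
#'
#' @param preset a \code{ScenePreset}.
#' @param layout a \code{DeviceLayout}; must have at least
#'   \code{preset@nSpheroids} wells.
#' @param pixelSize micrometres per pixel of the rendered scene (default 1.4,
#'   so a ~300 um spheroid spans ~215 px).
#' @param binaryThreshold intensity the calcein profile crosses at the knee,
#'   RFU (default 100).
#' @param margin image border beyond the outermost well centers, um.
#' @param seed overrides the preset's seed when given.
#' @return list with \code{images} (named list of three
#'   \code{ChannelImage}s: brightfield, calcein, hoechst) and \code{truth}
#'   (data.frame: \code{well_id}, \code{true_diameter},
#'   \code{true_viable_diameter}, \code{true_baf}, \code{true_imvis}).
#' @examples
#' sc <- generateScene(scenePreset("demo", nSpheroids = 2, seed = 3),
#'                     deviceLayout(1, 2, wellWidth = 450, pitch = 620))
#' sc$truth
#' @export
generateScene <- function(preset, layout, pixelSize = 1.4,
                          binaryThreshold = 100, margin = 350,
                          seed = preset@seed) {
  stopifnot(is(preset, "ScenePreset"), is(layout, "DeviceLayout"))
  validObject(preset); validObject(layout)
  n <- preset@nSpheroids
  if (n > totalWells(layout))
    stop(sprintf("preset asks for %d spheroids but the layout has %d wells",
                 n, totalWells(layout)))
  centers <- wellCenters(layout)[seq_len(n), , drop = FALSE]
  nx <- ceiling((max(centers[, 1]) + margin) / pixelSize)
  ny <- ceiling((max(centers[, 2]) + margin) / pixelSize)
  bitMax <- 250
  .withSeed(seed, {
    dia <- stats::rnorm(n, preset@trueDiameterMean * preset@looseningFactor,
                        preset@trueDiameterSd)
    dia <- pmax(dia, 20)  # guard against non-physical draws
    bf <- matrix(.BF_BACKGROUND, ny, nx)
    cal <- matrix(preset@backgroundLevel, ny, nx)
    hoe <- matrix(.HOECHST_BACKGROUND, ny, nx)
    knee <- preset@intensityProfileKnee
    core <- preset@coreIntensity
    for (i in seq_len(n)) {
      cx <- centers[i, 1] / pixelSize
      cy <- centers[i, 2] / pixelSize
      rPx <- dia[i] / 2 / pixelSize
      rvPx <- rPx * (1 - preset@deadRimFraction)
      bf <- .renderDisk(bf, cx, cy, rPx, function(rho) .BF_OBJECT)
      hoe <- .renderDisk(hoe, cx, cy, rPx, function(rho) .HOECHST_OBJECT)
      cal <- .renderDisk(cal, cx, cy, rvPx, function(rho)
        .calceinProfile(rho / rvPx, core, knee, binaryThreshold))
      if (preset@satellites) {
        rs <- 0.15 * rPx  # area 2.25% of the spheroid, well under 10%
        off <- (rPx + rs + 10 / pixelSize) / sqrt(2)
        bf <- .renderDisk(bf, cx + off, cy + off, rs, function(rho) .BF_OBJECT)
        cal <- .renderDisk(cal, cx + off, cy + off, rs, function(rho) core)
      }
    }
    addNoise <- function(m) {
      if (preset@poissonScale > 0)
        m <- matrix(stats::rpois(length(m), m * preset@poissonScale) /
                      preset@poissonScale, nrow(m), ncol(m))
      if (preset@gaussianNoiseSd > 0)
        m <- m + stats::rnorm(length(m), 0, preset@gaussianNoiseSd)
      round(pmin(pmax(m, 0), bitMax))
    }
    bf <- addNoise(bf); cal <- addNoise(cal); hoe <- addNoise(hoe)
    viable <- dia * (1 - preset@deadRimFraction)
    trueBaf <- knee^2
    truth <- data.frame(
      well_id = seq_len(n),
      true_diameter = dia,
      true_viable_diameter = viable,
      true_baf = trueBaf,
      true_imvis = (pi / 6) * viable^3 * trueBaf
    )
    list(
      images = list(
        brightfield = ChannelImage(bf, "brightfield", pixelSize, bitMax),
        calcein = ChannelImage(cal, "calcein", pixelSize, bitMax),
        hoechst = ChannelImage(hoe, "hoechst", pixelSize, bitMax)
      ),
      truth = truth
    )
  })
}
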