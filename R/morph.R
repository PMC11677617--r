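#' Maximum and minimum Feret (caliper) diameters of a binary mask
#'
#' The maximum Feret diameter is the largest caliper width of the object's
#' convex hull over all orientations; the minimum Feret diameter is the
#' smallest. Widths are computed on the convex hull of pixel centers with a
#' one-pixel allowance for the pixel footprint, so a rasterized circle of
#' diameter d pixels measures ~d in both directions. Degenerate masks (a
#' single pixel or a collinear pixel run) fall back to point-pair distances.
#'
#' @param mask logical (or 0/1) matrix; must contain at least one TRUE pixel
#'   and is expected to be a single connected component.
#' @param pixelSize micrometres per pixel (default 1, i.e. pixel units).
#' @return named numeric vector \code{c(dMax=, dMin=)} in micrometres.
#' @examples
#' m <- matrix(FALSE, 64, 64)
#' m[20:40, 25:35] <- TRUE
#' feretDiameters(m)
#' @export
feretDiameters <- function(mask, pixelSize = 1) {
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: Feret diameters are undefined")
  # pixel centers, 0-based (x = column, y = row)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n <= 2L) {
    dMax <- if (n == 1L) 0 else sqrt(sum((hp[1, ] - hp[2, ])^2))
    dMin <- 0
  } else {
    dd <- as.matrix(stats::dist(hp))
    dMax <- max(dd)
    # minimal width: for each hull edge, the largest vertex distance to the
    # edge's supporting line (all vertices lie on one side)
    nxt <- c(2:n, 1L)
    widths <- vapply(seq_len(n), function(i) {
      e <- hp[nxt[i], ] - hp[i, ]
      len <- sqrt(sum(e^2))
      if (len == 0) return(Inf)
      nrm <- c(-e[2], e[1]) / len
      max(abs((hp[, 1] - hp[i, 1]) * nrm[1] + (hp[, 2] - hp[i, 2]) * nrm[2]))
    }, numeric(1))
    dMin <- min(widths)
    if (!is.finite(dMin)) dMin <- 0  # all hull edges degenerate
  }
  c(dMax = (dMax + 1) * pixelSize, dMin = (dMin + 1) * pixelSize)
}

#' Mean diameter from the two Feret extremes
#'
#' The per-spheroid size statistic is the average of the minimum and maximum
#' measured diameters: \eqn{D_{mean} = (D_{min} + D_{max}) / 2}.
#'
#' @param dMin,dMax minimum and maximum diameters, um; both positive with
#'   \code{dMin <= dMax}.
#' @return mean diameter, um.
#' @examples
#' meanDiameter(200, 300)  # 250
#' @export
meanDiameter <- function(dMin, dMax) {
  if (any(dMin <= 0) || any(dMax <= 0))
    stop("diameters must be positive")
  if (any(dMin > dMax))
    stop("'dMin' must not exceed 'dMax'")
  (dMin + dMax) / 2
}
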