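#' Spheroid volume from the mean diameter
#'
#' Each spheroid is treated as a sphere whose diameter is the mean measured
#' diameter: \eqn{V = \frac{4}{3}\pi (D_{mean}/2)^3}.
#'
#' @param dMean mean diameter, um (>= 0).
#' @return volume in um^3.
#' @examples
#' sphereVolume(2)  # 4*pi/3
#' @export
sphereVolume <- function(dMean) {
  if (any(!is.finite(dMean)) || any(dMean < 0))
    stop("'dMean' must be non-negative")
  (4 / 3) * pi * (dMean / 2)^3
}

#' IMVIS viability index
#'
#' The indirect and mediated vitality index of a spheroid combines the
#' calcein-derived volume with the binary area fraction:
#' \eqn{IMVIS = V \times BAF}. BAF enters as a fraction in [0, 1], so IMVIS
#' carries the units of V (um^3) and is bounded by it.
#'
#' @param V calcein-positive spheroid volume, um^3 (>= 0).
#' @param BAF binary area fraction in [0, 1].
#' @return IMVIS in um^3.
#' @examples
#' imvis(sphereVolume(300), 0.5)
#' @export
imvis <- function(V, BAF) {
  if (any(!is.finite(V)) || any(V < 0)) stop("'V' must be non-negative")
  if (any(!is.finite(BAF)) || any(BAF < 0) || any(BAF > 1))
    stop("'BAF' must lie in [0, 1]")
  V * BAF
}

#' Percent change of a treated group versus its control
#'
#' \code{100 * (treated - control) / control}; negative values are decreases
#' (a result of -75 means the treated mean fell to a quarter of control).
#'
#' @param treatedMean group mean under treatment.
#' @param controlMean untreated group mean; must be > 0.
#' @return percent change.
#' @examples
#' percentChange(25, 100)  # -75
#' @export
percentChange <- function(treatedMean, controlMean) {
  if (any(!is.finite(controlMean)) || any(controlMean <= 0))
    stop("'controlMean' must be positive")
  100 * (treatedMean - controlMean) / controlMean
}
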