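# Shared fixtures and independent oracles, all built in code.

# Rasterized disk mask: pixel centers (0-based) within radius r of (cx, cy).
diskMask <- function(n, r, cx = (n - 1) / 2, cy = (n - 1) / 2) {
  xs <- 0:(n - 1)
  outer(xs, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

# Small one-chamber layout for fast synthetic scenes.
rowLayout <- function(nWells = 3L) {
  deviceLayout(1L, nWells, wellWidth = 450, wellDepth = 450, pitch = 620)
}

# Disable all noise sources on a preset (diameter spread kept unless zeroed).
noiseFree <- function(preset, sd = preset@trueDiameterSd) {
  preset@gaussianNoiseSd <- 0
  preset@poissonScale <- 0
  preset@trueDiameterSd <- sd
  preset
}

# Exhaustive-projection Feret oracle: caliper width of the pixel-center
# point set over a dense grid of orientations, plus the 1 px footprint.
bruteFeret <- function(mask, nAngles = 3600L) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  th <- seq(0, pi, length.out = nAngles)
  w <- vapply(th, function(a) {
    p <- x * cos(a) + y * sin(a)
    max(p) - min(p)
  }, numeric(1))
  c(dMax = max(w) + 1, dMin = min(w) + 1)
}

# Exact Mann-Whitney oracle: enumerate every split of the pooled values into
# groups of the observed sizes, build the null distribution of U1, and
# compute the symmetric two-tailed p the same doubling way as the test.
bruteMannWhitneyP <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u1Obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  u1Null <- apply(splits, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  pLow <- mean(u1Null <= u1Obs)
  pHigh <- mean(u1Null >= u1Obs)
  min(1, 2 * min(pLow, pHigh))
}

# Ground-truth viability index implied by a preset's constants alone.
presetTrueImvis <- function(p) {
  viable <- p@trueDiameterMean * p@looseningFactor * (1 - p@deadRimFraction)
  (pi / 6) * viable^3 * p@intensityProfileKnee^2
}
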