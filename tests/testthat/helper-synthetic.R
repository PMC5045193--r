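# shared fixture builders; everything is generated in code at test time

# small, fast calibration: default pixel/frame timing on a 128 x 128 field
smallConfig <- function(nFrames = 61L, shape = c(128L, 128L), bitScale = 255)
  imagingConfig(nFrames = nFrames, imageShape = shape, bitScale = bitScale)

# a hand-built track set with full control over every trajectory
manualTracks <- function(df, v = 0.88, durationS = 30) {
  n <- nrow(df)
  if (!"velocityUmPerS" %in% names(df)) df$velocityUmPerS <- rep(v, n)
  if (!"deathS" %in% names(df)) df$deathS <- rep(durationS, n)
  if (!"birthS" %in% names(df)) df$birthS <- rep(0, n)
  if (!"centrosome" %in% names(df)) df$centrosome <- rep(1L, n)
  df$id <- seq_len(n)
  new("CometTrackSet",
      tracks = df[, c("id", "centrosome", "birthS", "originRow", "originCol",
                      "directionDeg", "velocityUmPerS", "deathS")],
      params = cometSimParams(velocityUmPerS = max(df$velocityUmPerS, v)),
      seed = 0L, durationS = durationS)
}

# noise-free render model (continuous intensities, no PCM blob)
cleanModel <- function(...)
  renderModel(gaussianNoiseSigma = 0, poissonNoise = FALSE, quantize = FALSE,
              pcmAmplitude = 0, ...)

# brute-force oracles -------------------------------------------------------

# lattice count of pixels whose centers fall within d/2 of (cr, cc)
bruteDiscCount <- function(shape, center, diameter) {
  g <- expand.grid(r = seq_len(shape[1]), c = seq_len(shape[2]))
  sum((g$r - center[1])^2 + (g$c - center[2])^2 <= (diameter / 2)^2 + 1e-9)
}

# nearest-pixel arc sampler (tests only; the package interpolates bilinearly)
bruteArcNearest <- function(img, center, radius, spanDeg, gapCenterDeg,
                            widthPx, step = 1) {
  arcLen <- 2 * pi * radius * spanDeg / 360
  n <- floor(arcLen / step)
  a0 <- gapCenterDeg + (360 - spanDeg) / 2
  stepDeg <- (step / radius) * 180 / pi
  offs <- seq(-(widthPx - 1) / 2, (widthPx - 1) / 2, length.out = widthPx)
  vapply(seq_len(n), function(k) {
    th <- (a0 + (k - 1) * stepDeg) * pi / 180
    mean(vapply(offs, function(o) {
      r <- round(center[1] + (radius + o) * sin(th))
      c <- round(center[2] + (radius + o) * cos(th))
      img[r, c]
    }, numeric(1)))
  }, numeric(1))
}

# brute-force 8-connected component count by repeated mask erosion of seeds
bruteLabel8 <- function(mask) {
  comp <- 0L
  while (any(mask)) {
    comp <- comp + 1L
    seed <- which(mask)[1]
    grp <- seed
    repeat {
      rs <- (grp - 1) %% nrow(mask) + 1
      cs <- (grp - 1) %/% nrow(mask) + 1
      nb <- unique(unlist(lapply(seq_along(grp), function(i) {
        rr <- rs[i] + rep(-1:1, 3); cc <- cs[i] + rep(-1:1, each = 3)
        ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
        (cc[ok] - 1) * nrow(mask) + rr[ok]
      })))
      nb <- nb[mask[nb]]
      grown <- union(grp, nb)
      if (length(grown) == length(grp)) break
      grp <- grown
    }
    mask[grp] <- FALSE
  }
  comp
}
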