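#' Construct a one-cell embryo geometry
#'
#' Defaults place a ~50 x 30 um elliptical embryo in the default field of
#' view with a single centrosome at the embryo center. Positions are in
#' pixels under `config`.
#'
#' @param centerPx (row, col) of the ellipse center; default = field center.
#' @param semiAxesUm semi-axes in um, (along columns, along rows).
#' @param centrosomesPx (n x 2) matrix of centrosome positions; default one
#'   centrosome at the embryo center.
#' @param spindleAxisDeg orientation of the centrosome pair.
#' @param config an \linkS4class{ImagingConfig}.
#' @return an \linkS4class{EmbryoGeometry}. Centrosomes outside the cortex
#'   are an error.
#' @export
embryoGeometry <- function(centerPx = NULL, semiAxesUm = c(25, 15),
                           centrosomesPx = NULL, spindleAxisDeg = 0,
                           config = imagingConfig()) {
  if (is.null(centerPx))
    centerPx <- (as.numeric(config@imageShape) + 1) / 2
  if (is.null(centrosomesPx))
    centrosomesPx <- matrix(centerPx, nrow = 1)
  centrosomesPx <- as.matrix(centrosomesPx)
  a <- semiAxesUm[1] / config@pixelSizeUm
  b <- semiAxesUm[2] / config@pixelSizeUm
  u <- ((centrosomesPx[, 2] - centerPx[2]) / a)^2 +
    ((centrosomesPx[, 1] - centerPx[1]) / b)^2
  if (any(u >= 1)) stop("centrosomes must lie strictly inside the cortex ellipse")
  new("EmbryoGeometry", centerPx = as.numeric(centerPx),
      semiAxesUm = as.numeric(semiAxesUm), centrosomesPx = centrosomesPx,
      spindleAxisDeg = spindleAxisDeg)
}

#' Construct comet simulation parameters
#'
#' @param nucleationRatePerS Poisson birth rate per second per centrosome.
#' @param velocityUmPerS radial plus-end speed, um/s (0.88 is the wild-type
#'   astral growth rate in one-cell embryos; 0.70 a slowed mutant rate).
#' @param catastrophePerFrame per-frame Bernoulli termination probability.
#' @param birthRadiusPx nucleation offset from the centrosome center.
#' @param angularSectorDeg,sectorCenterDeg the angular sector comets are
#'   launched into (uniform directions).
#' @param maxLiveComets error cap on expected simultaneous comets.
#' @return a \linkS4class{CometSimParams}.
#' @export
cometSimParams <- function(nucleationRatePerS = 1.26, velocityUmPerS = 0.88,
                           catastrophePerFrame = 0, birthRadiusPx = 2,
                           angularSectorDeg = 360, sectorCenterDeg = 90,
                           maxLiveComets = 2000) {
  new("CometSimParams", nucleationRatePerS = nucleationRatePerS,
      velocityUmPerS = velocityUmPerS,
      catastrophePerFrame = catastrophePerFrame,
      birthRadiusPx = birthRadiusPx, angularSectorDeg = angularSectorDeg,
      sectorCenterDeg = sectorCenterDeg, maxLiveComets = maxLiveComets)
}

#' Construct a rendering model
#'
#' Defaults put comets (amplitude 120) safely above the comet count
#' threshold of 40 on the 0--255 working scale while background (20) plus
#' read noise (sigma 5) stays below it.
#'
#' @param cometAmplitude,cometSigmaPx comet spot peak and Gaussian sigma.
#' @param pcmAmplitude,pcmSigmaPx centrosome (PCM) blob peak and sigma.
#' @param backgroundLevel additive constant background.
#' @param gaussianNoiseSigma additive read-noise sigma.
#' @param poissonNoise resample pixels as Poisson (shot noise).
#' @param quantize round final frames to integer counts.
#' @return a \linkS4class{RenderModel}.
#' @export
renderModel <- function(cometAmplitude = 120, cometSigmaPx = 0.7,
                        pcmAmplitude = 60, pcmSigmaPx = 2,
                        backgroundLevel = 20, gaussianNoiseSigma = 5,
                        poissonNoise = TRUE, quantize = TRUE) {
  new("RenderModel", cometAmplitude = cometAmplitude,
      cometSigmaPx = cometSigmaPx, pcmAmplitude = pcmAmplitude,
      pcmSigmaPx = pcmSigmaPx, backgroundLevel = backgroundLevel,
      gaussianNoiseSigma = gaussianNoiseSigma, poissonNoise = poissonNoise,
      quantize = quantize)
}

## distance (px) from a point to the cortex ellipse along a ray; Inf if the
## ray never leaves (should not happen for points inside)
.rayToCortex <- function(origin, dirRC, geometry, config) {
  a <- geometry@semiAxesUm[1] / config@pixelSizeUm
  b <- geometry@semiAxesUm[2] / config@pixelSizeUm
  ## solve ((c0 + s*dc)/a)^2 + ((r0 + s*dr)/b)^2 = 1
  r0 <- origin[1] - geometry@centerPx[1]
  c0 <- origin[2] - geometry@centerPx[2]
  dr <- dirRC[1]; dc <- dirRC[2]
  A <- (dc / a)^2 + (dr / b)^2
  B <- 2 * (c0 * dc / a^2 + r0 * dr / b^2)
  C <- (c0 / a)^2 + (r0 / b)^2 - 1
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(Inf)
  s <- (-B + sqrt(disc)) / (2 * A)
  if (s < 0) Inf else s
}

#' Simulate ground-truth comet trajectories
#'
#' Births are a homogeneous Poisson process at the nucleation rate per
#' centrosome; directions are uniform in the configured sector; each comet
#' starts `birthRadiusPx` from its centrosome and moves radially outward at
#' constant speed until per-frame catastrophe, the cortex, or the end of the
#' recording. Identical (params, geometry, duration, seed) reproduce the
#' track set exactly.
#'
#' @param params a \linkS4class{CometSimParams}.
#' @param geometry an \linkS4class{EmbryoGeometry}; NULL simulates without a
#'   cortex (comets die only by catastrophe or recording end).
#' @param durationS recording duration, seconds (> 0).
#' @param config an \linkS4class{ImagingConfig}.
#' @param seed integer seed.
#' @return a \linkS4class{CometTrackSet}.
#' @export
simulateComets <- function(params, geometry = NULL, durationS = 30,
                           config = imagingConfig(), seed = 1L) {
  if (durationS <= 0) stop("durationS must be > 0")
  lam <- params@nucleationRatePerS
  v <- params@velocityUmPerS
  vpx <- v / config@pixelSizeUm
  dt <- config@frameIntervalS
  centros <- if (is.null(geometry)) {
    matrix((as.numeric(config@imageShape) + 1) / 2, nrow = 1)
  } else geometry@centrosomesPx
  ## cap: expected live comets per centrosome = lam * E[lifetime]
  meanLife <- if (params@catastrophePerFrame > 0)
    dt / params@catastrophePerFrame else durationS
  if (lam * meanLife * nrow(centros) > params@maxLiveComets)
    stop("expected live comets exceed maxLiveComets cap; reduce the nucleation rate")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    idc <- 0L
    for (ci in seq_len(nrow(centros))) {
      n <- stats::rpois(1, lam * durationS)
      if (n == 0) next
      birth <- sort(stats::runif(n, 0, durationS))
      ang <- params@sectorCenterDeg +
        stats::runif(n, -params@angularSectorDeg / 2, params@angularSectorDeg / 2)
      dv <- .dirVec(ang)
      origin <- cbind(centros[ci, 1] + params@birthRadiusPx * dv[, 1],
                      centros[ci, 2] + params@birthRadiusPx * dv[, 2])
      death <- rep(durationS, n)
      if (params@catastrophePerFrame > 0) {
        ## comet survives a Geometric number of frame boundaries after birth
        surv <- stats::rgeom(n, prob = params@catastrophePerFrame)
        tcat <- (floor(birth / dt) + surv + 1) * dt
        death <- pmin(death, tcat)
      }
      if (!is.null(geometry)) {
        tcx <- vapply(seq_len(n), function(i) {
          s <- .rayToCortex(origin[i, ], dv[i, ], geometry, config)
          birth[i] + s / vpx
        }, numeric(1))
        death <- pmin(death, tcx)
      }
      rows[[ci]] <- data.frame(
        id = idc + seq_len(n), centrosome = ci, birthS = birth,
        originRow = origin[, 1], originCol = origin[, 2],
        directionDeg = ang, velocityUmPerS = v, deathS = pmax(death, birth))
      idc <- idc + n
    }
    tr <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = integer(), centrosome = integer(), birthS = numeric(),
                 originRow = numeric(), originCol = numeric(),
                 directionDeg = numeric(), velocityUmPerS = numeric(),
                 deathS = numeric())
    new("CometTrackSet", tracks = tr, params = params,
        seed = as.integer(seed), durationS = durationS)
  })
}

#' Comet positions at a time point
#'
#' @param trackSet a \linkS4class{CometTrackSet}.
#' @param timeS time in seconds.
#' @param config an \linkS4class{ImagingConfig} (for um/s -> px/s).
#' @return data.frame of live comets with columns \code{id}, \code{row},
#'   \code{col}.
#' @export
cometPositions <- function(trackSet, timeS, config = imagingConfig()) {
  tr <- trackSet@tracks
  live <- tr$birthS <= timeS & tr$deathS >= timeS
  tr <- tr[live, , drop = FALSE]
  if (!nrow(tr))
    return(data.frame(id = integer(), row = numeric(), col = numeric()))
  dpx <- (tr$velocityUmPerS / config@pixelSizeUm) * (timeS - tr$birthS)
  dv <- .dirVec(tr$directionDeg)
  data.frame(id = tr$id, row = tr$originRow + dpx * dv[, 1],
             col = tr$originCol + dpx * dv[, 2])
}

#' Ground-truth arc crossings
#'
#' Number of tracks whose radial distance from the given center passes the
#' arc radius during the window (and, if the arc is partial, whose direction
#' lies on the arc). With no catastrophe and no cortex every comet crosses
#' every concentric arc with radius above its birth radius exactly once.
#'
#' @param trackSet a \linkS4class{CometTrackSet}.
#' @param center (row, col) of the arc center (the centrosome).
#' @param radiusPx arc radius.
#' @param window numeric (start, end) seconds; crossings with time in
#'   [start, end) are counted.
#' @param config an \linkS4class{ImagingConfig}.
#' @param spanDeg,gapCenterDeg angular extent of the arc (default full
#'   circle).
#' @return integer crossing count.
#' @export
expectedArcCrossings <- function(trackSet, center, radiusPx,
                                 window = c(0, Inf),
                                 config = imagingConfig(),
                                 spanDeg = 360, gapCenterDeg = 0) {
  tr <- trackSet@tracks
  if (!nrow(tr)) return(0L)
  vpx <- tr$velocityUmPerS / config@pixelSizeUm
  r0 <- sqrt((tr$originRow - center[1])^2 + (tr$originCol - center[2])^2)
  tc <- tr$birthS + (radiusPx - r0) / vpx
  ok <- radiusPx >= r0 & tc >= window[1] & tc < window[2] & tc <= tr$deathS
  if (spanDeg < 360) {
    a0 <- gapCenterDeg + (360 - spanDeg) / 2
    rel <- (tr$directionDeg - a0) %% 360
    ok <- ok & rel <= spanDeg
  }
  sum(ok)
}
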