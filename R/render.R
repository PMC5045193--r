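## add a Gaussian spot to `img` in place-ish (returns modified matrix);
## only the +-4 sigma patch is touched
.addSpot <- function(img, row, col, amplitude, sigma) {
  if (amplitude <= 0 || sigma <= 0) return(img)
  H <- nrow(img); W <- ncol(img)
  R <- ceiling(4 * sigma)
  r0 <- max(1L, floor(row - R)); r1 <- min(H, ceiling(row + R))
  c0 <- max(1L, floor(col - R)); c1 <- min(W, ceiling(col + R))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  patch <- amplitude * exp(-outer((rr - row)^2, (cc - col)^2, "+") /
                             (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + patch
  img
}

## noise-free frame at time t: background + PCM blobs + live comet spots
.renderCleanFrame <- function(timeS, trackSet, model, config, geometry) {
  shape <- config@imageShape
  img <- matrix(model@backgroundLevel, shape[1], shape[2])
  centros <- if (is.null(geometry)) {
    matrix((as.numeric(shape) + 1) / 2, nrow = 1)
  } else geometry@centrosomesPx
  if (model@pcmAmplitude > 0)
    for (i in seq_len(nrow(centros)))
      img <- .addSpot(img, centros[i, 1], centros[i, 2],
                      model@pcmAmplitude, model@pcmSigmaPx)
  pos <- cometPositions(trackSet, timeS, config)
  for (i in seq_len(nrow(pos)))
    img <- .addSpot(img, pos$row[i], pos$col[i],
                    model@cometAmplitude, model@cometSigmaPx)
  img
}

.applyNoise <- function(img, model, bitScale) {
  if (model@poissonNoise)
    img <- matrix(stats::rpois(length(img), lambda = pmax(img, 0)),
                  nrow(img), ncol(img))
  if (model@gaussianNoiseSigma > 0)
    img <- img + stats::rnorm(length(img), 0, model@gaussianNoiseSigma)
  img <- pmin(pmax(img, 0), bitScale)
  if (model@quantize) img <- round(img)
  img
}

#' Render a synthetic comet movie
#'
#' Each frame is background + PCM blobs + one Gaussian spot per live comet,
#' then optional Poisson resampling, additive Gaussian noise, clipping to
#' \code{[0, bitScale]} and integer quantization. The returned ground truth
#' keeps the track set and the noise-free reference stack.
#'
#' @param trackSet a \linkS4class{CometTrackSet} (track times must fit the
#'   recording).
#' @param model a \linkS4class{RenderModel}.
#' @param config an \linkS4class{ImagingConfig}; frames are rendered at
#'   times \code{(0:(nFrames-1)) * frameIntervalS}.
#' @param geometry an \linkS4class{EmbryoGeometry} or NULL; provides PCM
#'   blob positions.
#' @param seed integer seed for the noise.
#' @return list with elements \code{stack} (the noisy
#'   \linkS4class{ImageStack}) and \code{groundTruth} (list: \code{tracks},
#'   \code{reference} noise-free stack, \code{pcmPositions}).
#' @export
renderMovie <- function(trackSet, model = renderModel(),
                        config = imagingConfig(), geometry = NULL,
                        seed = 1L) {
  nT <- config@nFrames
  dt <- config@frameIntervalS
  recLen <- nT * dt
  tr <- trackSet@tracks
  if (nrow(tr) && any(tr$birthS > recLen))
    warning("some comets are born after the last frame")
  shape <- config@imageShape
  clean <- array(0, dim = c(nT, 1, 1, shape[1], shape[2]))
  for (t in seq_len(nT))
    clean[t, 1, 1, , ] <- .renderCleanFrame((t - 1) * dt, trackSet, model,
                                            config, geometry)
  noisy <- withr::with_seed(as.integer(seed), {
    out <- clean
    for (t in seq_len(nT))
      out[t, 1, 1, , ] <- .applyNoise(matrix(clean[t, 1, 1, , ],
                                             shape[1], shape[2]),
                                      model, config@bitScale)
    out
  })
  centros <- if (is.null(geometry))
    matrix((as.numeric(shape) + 1) / 2, nrow = 1) else geometry@centrosomesPx
  list(
    stack = new("ImageStack", data = noisy, config = config,
                channelNames = "EB"),
    groundTruth = list(
      tracks = trackSet,
      reference = new("ImageStack", data = clean, config = config,
                      channelNames = "EB"),
      pcmPositions = centros))
}

#' Render a fixed-cell multi-channel z-stack
#'
#' Emulates immunofluorescence z-stacks: each blob is brightest at its
#' designated focal plane and attenuated on neighboring planes by an axial
#' Gaussian factor \code{exp(-(z - focal)^2 / (2 * axialSigmaPlanes^2))}.
#'
#' @param scene data.frame with columns \code{row}, \code{col},
#'   \code{channel} (integer), \code{amplitude}, \code{sigmaPx},
#'   \code{focalPlane} (1-based z index).
#' @param model a \linkS4class{RenderModel} (background and noise terms are
#'   used; spot amplitudes come from the scene).
#' @param config an \linkS4class{ImagingConfig}.
#' @param nZ number of z planes (>= 1).
#' @param nChannels number of channels; default = max channel in the scene.
#' @param axialSigmaPlanes axial Gaussian sigma in planes.
#' @param seed integer seed for the noise.
#' @return list with \code{stack} (t = 1) and \code{groundTruth} (the scene
#'   and the noise-free reference stack).
#' @export
renderIFScene <- function(scene, model = renderModel(),
                          config = imagingConfig(), nZ = 5L,
                          nChannels = NULL, axialSigmaPlanes = 1,
                          seed = 1L) {
  if (nZ < 1) stop("nZ must be >= 1")
  if (is.null(nChannels))
    nChannels <- if (nrow(scene)) max(scene$channel) else 1L
  shape <- config@imageShape
  clean <- array(model@backgroundLevel,
                 dim = c(1, nZ, nChannels, shape[1], shape[2]))
  for (z in seq_len(nZ)) for (ch in seq_len(nChannels)) {
    img <- matrix(clean[1, z, ch, , ], shape[1], shape[2])
    sel <- which(scene$channel == ch)
    for (i in sel) {
      att <- exp(-(z - scene$focalPlane[i])^2 / (2 * axialSigmaPlanes^2))
      img <- .addSpot(img, scene$row[i], scene$col[i],
                      scene$amplitude[i] * att, scene$sigmaPx[i])
    }
    clean[1, z, ch, , ] <- img
  }
  noisy <- withr::with_seed(as.integer(seed), {
    out <- clean
    for (z in seq_len(nZ)) for (ch in seq_len(nChannels))
      out[1, z, ch, , ] <- .applyNoise(matrix(clean[1, z, ch, , ],
                                              shape[1], shape[2]),
                                       model, config@bitScale)
    out
  })
  cfg <- config
  cfg@nFrames <- 1L
  chn <- paste0("ch", seq_len(nChannels))
  list(
    stack = new("ImageStack", data = noisy, config = cfg, channelNames = chn),
    groundTruth = list(
      scene = scene,
      reference = new("ImageStack", data = clean, config = cfg,
                      channelNames = chn)))
}
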