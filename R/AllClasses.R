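#' @import methods
NULL

#' Imaging calibration
#'
#' Physical calibration of an acquisition: pixel size, frame interval, number
#' of frames, the working intensity scale and the frame shape in pixels. The
#' defaults reproduce spinning-disk confocal recordings of one-cell
#' \emph{C. elegans} embryos: 0.151 um/pixel, 500 ms/frame, 61 frames, an
#' 8-bit (0--255) working scale and a field large enough to hold a
#' ~50 x 30 um embryo.
#'
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot frameIntervalS seconds between consecutive frames (> 0).
#' @slot nFrames number of time points (>= 1).
#' @slot bitScale maximum representable intensity of the working scale (> 0);
#'   intensities are kept as floating point on \code{[0, bitScale]}.
#' @slot imageShape integer (rows, cols) of one frame.
#' @exportClass ImagingConfig
setClass("ImagingConfig",
  representation(
    pixelSizeUm = "numeric",
    frameIntervalS = "numeric",
    nFrames = "integer",
    bitScale = "numeric",
    imageShape = "integer"
  ),
  prototype(
    pixelSizeUm = 0.151,
    frameIntervalS = 0.5,
    nFrames = 61L,
    bitScale = 255,
    imageShape = c(199L, 331L)
  )
)

setValidity("ImagingConfig", function(object) {
  msg <- character()
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(object@frameIntervalS) != 1 || !is.finite(object@frameIntervalS) ||
      object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a single positive number")
  if (length(object@nFrames) != 1 || is.na(object@nFrames) || object@nFrames < 1)
    msg <- c(msg, "nFrames must be >= 1")
  if (length(object@bitScale) != 1 || !is.finite(object@bitScale) ||
      object@bitScale <= 0)
    msg <- c(msg, "bitScale must be a single positive number")
  if (length(object@imageShape) != 2 || any(is.na(object@imageShape)) ||
      any(object@imageShape < 1))
    msg <- c(msg, "imageShape must be two positive integers (rows, cols)")
  if (length(msg)) msg else TRUE
})

#' Calibrated fluorescence image stack
#'
#' A five-dimensional nonnegative intensity array indexed
#' \code{(t, z, c, y, x)} together with its \linkS4class{ImagingConfig} and
#' channel labels. Singleton axes are permitted, so a single 2-D image is a
#' stack with \code{t = z = c = 1}.
#'
#' @slot data numeric array with \code{dim = c(t, z, c, rows, cols)}.
#' @slot config the \linkS4class{ImagingConfig} of the acquisition.
#' @slot channelNames character vector, one label per channel.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    data = "array",
    config = "ImagingConfig",
    channelNames = "character"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 5)
    msg <- c(msg, "data must be a 5-D array (t, z, c, y, x)")
  else {
    if (any(object@data < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be >= 0")
    if (!identical(d[4:5], as.integer(object@config@imageShape)))
      msg <- c(msg, sprintf(
        "frame shape (%d, %d) does not match config imageShape (%d, %d)",
        d[4], d[5], object@config@imageShape[1], object@config@imageShape[2]))
    if (length(object@channelNames) != d[3])
      msg <- c(msg, "channelNames length must equal the channel axis extent")
  }
  if (length(msg)) msg else TRUE
})

## Measurement region geometries. RegionSpec is virtual; the four concrete
## kinds mirror the regions drawn in the underlying assays: discs for
## centrosomal / centriolar / cytoplasmic means, near-full or semicircular
## arcs around centrosomes, line segments along comet tracks, and an
## inward-offset ring following the cell cortex.

#' Measurement region (virtual base class)
#'
#' @seealso [discRegion()], [arcRegion()], [lineRegion()],
#'   [polygonOffsetRegion()]
#' @exportClass RegionSpec
setClass("RegionSpec", representation("VIRTUAL"))

#' @slot center numeric (row, col) pixel coordinates; fractional allowed.
#' @slot diameterPx disc diameter in pixels. A pixel belongs to the disc iff
#'   the distance from its center to the region center is <= diameterPx / 2.
#' @rdname RegionSpec-class
#' @exportClass DiscRegion
setClass("DiscRegion", contains = "RegionSpec",
  representation(center = "numeric", diameterPx = "numeric"))

setValidity("DiscRegion", function(object) {
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    return("center must be finite (row, col)")
  if (object@diameterPx <= 0) return("diameterPx must be > 0")
  TRUE
})

#' @slot radiusPx arc radius in pixels (> 0).
#' @slot spanDeg angular span of the arc in degrees, in (0, 360]. The default
#'   355 leaves a 5 degree excluded wedge.
#' @slot gapCenterDeg direction (degrees) of the center of the excluded
#'   wedge; 0 points along +x (increasing column).
#' @slot widthPx radial sampling width in pixels (>= 1).
#' @rdname RegionSpec-class
#' @exportClass ArcRegion
setClass("ArcRegion", contains = "RegionSpec",
  representation(center = "numeric", radiusPx = "numeric", spanDeg = "numeric",
                 gapCenterDeg = "numeric", widthPx = "numeric"))

setValidity("ArcRegion", function(object) {
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    return("center must be finite (row, col)")
  if (object@radiusPx <= 0) return("radiusPx must be > 0")
  if (object@spanDeg <= 0 || object@spanDeg > 360)
    return("spanDeg must lie in (0, 360]")
  if (object@widthPx < 1) return("widthPx must be >= 1")
  TRUE
})

#' @slot from,to numeric (row, col) endpoints of the segment.
#' @rdname RegionSpec-class
#' @exportClass LineRegion
setClass("LineRegion", contains = "RegionSpec",
  representation(from = "numeric", to = "numeric", widthPx = "numeric"))

setValidity("LineRegion", function(object) {
  if (length(object@from) != 2 || length(object@to) != 2 ||
      any(!is.finite(c(object@from, object@to))))
    return("from and to must be finite (row, col) points")
  if (all(object@from == object@to)) return("line endpoints must differ")
  if (object@widthPx < 1) return("widthPx must be >= 1")
  TRUE
})

#' @slot vertices numeric matrix (n x 2) of (row, col) polygon vertices,
#'   ordered along the boundary (open; the closing edge is implicit).
#' @slot offsetPx inward offset from the polygon boundary in pixels (>= 0).
#' @rdname RegionSpec-class
#' @exportClass PolygonOffsetRegion
setClass("PolygonOffsetRegion", contains = "RegionSpec",
  representation(vertices = "matrix", offsetPx = "numeric", widthPx = "numeric"))

setValidity("PolygonOffsetRegion", function(object) {
  if (ncol(object@vertices) != 2 || nrow(object@vertices) < 3)
    return("vertices must be an (n >= 3) x 2 matrix of (row, col) points")
  if (any(!is.finite(object@vertices))) return("vertices must be finite")
  if (object@offsetPx < 0) return("offsetPx must be >= 0")
  if (object@widthPx < 1) return("widthPx must be >= 1")
  TRUE
})

#' One-cell embryo geometry
#'
#' An elliptical cortex (default ~50 x 30 um, i.e. semi-axes 25 x 15 um)
#' with one or two centrosomes strictly inside it.
#'
#' @slot centerPx (row, col) of the ellipse center in pixels.
#' @slot semiAxesUm ellipse semi-axes in micrometres, (along columns, along
#'   rows).
#' @slot centrosomesPx numeric matrix (n x 2) of centrosome (row, col)
#'   positions in pixels.
#' @slot spindleAxisDeg orientation of the centrosome pair in degrees.
#' @exportClass EmbryoGeometry
setClass("EmbryoGeometry",
  representation(centerPx = "numeric", semiAxesUm = "numeric",
                 centrosomesPx = "matrix", spindleAxisDeg = "numeric"))

#' Comet simulation parameters
#'
#' Parameters of the plus-end comet birth/death process. Births are a
#' homogeneous Poisson process per centrosome; directions are uniform in an
#' angular sector; each comet moves radially at constant speed and dies by a
#' per-frame Bernoulli catastrophe, on reaching the cortex, or at the end of
#' the recording.
#'
#' @slot nucleationRatePerS mean comet births per second per centrosome (>= 0).
#' @slot velocityUmPerS radial plus-end speed in um/s (> 0).
#' @slot catastrophePerFrame probability in [0, 1) that a comet terminates at
#'   each frame boundary after birth.
#' @slot birthRadiusPx radial offset of nucleation from the centrosome center.
#' @slot angularSectorDeg width of the sector into which directions are drawn
#'   uniformly (default 360).
#' @slot sectorCenterDeg direction of the sector center (degrees).
#' @slot maxLiveComets cap on the expected number of simultaneously live
#'   comets; exceeding it is an error (prevents degenerate renders).
#' @exportClass CometSimParams
setClass("CometSimParams",
  representation(nucleationRatePerS = "numeric", velocityUmPerS = "numeric",
                 catastrophePerFrame = "numeric", birthRadiusPx = "numeric",
                 angularSectorDeg = "numeric", sectorCenterDeg = "numeric",
                 maxLiveComets = "numeric"))

setValidity("CometSimParams", function(object) {
  msg <- character()
  if (object@nucleationRatePerS < 0) msg <- c(msg, "nucleationRatePerS must be >= 0")
  if (object@velocityUmPerS <= 0) msg <- c(msg, "velocityUmPerS must be > 0")
  if (object@catastrophePerFrame < 0 || object@catastrophePerFrame >= 1)
    msg <- c(msg, "catastrophePerFrame must lie in [0, 1)")
  if (object@birthRadiusPx < 0) msg <- c(msg, "birthRadiusPx must be >= 0")
  if (object@angularSectorDeg <= 0 || object@angularSectorDeg > 360)
    msg <- c(msg, "angularSectorDeg must lie in (0, 360]")
  if (length(msg)) msg else TRUE
})

#' Rendering model for synthetic movies and z-stacks
#'
#' Comets are rendered as isotropic Gaussian spots (point-like plus-end
#' signal; no comet tail), centrosomes as wider Gaussian PCM blobs, on a
#' constant background with optional Poisson resampling (shot noise) and
#' additive Gaussian read noise. Rendered intensities are clipped to
#' \code{[0, bitScale]} and, by default, quantized to integer camera counts.
#'
#' @slot cometAmplitude peak intensity added by one comet (working-scale units).
#' @slot cometSigmaPx isotropic Gaussian sigma of a comet spot, pixels. The
#'   default 0.7 px (~0.11 um) is the diffraction-limited spot of a high-NA
#'   objective at GFP wavelengths sampled at 0.151 um/px.
#' @slot pcmAmplitude,pcmSigmaPx amplitude and sigma of the centrosome blob.
#' @slot backgroundLevel additive constant background.
#' @slot gaussianNoiseSigma sigma of the additive Gaussian read-noise term.
#' @slot poissonNoise logical; resample each pixel as Poisson with its
#'   noise-free mean before adding Gaussian noise.
#' @slot quantize logical; round the final frame to integer counts.
#' @exportClass RenderModel
setClass("RenderModel",
  representation(cometAmplitude = "numeric", cometSigmaPx = "numeric",
                 pcmAmplitude = "numeric", pcmSigmaPx = "numeric",
                 backgroundLevel = "numeric", gaussianNoiseSigma = "numeric",
                 poissonNoise = "logical", quantize = "logical"))

setValidity("RenderModel", function(object) {
  vals <- c(object@cometAmplitude, object@cometSigmaPx, object@pcmAmplitude,
            object@pcmSigmaPx, object@backgroundLevel, object@gaussianNoiseSigma)
  if (any(!is.finite(vals)) || any(vals < 0))
    return("all amplitudes, sigmas and noise levels must be finite and >= 0")
  TRUE
})

#' Ground-truth comet trajectories
#'
#' One row per comet: birth time, origin, direction, velocity and death time,
#' plus the generating parameters and seed. A comet's position at time t is
#' \code{origin + v * (t - birth)} along its direction, for t in
#' [birth, death].
#'
#' @slot tracks data.frame with columns \code{id}, \code{centrosome},
#'   \code{birthS}, \code{originRow}, \code{originCol}, \code{directionDeg},
#'   \code{velocityUmPerS}, \code{deathS}.
#' @slot params the generating \linkS4class{CometSimParams}.
#' @slot seed integer seed used for the simulation.
#' @slot durationS simulated duration in seconds.
#' @exportClass CometTrackSet
setClass("CometTrackSet",
  representation(tracks = "data.frame", params = "CometSimParams",
                 seed = "integer", durationS = "numeric"))

setValidity("CometTrackSet", function(object) {
  need <- c("id", "centrosome", "birthS", "originRow", "originCol",
            "directionDeg", "velocityUmPerS", "deathS")
  if (!all(need %in% names(object@tracks)))
    return(paste("tracks must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@tracks) &&
      any(object@tracks$deathS < object@tracks$birthS, na.rm = TRUE))
    return("deathS must be >= birthS for every track")
  TRUE
})

#' Kymograph
#'
#' A 2-D resampling of a movie along an arc or line region: one row per frame
#' in the analysis window, one column per sample position along the region.
#'
#' @slot data numeric matrix (time rows x positions).
#' @slot region the source \linkS4class{RegionSpec}.
#' @slot windowS numeric (start, end) of the window in seconds; frames with
#'   time in [start, end) are included.
#' @slot stepPx arc length (or line length) per column, pixels.
#' @slot frameTimesS acquisition time of each row, seconds.
#' @exportClass Kymograph
setClass("Kymograph",
  representation(data = "matrix", region = "RegionSpec", windowS = "numeric",
                 stepPx = "numeric", frameTimesS = "numeric"))

setValidity("Kymograph", function(object) {
  if (nrow(object@data) != length(object@frameTimesS))
    return("rows must equal the number of frame times")
  TRUE
})
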