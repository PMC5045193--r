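#' @name kymoMT-accessors
#' @title Accessors for kymoMT classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object a kymoMT S4 object.
#' @return the corresponding slot value.
NULL

#' @rdname kymoMT-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("bitScale", function(object) standardGeneric("bitScale"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("imageShape", function(object) standardGeneric("imageShape"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("imagingConfigOf", function(object) standardGeneric("imagingConfigOf"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("kymoData", function(object) standardGeneric("kymoData"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("nTracks", function(object) standardGeneric("nTracks"))
#' @rdname kymoMT-accessors
#' @export
setGeneric("centrosomes", function(object) standardGeneric("centrosomes"))

setMethod("pixelSize", "ImagingConfig", function(object) object@pixelSizeUm)
setMethod("frameInterval", "ImagingConfig", function(object) object@frameIntervalS)
setMethod("nFrames", "ImagingConfig", function(object) object@nFrames)
setMethod("bitScale", "ImagingConfig", function(object) object@bitScale)
setMethod("imageShape", "ImagingConfig", function(object) object@imageShape)

setMethod("pixelSize", "ImageStack", function(object) object@config@pixelSizeUm)
setMethod("frameInterval", "ImageStack", function(object) object@config@frameIntervalS)
setMethod("nFrames", "ImageStack", function(object) dim(object@data)[1])
setMethod("bitScale", "ImageStack", function(object) object@config@bitScale)
setMethod("imageShape", "ImageStack", function(object) dim(object@data)[4:5])
setMethod("stackData", "ImageStack", function(object) object@data)
setMethod("imagingConfigOf", "ImageStack", function(object) object@config)
setMethod("channelNames", "ImageStack", function(object) object@channelNames)

setMethod("kymoData", "Kymograph", function(object) object@data)
setMethod("tracks", "CometTrackSet", function(object) object@tracks)
setMethod("nTracks", "CometTrackSet", function(object) nrow(object@tracks))
setMethod("centrosomes", "EmbryoGeometry", function(object) object@centrosomesPx)

setMethod("show", "ImagingConfig", function(object) {
  cat("ImagingConfig:", object@pixelSizeUm, "um/px,",
      object@frameIntervalS, "s/frame,", object@nFrames, "frames,",
      "scale 0 -", object@bitScale, "\n")
  cat("  frame shape:", object@imageShape[1], "x", object@imageShape[2], "px\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: t=%d z=%d c=%d, %d x %d px (%s)\n",
              d[1], d[2], d[3], d[4], d[5],
              paste(object@channelNames, collapse = ", ")))
  cat(sprintf("  %.3f um/px, %.3g s/frame, intensities [%.3g, %.3g]\n",
              object@config@pixelSizeUm, object@config@frameIntervalS,
              min(object@data), max(object@data)))
})

setMethod("show", "DiscRegion", function(object) {
  cat(sprintf("DiscRegion: center (%.2f, %.2f), diameter %.2f px\n",
              object@center[1], object@center[2], object@diameterPx))
})

setMethod("show", "ArcRegion", function(object) {
  cat(sprintf(
    "ArcRegion: center (%.2f, %.2f), radius %.1f px, span %.0f deg (gap at %.0f deg), width %g px\n",
    object@center[1], object@center[2], object@radiusPx, object@spanDeg,
    object@gapCenterDeg, object@widthPx))
})

setMethod("show", "LineRegion", function(object) {
  cat(sprintf("LineRegion: (%.2f, %.2f) -> (%.2f, %.2f), length %.2f px, width %g px\n",
              object@from[1], object@from[2], object@to[1], object@to[2],
              sqrt(sum((object@to - object@from)^2)), object@widthPx))
})

setMethod("show", "PolygonOffsetRegion", function(object) {
  cat(sprintf("PolygonOffsetRegion: %d vertices, inward offset %.1f px, width %g px\n",
              nrow(object@vertices), object@offsetPx, object@widthPx))
})

setMethod("show", "CometTrackSet", function(object) {
  cat(sprintf("CometTrackSet: %d comets over %.1f s (seed %d)\n",
              nrow(object@tracks), object@durationS, object@seed))
  if (nrow(object@tracks))
    cat(sprintf("  velocity %.2f um/s, nucleation %.3g /s, catastrophe %.3g /frame\n",
                object@params@velocityUmPerS, object@params@nucleationRatePerS,
                object@params@catastrophePerFrame))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d frames x %d positions, window [%.2f, %.2f) s, step %g px\n",
              nrow(object@data), ncol(object@data), object@windowS[1],
              object@windowS[2], object@stepPx))
})

setMethod("show", "EmbryoGeometry", function(object) {
  cat(sprintf("EmbryoGeometry: ellipse %g x %g um at (%.1f, %.1f) px, %d centrosome(s)\n",
              object@semiAxesUm[1], object@semiAxesUm[2], object@centerPx[1],
              object@centerPx[2], nrow(object@centrosomesPx)))
})
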