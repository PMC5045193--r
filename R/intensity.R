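#' Region-based intensity measurement with focal-plane selection
#'
#' Evaluates the disc-mean on every z-plane of the stack and reports the
#' plane with the highest mean (ties broken toward the lowest plane index),
#' following the standard centrosomal quantification protocol: the average
#' intensity within a 25-px-diameter disc centered on the centrosome, taken
#' at the focal plane where that average is maximal. Use a 5-px disc for
#' centriolar signal and a same-size disc in the cytoplasm or outside the
#' embryo for cytoplasmic/background measurements.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param region a \linkS4class{DiscRegion}.
#' @param channel,t channel and time indices (1-based).
#' @param label free-text identifier (embryo/centrosome).
#' @param compartment one of "centrosomal", "centriolar", "cytoplasmic",
#'   "background".
#' @param plane optional fixed z plane; when given, no plane search is done.
#' @return one-row data.frame: \code{label}, \code{compartment},
#'   \code{channel}, \code{plane}, \code{mean}, \code{nPixels},
#'   \code{clipped} (TRUE if part of the disc fell outside the image; the
#'   mean then covers in-frame pixels only).
#' @export
measureRegion <- function(stack, region, channel = 1L, t = 1L,
                          label = "", compartment = "centrosomal",
                          plane = NULL) {
  if (!is(region, "DiscRegion"))
    stop("measureRegion expects a disc region")
  d <- dim(stack@data)
  mask <- maskPixels(d[4:5], region)
  if (isTRUE(attr(mask, "outside")))
    stop("measurement region lies entirely outside the image")
  clipped <- isTRUE(attr(mask, "clipped"))
  zs <- if (is.null(plane)) seq_len(d[2]) else as.integer(plane)
  means <- vapply(zs, function(z) {
    mean(matrix(stack@data[t, z, channel, , ], d[4], d[5])[mask])
  }, numeric(1))
  best <- which.max(means)   # ties -> lowest index
  data.frame(label = label, compartment = compartment, channel = channel,
             plane = zs[best], mean = means[best], nPixels = sum(mask),
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Background measurement outside the embryo
#'
#' Same-size disc mean on a stated plane (by default the plane paired with
#' the foreground measurement). If an embryo geometry is supplied and the
#' disc intersects the embryo, a warning is recorded and the measurement is
#' still returned (column \code{overlapsEmbryo}).
#'
#' @inheritParams measureRegion
#' @param plane z plane to measure on; defaults to plane 1. Pair it with the
#'   chosen plane of the corresponding foreground measurement.
#' @param geometry optional \linkS4class{EmbryoGeometry} used to check the
#'   region lies outside the embryo.
#' @return one-row data.frame as [measureRegion()], plus
#'   \code{overlapsEmbryo}.
#' @export
measureBackground <- function(stack, region, channel = 1L, t = 1L,
                              plane = 1L, label = "", geometry = NULL) {
  overlaps <- FALSE
  if (!is.null(geometry)) {
    cfg <- stack@config
    a <- geometry@semiAxesUm[1] / cfg@pixelSizeUm
    b <- geometry@semiAxesUm[2] / cfg@pixelSizeUm
    u <- ((region@center[2] - geometry@centerPx[2]) / a)^2 +
      ((region@center[1] - geometry@centerPx[1]) / b)^2
    ## closest-approach check on the disc center vs an ellipse shrunk by the
    ## disc radius is conservative enough for background placement
    if (sqrt(u) < 1 + region@diameterPx / (2 * min(a, b))) {
      warning("background region overlaps (or touches) the embryo")
      overlaps <- TRUE
    }
  }
  m <- measureRegion(stack, region, channel = channel, t = t, label = label,
                     compartment = "background", plane = plane)
  m$overlapsEmbryo <- overlaps
  m
}

#' Fold change of background-subtracted group means
#'
#' Each measurement is background-subtracted (signal minus its paired
#' background); the fold change is the ratio of the sample-group mean to the
#' control-group mean. Per-sample ratios to the control mean are retained
#' and their SD reported as the dispersion. Adding a constant to every pixel
#' of all stacks leaves the ratio unchanged; a nonpositive control mean is a
#' quantification failure and an error.
#'
#' @param samples,controls data.frames with numeric columns \code{signal}
#'   and \code{background} (one row per embryo/centrosome), or numeric
#'   vectors of already-subtracted values.
#' @return object of class \code{"foldChange"}: list with \code{ratio},
#'   \code{numeratorMean}, \code{denominatorMean}, \code{nNum}, \code{nDen},
#'   \code{dispersion}, \code{sampleRatios}.
#' @export
foldChange <- function(samples, controls) {
  netOf <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("signal", "background") %in% names(x)))
      x$signal - x$background
    } else as.numeric(x)
  }
  netS <- netOf(samples)
  netC <- netOf(controls)
  if (!length(netS) || !length(netC))
    stop("need at least one sample and one control pair")
  mC <- mean(netC)
  if (!is.finite(mC) || mC <= 0)
    stop("nonpositive control mean after background subtraction")
  ratios <- netS / mC
  out <- list(ratio = mean(netS) / mC, numeratorMean = mean(netS),
              denominatorMean = mC, nNum = length(netS),
              nDen = length(netC),
              dispersion = if (length(netS) > 1) stats::sd(ratios) else NA_real_,
              sampleRatios = ratios)
  class(out) <- "foldChange"
  out
}

#' @export
print.foldChange <- function(x, ...) {
  cat(sprintf("Fold change: %.3f (n = %d vs %d controls), dispersion SD %.3f\n",
              x$ratio, x$nNum, x$nDen, x$dispersion))
  invisible(x)
}
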