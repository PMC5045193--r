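#' Create an imaging calibration
#'
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalS seconds per frame.
#' @param nFrames number of time points.
#' @param bitScale maximum intensity of the working scale. Intensities are
#'   handled as floating point on \code{[0, bitScale]}; the default 0--255
#'   scale is the one on which the comet count threshold of 40 is defined.
#' @param imageShape integer (rows, cols) of a frame.
#' @return an \linkS4class{ImagingConfig}.
#' @examples
#' cfg <- imagingConfig()
#' umToPx(1.5, cfg)   # 1.5 um inside the cortex is ~10 px
#' @export
imagingConfig <- function(pixelSizeUm = 0.151, frameIntervalS = 0.5,
                          nFrames = 61L, bitScale = 255,
                          imageShape = c(199L, 331L)) {
  new("ImagingConfig", pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS, nFrames = as.integer(nFrames),
      bitScale = bitScale, imageShape = as.integer(imageShape))
}

#' Convert between pixels and micrometres
#'
#' `pxToUm(umToPx(x))` is the identity for all representable x.
#'
#' @param x value(s) to convert.
#' @param config an \linkS4class{ImagingConfig}.
#' @return converted numeric vector.
#' @export
pxToUm <- function(x, config = imagingConfig()) x * config@pixelSizeUm

#' @rdname pxToUm
#' @export
umToPx <- function(x, config = imagingConfig()) x / config@pixelSizeUm

#' Construct an image stack
#'
#' Accepts a 2-D matrix (one frame), a 3-D array (t, y, x) or a full 5-D
#' array (t, z, c, y, x); missing axes become singletons.
#'
#' @param data numeric array of intensities (>= 0).
#' @param config an \linkS4class{ImagingConfig}; its \code{imageShape} and
#'   \code{nFrames} are adjusted to the data if they disagree.
#' @param channelNames labels for the channel axis.
#' @return an \linkS4class{ImageStack}.
#' @export
imageStack <- function(data, config = imagingConfig(), channelNames = NULL) {
  d <- dim(data)
  if (is.null(d) || length(d) == 2) {
    data <- array(data, dim = c(1L, 1L, 1L, dim(as.matrix(data))))
  } else if (length(d) == 3) {
    data <- array(data, dim = c(d[1], 1L, 1L, d[2], d[3]))
  } else if (length(d) != 5) {
    stop("data must be 2-D (y, x), 3-D (t, y, x) or 5-D (t, z, c, y, x)")
  }
  d <- dim(data)
  cfg <- config
  cfg@imageShape <- as.integer(d[4:5])
  cfg@nFrames <- as.integer(d[1])
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(d[3]))
  new("ImageStack", data = data, config = cfg,
      channelNames = as.character(channelNames))
}

#' Extract one 2-D frame
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param t,z,channel indices (1-based) on the time, z and channel axes.
#' @return a numeric matrix (rows x cols).
#' @export
getFrame <- function(stack, t = 1L, z = 1L, channel = 1L) {
  d <- dim(stack@data)
  if (t < 1 || t > d[1]) stop("frame index t out of range")
  if (z < 1 || z > d[2]) stop("z index out of range")
  if (channel < 1 || channel > d[3]) stop("channel index out of range")
  matrix(stack@data[t, z, channel, , ], nrow = d[4], ncol = d[5])
}

.sidecarPath <- function(path) paste0(path, ".json")

#' Write an image stack as a multi-page TIFF
#'
#' Pages are ordered t (slowest), then z, then channel (fastest). Axis
#' lengths, calibration and channel names are written to a JSON sidecar
#' (\code{<path>.json}) so that [readStack()] can reconstruct the stack
#' without guessing; plain multi-page TIFFs from other sources are read with
#' axis lengths supplied by the caller.
#'
#' Stacks whose intensities are all integers on a 0--255 scale are stored as
#' 8-bit and round-trip bit-exactly; all other stacks are stored as 32-bit
#' float (relative precision ~1e-7).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @param metadata write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, metadata = TRUE) {
  d <- dim(stack@data)
  bs <- stack@config@bitScale
  intlike <- bs == 255 && max(stack@data) <= 255 &&
    isTRUE(all.equal(as.vector(stack@data), round(as.vector(stack@data)),
                     tolerance = 0, check.attributes = FALSE))
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    pages[[k]] <- matrix(stack@data[t, z, ch, , ], d[4], d[5]) / bs
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = if (intlike) 8L else 32L,
                  compression = "none", reduce = FALSE)
  if (metadata) {
    meta <- list(
      axes = list(t = d[1], z = d[2], c = d[3], y = d[4], x = d[5]),
      pixelSizeUm = stack@config@pixelSizeUm,
      frameIntervalS = stack@config@frameIntervalS,
      bitScale = bs,
      channelNames = stack@channelNames,
      storage = if (intlike) "uint8" else "float32")
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are assumed ordered t, then z, then channel (channel fastest), as
#' written by [writeStack()]. When a JSON metadata sidecar (\code{<path>.json})
#' is present its axis lengths and calibration override `config` (a message
#' records the override); otherwise the page count together with `nZ` and
#' `nChannels` determines the time axis, which must divide evenly or the
#' ambiguous axis is reported as an error.
#'
#' @param path TIFF file path.
#' @param config an \linkS4class{ImagingConfig} supplying calibration
#'   defaults.
#' @param nZ,nChannels axis lengths used when no sidecar is present.
#' @param channelNames optional channel labels.
#' @return an \linkS4class{ImageStack}; intensities on \code{[0, bitScale]}.
#' @export
readStack <- function(path, config = imagingConfig(), nZ = 1L,
                      nChannels = 1L, channelNames = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nPages <- length(pages)
  bs <- config@bitScale
  meta <- NULL
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    nZ <- meta$axes$z
    nChannels <- meta$axes$c
    if (!is.null(meta$pixelSizeUm) &&
        meta$pixelSizeUm != config@pixelSizeUm) {
      message(sprintf("readStack: pixel size %g um from metadata overrides config (%g um)",
                      meta$pixelSizeUm, config@pixelSizeUm))
    }
    config@pixelSizeUm <- meta$pixelSizeUm %||% config@pixelSizeUm
    config@frameIntervalS <- meta$frameIntervalS %||% config@frameIntervalS
    bs <- meta$bitScale %||% bs
    if (is.null(channelNames)) channelNames <- meta$channelNames
  }
  if (nPages %% (nZ * nChannels) != 0)
    stop(sprintf(
      "ambiguous axis layout: %d pages do not factor into z=%d x c=%d (time axis)",
      nPages, nZ, nChannels))
  nT <- nPages %/% (nZ * nChannels)
  ## readTIFF returns [0,1]; 8-bit pages carry exact k/255 values, so
  ## round to the stored integer grid before rescaling to the working scale
  stored8 <- !is.null(meta) && identical(meta$storage, "uint8")
  shape <- dim(pages[[1]])[1:2]
  arr <- array(0, dim = c(nT, nZ, nChannels, shape[1], shape[2]))
  k <- 1L
  for (t in seq_len(nT)) for (z in seq_len(nZ)) for (ch in seq_len(nChannels)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]   # collapse unexpected samples
    v <- if (stored8) round(pg * 255) * (bs / 255) else pg * bs
    arr[t, z, ch, , ] <- v
    k <- k + 1L
  }
  config@imageShape <- as.integer(shape)
  config@nFrames <- as.integer(nT)
  config@bitScale <- bs
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nChannels))
  new("ImageStack", data = arr, config = config,
      channelNames = as.character(channelNames))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
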