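## frames whose acquisition time falls in [window[1], window[2])
.framesInWindow <- function(config, window) {
  times <- (seq_len(config@nFrames) - 1) * config@frameIntervalS
  idx <- which(times >= window[1] & times < window[2])
  if (!length(idx)) stop("analysis window contains no frames")
  list(idx = idx, times = times[idx])
}

#' Maximum-intensity time projection
#'
#' Pixel-wise maximum over the frames of a window (10 frames for the
#' conventional 5-s window at 500 ms/frame); growing plus-end comets leave
#' their tracks as bright lines.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param window numeric (start, end) seconds; default the first 5 s.
#' @param z,channel plane and channel indices.
#' @return numeric matrix (rows x cols).
#' @export
timeProjection <- function(stack, window = c(0, 5), z = 1L, channel = 1L) {
  fw <- .framesInWindow(stack@config, window)
  d <- dim(stack@data)
  proj <- matrix(-Inf, d[4], d[5])
  for (t in fw$idx)
    proj <- pmax(proj, matrix(stack@data[t, z, channel, , ], d[4], d[5]))
  proj
}

#' Build a kymograph along an arc or line
#'
#' Row t of the kymograph is the sampled intensity profile of frame t along
#' the region; the conventional analysis uses a 355-degree arc of radius
#' 35 px around the centrosome over the first 5 s of the recording.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param region an \linkS4class{ArcRegion} or \linkS4class{LineRegion}.
#' @param window numeric (start, end) seconds.
#' @param step arc length (or line distance) per column, pixels.
#' @param z,channel plane and channel indices.
#' @return a \linkS4class{Kymograph}.
#' @export
buildKymograph <- function(stack, region, window = c(0, 5), step = 1,
                           z = 1L, channel = 1L) {
  fw <- .framesInWindow(stack@config, window)
  sampler <- if (is(region, "ArcRegion")) sampleArc
    else if (is(region, "LineRegion")) sampleLine
    else stop("buildKymograph expects an arc or line region")
  rows <- lapply(fw$idx, function(t)
    sampler(getFrame(stack, t = t, z = z, channel = channel), region,
            step = step)$value)
  new("Kymograph", data = do.call(rbind, rows), region = region,
      windowS = as.numeric(window), stepPx = step, frameTimesS = fw$times)
}

#' Average linescan profile of a kymograph
#'
#' Per-column mean across the time rows: the average signal at every
#' position along the arc over the analysis window.
#'
#' @param kym a \linkS4class{Kymograph}.
#' @return data.frame with \code{positionPx} (arc length from the profile
#'   start) and \code{mean}.
#' @export
linescanProfile <- function(kym) {
  if (!length(kym@data)) stop("empty kymograph")
  data.frame(positionPx = (seq_len(ncol(kym@data)) - 1) * kym@stepPx,
             mean = colMeans(kym@data, na.rm = TRUE))
}

#' Microtubule nucleation intensity at a centrosome
#'
#' Mean intensity of a 5-px-wide semicircular linescan (default radius
#' 25 px) around the centrosome, measured on the maximum-intensity time
#' projection of the window and background-subtracted with an identically
#' shaped linescan placed in the cytoplasm.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param center centrosome (row, col), pixels.
#' @param backgroundCenter (row, col) of the cytoplasmic reference
#'   semicircle; required.
#' @param radiusPx,widthPx semicircle radius and linescan width.
#' @param facingDeg direction the semicircle opens toward.
#' @param window numeric (start, end) seconds for the projection.
#' @param z,channel plane and channel indices.
#' @return list: \code{net}, \code{signal}, \code{background},
#'   \code{region}, \code{backgroundRegion}.
#' @export
nucleationIntensity <- function(stack, center, backgroundCenter,
                                radiusPx = 25, widthPx = 5, facingDeg = 90,
                                window = c(0, 5), z = 1L, channel = 1L) {
  if (missing(backgroundCenter) || is.null(backgroundCenter))
    stop("a cytoplasmic background region center is required")
  proj <- timeProjection(stack, window = window, z = z, channel = channel)
  reg <- semicircleRegion(center, radiusPx, facingDeg, widthPx)
  bgReg <- semicircleRegion(backgroundCenter, radiusPx, facingDeg, widthPx)
  sig <- mean(sampleArc(proj, reg)$value, na.rm = TRUE)
  bg <- mean(sampleArc(proj, bgReg)$value, na.rm = TRUE)
  list(net = sig - bg, signal = sig, background = bg, region = reg,
       backgroundRegion = bgReg)
}

## --- suprathreshold structure of a kymograph -------------------------------

## 8-connected component labelling (BFS); returns the number of components
.labelComponents8 <- function(mask) {
  mask[is.na(mask)] <- FALSE
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L; c <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && !lab[rr, cc]) {
          lab[(cc - 1L) * H + rr] <- cur
          queue <- c(queue, (cc - 1L) * H + rr)
        }
      }
    }
  }
  cur
}

## local maxima (>= all 8 neighbours) above `threshold`, then greedy
## suppression of maxima within Chebyshev distance `minSeparation`
.kymoPeaks <- function(K, threshold, minSeparation = 1L) {
  K[is.na(K)] <- -Inf
  H <- nrow(K); W <- ncol(K)
  isMax <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(-Inf, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    sh[rs, cs] <- K[rs - dr, cs - dc]
    isMax <- isMax & (K >= sh)
  }
  cand <- which(isMax & K > threshold, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  ord <- order(K[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i] || i == nrow(cand)) next
    j <- (i + 1):nrow(cand)
    d <- pmax(abs(cand[j, 1] - cand[i, 1]), abs(cand[j, 2] - cand[i, 2]))
    keep[j[d <= minSeparation]] <- FALSE
  }
  cand[keep, , drop = FALSE]
}

#' Count comet crossing events in a kymograph
#'
#' Pixels above the count threshold (40 on the 0--255 working scale) are
#' tallied three ways: the raw suprathreshold pixel count; the number of
#' 8-connected components of the suprathreshold mask; and the number of
#' events resolved as local intensity maxima above the threshold separated
#' by more than `minSeparation` kymograph cells. At low comet density the
#' component and event counts agree; at high density overlapping crossings
#' merge components, and the peak-resolved \code{nEvents} is the faithful
#' "number of growing microtubules" (it is also render-scale invariant,
#' which the pixel count is not).
#'
#' @param kym a \linkS4class{Kymograph}.
#' @param threshold intensity threshold on the working scale.
#' @param minSeparation peak suppression radius, kymograph cells (Chebyshev).
#' @param role which arc the kymograph came from ("proximal", "midpoint",
#'   "cortex", ...), carried through to the result.
#' @return object of class \code{"cometCount"}: list with \code{nEvents},
#'   \code{nComponents}, \code{nPixels}, \code{threshold}, \code{role},
#'   \code{window}, \code{peaks} (matrix of peak row/col indices).
#' @export
countCometEvents <- function(kym, threshold = 40, minSeparation = 1L,
                             role = "proximal") {
  mask <- kym@data > threshold
  peaks <- .kymoPeaks(kym@data, threshold, minSeparation)
  out <- list(nEvents = nrow(peaks), nComponents = .labelComponents8(mask),
              nPixels = sum(mask, na.rm = TRUE), threshold = threshold,
              role = role, window = kym@windowS, peaks = peaks)
  class(out) <- "cometCount"
  out
}

#' @export
print.cometCount <- function(x, ...) {
  cat(sprintf("%s comet count over [%.1f, %.1f) s: %d events (%d components, %d px > %g)\n",
              x$role, x$window[1], x$window[2], x$nEvents, x$nComponents,
              x$nPixels, x$threshold))
  invisible(x)
}

#' Count comets crossing an offset ring inside the cortex
#'
#' Builds a kymograph along the contour offset `offsetPx` inward from the
#' cortex polygon (1.5 um = 10 px at the default calibration) and counts
#' crossing events as local maxima above the threshold with a minimum
#' separation -- an automated stand-in for manual dot counting.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param cortex a \linkS4class{PolygonOffsetRegion}, or an
#'   \linkS4class{EmbryoGeometry} whose elliptical cortex is used with
#'   `offsetPx`.
#' @param offsetPx inward offset, pixels (used when `cortex` is a geometry).
#' @param window numeric (start, end) seconds.
#' @param threshold,minSeparation as in [countCometEvents()].
#' @param step contour length per kymograph column, pixels.
#' @param z,channel plane and channel indices.
#' @return a \code{"cometCount"} (role "cortex") with the kymograph attached
#'   as attribute \code{kymograph}.
#' @export
countCortexCrossings <- function(stack, cortex, offsetPx = 10,
                                 window = c(0, 5), threshold = 40,
                                 minSeparation = 2L, step = 1,
                                 z = 1L, channel = 1L) {
  if (is(cortex, "EmbryoGeometry")) {
    poly <- ellipsePolygon(cortex, stack@config)
    cortex <- polygonOffsetRegion(poly, offsetPx)
  }
  if (!is(cortex, "PolygonOffsetRegion"))
    stop("cortex must be a PolygonOffsetRegion or EmbryoGeometry")
  path <- .offsetContour(cortex@vertices, cortex@offsetPx, step = step)
  fw <- .framesInWindow(stack@config, window)
  ## sample a width-px band normal to the contour
  m <- nrow(path)
  prv <- path[c(m, seq_len(m - 1)), ]
  nxt <- path[c(seq_len(m - 1) + 1, 1), ]
  tang <- nxt - prv
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2], tang[, 1])
  w <- as.integer(round(cortex@widthPx))
  offs <- seq(-(w - 1) / 2, (w - 1) / 2, length.out = w)
  K <- matrix(NA_real_, length(fw$idx), m)
  for (i in seq_along(fw$idx)) {
    img <- getFrame(stack, t = fw$idx[i], z = z, channel = channel)
    vals <- matrix(NA_real_, m, w)
    for (j in seq_len(w))
      vals[, j] <- bilinearAt(img, path[, 1] + offs[j] * nrm[, 1],
                              path[, 2] + offs[j] * nrm[, 2])
    K[i, ] <- rowMeans(vals, na.rm = TRUE)
  }
  kym <- new("Kymograph", data = K,
             region = cortex, windowS = as.numeric(window), stepPx = step,
             frameTimesS = fw$times)
  res <- countCometEvents(kym, threshold = threshold,
                          minSeparation = minSeparation, role = "cortex")
  attr(res, "kymograph") <- kym
  res
}

#' Microtubule polymerization rate from a kymograph slope
#'
#' A 4.5-um line is drawn along a single comet track; the line kymograph is
#' built, the comet position in each time row is estimated as the
#' intensity-weighted centroid of the suprathreshold samples, and the
#' velocity is the least-squares slope of position (um) against time (s).
#' Rows whose suprathreshold run touches either end of the line (partially
#' visible spot) are excluded, and the track is taken as the longest
#' consecutive run of comet-present rows, which rejects isolated
#' noise-triggered rows outside the comet's transit; fewer than 3 usable
#' rows is an error.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param trackLine a \linkS4class{LineRegion} of length ~4.5 um (a warning
#'   is issued beyond 10% off).
#' @param window numeric (start, end) seconds; default the whole recording.
#' @param threshold intensity threshold for comet presence.
#' @param step samples per pixel of line length.
#' @param z,channel plane and channel indices.
#' @return list: \code{velocityUmPerS}, \code{residualRmsPx},
#'   \code{nTimePoints}, \code{fit} (the lm object), \code{region}.
#' @export
polymerizationRate <- function(stack, trackLine, window = NULL,
                               threshold = 40, step = 1, z = 1L,
                               channel = 1L) {
  if (!is(trackLine, "LineRegion"))
    stop("trackLine must be a LineRegion")
  cfg <- stack@config
  Lum <- sqrt(sum((trackLine@to - trackLine@from)^2)) * cfg@pixelSizeUm
  if (abs(Lum - 4.5) > 0.45)
    warning(sprintf("track line is %.2f um long; the standard length is 4.5 um", Lum))
  if (is.null(window))
    window <- c(0, cfg@nFrames * cfg@frameIntervalS)
  kym <- buildKymograph(stack, trackLine, window = window, step = step,
                        z = z, channel = channel)
  K <- kym@data
  n <- ncol(K)
  pos <- rep(NA_real_, nrow(K))
  for (i in seq_len(nrow(K))) {
    sel <- which(K[i, ] > threshold)
    if (!length(sel)) next
    if (min(sel) == 1L || max(sel) == n) next  # spot truncated at line end
    wgt <- K[i, sel]
    pos[i] <- sum((sel - 1) * step * wgt) / sum(wgt)
  }
  ## the track is the longest consecutive run of comet-present rows;
  ## isolated suprathreshold rows elsewhere are noise, not the comet
  runs <- rle(!is.na(pos))
  if (!any(runs$values))
    stop("comet present in fewer than 3 kymograph rows; insufficient track")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  use <- starts[best]:ends[best]
  if (length(use) < 3)
    stop("comet present in fewer than 3 kymograph rows; insufficient track")
  tS <- kym@frameTimesS[use]
  posUm <- pos[use] * cfg@pixelSizeUm
  fit <- stats::lm(posUm ~ tS)
  vel <- abs(unname(stats::coef(fit)[2]))
  list(velocityUmPerS = vel,
       residualRmsPx = sqrt(mean(stats::residuals(fit)^2)) / cfg@pixelSizeUm,
       nTimePoints = length(use), fit = fit, region = trackLine)
}
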