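#' Measurement region constructors
#'
#' Regions are specified in pixel coordinates: 1-based (row, col) with pixel
#' (i, j) occupying the unit square centered on the integer point (i, j).
#' Fractional centers are allowed; all distances are computed between pixel
#' centers.
#'
#' @param center numeric (row, col).
#' @param diameterPx disc diameter in pixels. The field's standard choices
#'   are 25 px for centrosomal/cytoplasmic regions, 5 px for centriolar
#'   regions and 60 px for cytoplasmic colocalization regions.
#' @return a \linkS4class{RegionSpec} subclass instance.
#' @examples
#' disc <- discRegion(c(50, 50), 25)
#' sum(maskPixels(c(100, 100), disc))  # 489 pixels
#' @export
discRegion <- function(center, diameterPx = 25) {
  new("DiscRegion", center = as.numeric(center), diameterPx = diameterPx)
}

#' @param radiusPx arc radius in pixels.
#' @param spanDeg angular span in degrees, in (0, 360]; 355 leaves the
#'   conventional 5 degree gap, 180 gives a semicircle.
#' @param gapCenterDeg direction of the excluded wedge center (0 = +x,
#'   toward increasing column).
#' @param widthPx radial sampling width (number of 1-px-spaced radial
#'   offsets averaged per sample).
#' @rdname discRegion
#' @export
arcRegion <- function(center, radiusPx, spanDeg = 355, gapCenterDeg = 0,
                      widthPx = 5) {
  new("ArcRegion", center = as.numeric(center), radiusPx = radiusPx,
      spanDeg = spanDeg, gapCenterDeg = gapCenterDeg, widthPx = widthPx)
}

#' @param facingDeg direction the semicircle opens toward (its midpoint).
#' @rdname discRegion
#' @export
semicircleRegion <- function(center, radiusPx = 25, facingDeg = 90,
                             widthPx = 5) {
  arcRegion(center, radiusPx, spanDeg = 180,
            gapCenterDeg = facingDeg + 180, widthPx = widthPx)
}

#' @param from,to line endpoints, (row, col).
#' @rdname discRegion
#' @export
lineRegion <- function(from, to, widthPx = 1) {
  new("LineRegion", from = as.numeric(from), to = as.numeric(to),
      widthPx = widthPx)
}

#' @param vertices (n x 2) matrix of (row, col) boundary points, ordered.
#' @param offsetPx inward offset from the boundary, pixels.
#' @rdname discRegion
#' @export
polygonOffsetRegion <- function(vertices, offsetPx, widthPx = 3) {
  new("PolygonOffsetRegion", vertices = as.matrix(vertices),
      offsetPx = offsetPx, widthPx = widthPx)
}

## --- bilinear interpolation ------------------------------------------------

#' Bilinear interpolation at sub-pixel positions
#'
#' Values are defined at pixel centers (integer coordinates) and
#' interpolated bilinearly between them; positions outside the image return
#' NA.
#'
#' @param img numeric matrix.
#' @param row,col numeric vectors of positions.
#' @return numeric vector of interpolated values (NA outside the image).
#' @export
bilinearAt <- function(img, row, col) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= H & col >= 1 & col <= W &
    is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0
  v <- (1 - fr) * (1 - fc) * img[i00] +
    fr * (1 - fc) * img[i00 + 1] +
    (1 - fr) * fc * img[i00 + H] +
    fr * fc * img[i00 + H + 1]
  out[ok] <- v
  out
}

## --- pixel masks -----------------------------------------------------------

#' Pixel membership mask of a region
#'
#' For a disc, exactly the pixels whose centers lie within
#' \code{diameterPx / 2} of the region center. For a polygon-offset region,
#' the ~1-px-wide ring of pixels inside the polygon at distance
#' \code{offsetPx} from its boundary. A region entirely outside the image
#' yields an empty mask with attribute \code{outside = TRUE} and a warning.
#'
#' @param shape integer (rows, cols) of the image.
#' @param region a \linkS4class{DiscRegion} or
#'   \linkS4class{PolygonOffsetRegion}.
#' @return logical matrix of dimension `shape`, with attribute
#'   \code{clipped} if part of the region fell outside the image.
#' @export
maskPixels <- function(shape, region) {
  if (is(region, "DiscRegion")) return(.maskDisc(shape, region))
  if (is(region, "PolygonOffsetRegion")) return(.maskPolygonOffset(shape, region))
  stop("maskPixels supports disc and polygon-offset regions")
}

.maskDisc <- function(shape, region) {
  H <- shape[1]; W <- shape[2]
  r <- region@diameterPx / 2
  cr <- region@center[1]; cc <- region@center[2]
  rows <- max(1, floor(cr - r)):min(H, ceiling(cr + r))
  mask <- matrix(FALSE, H, W)
  clipped <- cr - r < 1 || cr + r > H || cc - r < 1 || cc + r > W
  if (cr + r < 1 || cr - r > H || cc + r < 1 || cc - r > W) {
    warning("region lies entirely outside the image; empty mask")
    attr(mask, "outside") <- TRUE
    return(mask)
  }
  cols <- max(1, floor(cc - r)):min(W, ceiling(cc + r))
  d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
  mask[rows, cols] <- d2 <= r^2 + 1e-9
  if (clipped) attr(mask, "clipped") <- TRUE
  mask
}

.maskPolygonOffset <- function(shape, region) {
  H <- shape[1]; W <- shape[2]
  mask <- matrix(FALSE, H, W)
  v <- region@vertices
  rows <- seq_len(H); cols <- seq_len(W)
  pts <- cbind(rep(rows, times = W), rep(cols, each = H))
  inside <- .pointInPolygon(pts[, 1], pts[, 2], v)
  db <- .distToPolygonBoundary(pts[, 1], pts[, 2], v)
  sel <- inside & abs(db - region@offsetPx) <= 0.5
  mask[cbind(pts[sel, 1], pts[sel, 2])] <- TRUE
  if (!any(sel)) {
    warning("offset ring contains no pixels inside the image")
    attr(mask, "outside") <- TRUE
  }
  mask
}

## even-odd ray casting; vertices open polygon (closing edge implicit)
.pointInPolygon <- function(pr, pc, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    vi <- v[i, ]; vj <- v[j, ]
    cross <- ((vi[1] > pr) != (vj[1] > pr)) &
      (pc < (vj[2] - vi[2]) * (pr - vi[1]) / (vj[1] - vi[1]) + vi[2])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

.distToPolygonBoundary <- function(pr, pc, v) {
  n <- nrow(v)
  d2 <- rep(Inf, length(pr))
  j <- n
  for (i in seq_len(n)) {
    a <- v[j, ]; b <- v[i, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dr <- pr - (a[1] + t * ab[1]); dc <- pc - (a[2] + t * ab[2])
    d2 <- pmin(d2, dr^2 + dc^2)
    j <- i
  }
  sqrt(d2)
}

## --- arc and line sampling -------------------------------------------------

## direction deg -> unit (row, col); 0 deg = +col, angles increase toward +row
.dirVec <- function(deg) {
  th <- deg * pi / 180
  cbind(sin(th), cos(th))
}

#' Sample image intensity along a circular arc
#'
#' Samples are placed at uniform angular spacing equivalent to `step` pixels
#' of arc length at the nominal radius, starting adjacent to the excluded
#' wedge and proceeding in the direction of increasing angle. Each sample is
#' the mean of bilinear interpolations at `widthPx` points spaced 1 px
#' radially, centered on the nominal radius. The profile has
#' \code{floor(arcLength / step)} samples.
#'
#' @param img numeric matrix (one frame).
#' @param region an \linkS4class{ArcRegion}.
#' @param step arc length per sample, pixels.
#' @return data.frame with columns \code{value}, \code{angleDeg},
#'   \code{row}, \code{col} (point on the nominal radius) and \code{oob}
#'   (TRUE when any contributing point fell outside the image; such samples
#'   average the in-frame points only, or are NA if all points were outside).
#' @export
sampleArc <- function(img, region, step = 1) {
  r <- region@radiusPx
  if (r <= 0) stop("arc radius must be > 0")
  span <- region@spanDeg
  if (span <= 0) stop("arc span must be positive (wedge covers the circle)")
  arcLen <- 2 * pi * r * span / 360
  n <- floor(arcLen / step)
  if (n < 1) stop("arc shorter than one sample step")
  a0 <- region@gapCenterDeg + (360 - span) / 2
  stepDeg <- (step / r) * 180 / pi
  angles <- a0 + (seq_len(n) - 1) * stepDeg
  w <- as.integer(round(region@widthPx))
  offs <- seq(-(w - 1) / 2, (w - 1) / 2, length.out = w)
  dv <- .dirVec(angles)              # n x 2
  cr <- region@center[1]; cc <- region@center[2]
  ## n*w interpolation points: radius (r+off) along each angle
  radii <- rep(r + offs, each = n)
  rowp <- cr + radii * rep(dv[, 1], times = w)
  colp <- cc + radii * rep(dv[, 2], times = w)
  vals <- matrix(bilinearAt(img, rowp, colp), nrow = n, ncol = w)
  value <- rowMeans(vals, na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  oob <- apply(vals, 1, anyNA)
  data.frame(value = value, angleDeg = angles,
             row = cr + r * dv[, 1], col = cc + r * dv[, 2], oob = oob)
}

#' Sample image intensity along a line segment
#'
#' Samples are placed every `step` pixels from `from` to `to` (both ends
#' included when they fall on the step grid); each sample averages
#' `widthPx` bilinear interpolations spaced 1 px perpendicular to the line.
#'
#' @inheritParams sampleArc
#' @param region a \linkS4class{LineRegion}.
#' @return data.frame with columns \code{value}, \code{distPx}, \code{row},
#'   \code{col}, \code{oob}.
#' @export
sampleLine <- function(img, region, step = 1) {
  p0 <- region@from; p1 <- region@to
  L <- sqrt(sum((p1 - p0)^2))
  n <- floor(L / step) + 1
  u <- (p1 - p0) / L
  perp <- c(-u[2], u[1])
  w <- as.integer(round(region@widthPx))
  offs <- seq(-(w - 1) / 2, (w - 1) / 2, length.out = w)
  dist <- (seq_len(n) - 1) * step
  base_r <- p0[1] + dist * u[1]
  base_c <- p0[2] + dist * u[2]
  rowp <- rep(base_r, times = w) + rep(offs, each = n) * perp[1]
  colp <- rep(base_c, times = w) + rep(offs, each = n) * perp[2]
  vals <- matrix(bilinearAt(img, rowp, colp), nrow = n, ncol = w)
  value <- rowMeans(vals, na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  data.frame(value = value, distPx = dist, row = base_r, col = base_c,
             oob = apply(vals, 1, anyNA))
}

## --- polygon offset path (for cortex-offset kymographs) --------------------

#' Polygon approximation of an embryo's elliptical cortex
#'
#' @param geometry an \linkS4class{EmbryoGeometry}.
#' @param config an \linkS4class{ImagingConfig} (for um -> px).
#' @param n number of vertices.
#' @return (n x 2) matrix of (row, col) vertices, counterclockwise.
#' @export
ellipsePolygon <- function(geometry, config = imagingConfig(), n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  a <- geometry@semiAxesUm[1] / config@pixelSizeUm  # along columns
  b <- geometry@semiAxesUm[2] / config@pixelSizeUm  # along rows
  cbind(geometry@centerPx[1] + b * sin(th),
        geometry@centerPx[2] + a * cos(th))
}

## ordered points on the inward-offset contour of a convex polygon,
## resampled to uniform spacing `step` (px); normals from neighbor tangents
.offsetContour <- function(vertices, offsetPx, step = 1) {
  v <- vertices
  n <- nrow(v)
  if (n < 3) stop("degenerate polygon")
  ## densify edges to ~1 px spacing
  dens <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1, ceiling(len))
    s <- (seq_len(k) - 1) / k
    cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
  }))
  m <- nrow(dens)
  if (m < 3) stop("degenerate polygon")
  centroid <- colMeans(dens)
  prv <- dens[c(m, seq_len(m - 1)), ]
  nxt <- dens[c(seq_len(m - 1) + 1, 1), ]
  tang <- nxt - prv
  tl <- sqrt(rowSums(tang^2))
  tang <- tang / tl
  nrm <- cbind(-tang[, 2], tang[, 1])
  flip <- rowSums(nrm * (matrix(centroid, m, 2, byrow = TRUE) - dens)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  path <- dens + offsetPx * nrm
  ## resample to uniform arc length
  seg <- sqrt(rowSums((path - path[c(m, seq_len(m - 1)), ])^2))
  seg[1] <- 0
  s <- cumsum(seg)
  total <- s[m] + sqrt(sum((path[1, ] - path[m, ])^2))
  ns <- max(3, floor(total / step))
  target <- (seq_len(ns) - 1) * total / ns
  ri <- approx(s, path[, 1], xout = pmin(target, s[m]), rule = 2)$y
  ci <- approx(s, path[, 2], xout = pmin(target, s[m]), rule = 2)$y
  cbind(ri, ci)
}

## --- region JSON exchange --------------------------------------------------

.regionToList <- function(region) {
  if (is(region, "DiscRegion"))
    list(kind = "disc", center = region@center, diameter_px = region@diameterPx)
  else if (is(region, "ArcRegion"))
    list(kind = "arc", center = region@center, radius_px = region@radiusPx,
         arc_span_deg = region@spanDeg, arc_gap_center_deg = region@gapCenterDeg,
         width_px = region@widthPx)
  else if (is(region, "LineRegion"))
    list(kind = "line", endpoints = list(region@from, region@to),
         width_px = region@widthPx)
  else if (is(region, "PolygonOffsetRegion"))
    list(kind = "polygon-offset",
         vertices = lapply(seq_len(nrow(region@vertices)),
                           function(i) region@vertices[i, ]),
         offset_px = region@offsetPx, width_px = region@widthPx)
  else stop("unknown region class")
}

.regionFromList <- function(x) {
  switch(x$kind,
    disc = discRegion(unlist(x$center), x$diameter_px),
    arc = arcRegion(unlist(x$center), x$radius_px,
                    spanDeg = x$arc_span_deg %||% 355,
                    gapCenterDeg = x$arc_gap_center_deg %||% 0,
                    widthPx = x$width_px %||% 5),
    line = lineRegion(unlist(x$endpoints[[1]]), unlist(x$endpoints[[2]]),
                      widthPx = x$width_px %||% 1),
    `polygon-offset` = polygonOffsetRegion(
      do.call(rbind, lapply(x$vertices, unlist)),
      x$offset_px, widthPx = x$width_px %||% 3),
    stop("unknown region kind: ", x$kind))
}

#' Read and write measurement regions as JSON
#'
#' Regions are exchanged as an array of JSON records with fields mirroring
#' the region classes (\code{kind}, \code{center}, \code{diameter_px},
#' \code{radius_px}, \code{arc_span_deg}, ...).
#'
#' @param regions a list of \linkS4class{RegionSpec} objects (named lists
#'   become named JSON records).
#' @param path JSON file path.
#' @return `readRegions` returns a list of regions; `writeRegions` its path,
#'   invisibly.
#' @export
writeRegions <- function(regions, path) {
  jsonlite::write_json(lapply(regions, .regionToList), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRegions
#' @export
readRegions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, .regionFromList)
}
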