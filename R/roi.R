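#' Closed polygon region of interest
#'
#' Constructs a closed polygon ROI in pixel coordinates. Pixels are addressed
#' by the coordinates of their centers: `x` is the column index and `y` the
#' row index of an image matrix, both 1-based, so the center of `image[i, j]`
#' is at `(x = j, y = i)`. A pixel belongs to the polygon iff its center lies
#' inside it under the even-odd rule; centers falling exactly on the boundary
#' are counted as inside.
#'
#' @param x,y Numeric vectors of vertex coordinates (equal length, >= 3).
#'   The polygon is closed implicitly; do not repeat the first vertex.
#' @return An object of class `roi_polygon`.
#' @examples
#' sq <- roi_polygon(c(2, 6, 6, 2), c(2, 2, 6, 6))
#' @export
roi_polygon <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("a polygon needs at least 3 vertices")
  if (anyNA(x) || anyNA(y)) stop("polygon vertices must be finite")
  if (length(x) > 3 && .poly_self_intersects(x, y))
    stop("polygon is self-intersecting")
  structure(list(x = x, y = y), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %d vertices, bbox x [%.6g, %.6g] y [%.6g, %.6g]\n",
              length(x$x), min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

# Segment-intersection test over non-adjacent edges (small ROIs only).
.poly_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  seg_int <- function(ax, ay, bx, by, cx, cy, dx, dy) {
    o <- function(px, py, qx, qy, rx, ry) {
      v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
      sign(v)
    }
    o1 <- o(ax, ay, bx, by, cx, cy); o2 <- o(ax, ay, bx, by, dx, dy)
    o3 <- o(cx, cy, dx, dy, ax, ay); o4 <- o(cx, cy, dx, dy, bx, by)
    (o1 != o2 && o3 != o4)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) next
      if (seg_int(x[i], y[i], x2[i], y2[i], x[j], y[j], x2[j], y2[j]))
        return(TRUE)
    }
  }
  FALSE
}

#' Donut-shaped annulus ROI between two nested polygons
#'
#' The annulus is the region between an outer and an inner closed polygon,
#' used to measure membrane-bound reporter signal at a cell boundary. The
#' inner polygon must lie strictly inside the outer one; partially
#' overlapping polygons are rejected rather than clipped.
#'
#' @param outer,inner `roi_polygon` objects.
#' @return An object of class `roi_annulus`.
#' @export
roi_annulus <- function(outer, inner) {
  stopifnot(inherits(outer, "roi_polygon"), inherits(inner, "roi_polygon"))
  inside <- point_in_polygon(inner$x, inner$y, outer)
  if (!all(inside))
    stop("inner polygon must lie strictly inside the outer polygon")
  structure(list(outer = outer, inner = inner), class = "roi_annulus")
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number (even-odd) containment test for arbitrary query points,
#' with points lying exactly on a polygon edge counted as inside. This is the
#' rule used to decide pixel membership throughout the package.
#'
#' @param px,py Numeric vectors of query-point coordinates.
#' @param poly An `roi_polygon`.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  vx <- poly$x; vy <- poly$y
  n <- length(vx)
  vx2 <- c(vx[-1], vx[1]); vy2 <- c(vy[-1], vy[1])
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    ax <- vx[e]; ay <- vy[e]; bx <- vx2[e]; by <- vy2[e]
    crosses <- (ay > py) != (by > py)
    if (any(crosses)) {
      xint <- ax + (py[crosses] - ay) * (bx - ax) / (by - ay)
      hit <- rep(FALSE, length(px)); hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
    # collinear and within segment bounding box -> on the edge
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    seg_len2 <- (bx - ax)^2 + (by - ay)^2
    tol <- 1e-9 * max(1, sqrt(seg_len2))
    col <- abs(cross) <= tol &
      px >= pmin(ax, bx) - tol & px <= pmax(ax, bx) + tol &
      py >= pmin(ay, by) - tol & py <= pmax(ay, by) + tol
    on_edge <- on_edge | col
  }
  inside | on_edge
}

#' Logical pixel mask of a polygon ROI
#'
#' Rasterizes a polygon over an image of given dimensions: a pixel is in the
#' mask iff its center is inside the polygon (even-odd rule, boundary
#' inclusive).
#'
#' @param poly An `roi_polygon`.
#' @param dim Integer vector `c(nrow, ncol)` of the target image.
#' @return Logical matrix of dimension `dim`.
#' @export
polygon_mask <- function(poly, dim) {
  nr <- dim[1]; nc <- dim[2]
  rows <- max(1L, floor(min(poly$y))):min(nr, ceiling(max(poly$y)))
  cols <- max(1L, floor(min(poly$x))):min(nc, ceiling(max(poly$x)))
  mask <- matrix(FALSE, nr, nc)
  if (!length(rows) || !length(cols)) return(mask)
  grid <- expand.grid(y = rows, x = cols)
  hit <- point_in_polygon(grid$x, grid$y, poly)
  mask[cbind(grid$y[hit], grid$x[hit])] <- TRUE
  mask
}

.check_poly_in_image <- function(poly, image) {
  nr <- nrow(image); nc <- ncol(image)
  if (min(poly$x) < 0.5 || max(poly$x) > nc + 0.5 ||
      min(poly$y) < 0.5 || max(poly$y) > nr + 0.5)
    stop("polygon extends outside the image bounds")
  invisible(TRUE)
}

#' Measure total signal and area of a polygon region
#'
#' Sums pixel intensities whose centers fall inside the polygon and counts
#' those pixels, giving the total signal, the area (pixel count) and the unit
#' intensity (total / area) of the region.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param roi An `roi_polygon`.
#' @return A list of class `region_measurement` with elements `total_signal`,
#'   `area` and `unit_intensity`.
#' @examples
#' img <- matrix(2, 8, 8)
#' m <- measure_region(img, roi_polygon(c(2, 5, 5, 2), c(2, 2, 5, 5)))
#' m$total_signal  # 32
#' @export
measure_region <- function(image, roi) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!inherits(roi, "roi_polygon")) stop("`roi` must be an roi_polygon")
  .check_poly_in_image(roi, image)
  mask <- polygon_mask(roi, dim(image))
  area <- sum(mask)
  if (area == 0) stop("degenerate polygon: rasterized area is zero")
  total <- sum(image[mask])
  structure(list(total_signal = total, area = area,
                 unit_intensity = total / area),
            class = "region_measurement")
}

#' @export
print.region_measurement <- function(x, ...) {
  cat(sprintf("<region_measurement> total %.6g over %d px (unit %.6g)\n",
              x$total_signal, x$area, x$unit_intensity))
  invisible(x)
}

#' Unit intensity of a donut annulus (UPS)
#'
#' The annulus unit intensity is the Methods formula
#' `(total_outer - total_inner) / (area_outer - area_inner)`:
#' the mean pixel intensity of the donut region between the two nested
#' polygons. Applied to a membrane PS-reporter channel this is the unit PS
#' intensity (UPS) of the cell surface.
#'
#' @param image Numeric matrix.
#' @param roi An `roi_annulus`.
#' @return Numeric scalar unit intensity.
#' @export
annulus_unit_intensity <- function(image, roi) {
  if (!inherits(roi, "roi_annulus")) stop("`roi` must be an roi_annulus")
  outer <- measure_region(image, roi$outer)
  inner <- measure_region(image, roi$inner)
  darea <- outer$area - inner$area
  if (darea <= 0)
    stop("annulus has non-positive area (outer area <= inner area)")
  (outer$total_signal - inner$total_signal) / darea
}

#' Background-relative intensity (RPS or Ca_R)
#'
#' Divides a target unit intensity by a background unit intensity measured
#' from an equivalent nearby region. A value of 1 indicates no enrichment of
#' signal over the non-specific background. For the PS channel the target is
#' the annulus unit intensity (giving RPS); for the calcium channel it is the
#' cell-body unit intensity (giving Ca_R).
#'
#' @param target_unit Numeric scalar unit intensity of the target region, or
#'   a `region_measurement`.
#' @param background A `region_measurement` of the background region, or a
#'   positive numeric scalar unit intensity.
#' @return Numeric scalar ratio (dimensionless, fold over background).
#' @export
relative_intensity <- function(target_unit, background) {
  if (inherits(target_unit, "region_measurement"))
    target_unit <- target_unit$unit_intensity
  bg <- if (inherits(background, "region_measurement"))
    background$unit_intensity else background
  stopifnot(is.numeric(target_unit), length(target_unit) == 1,
            is.numeric(bg), length(bg) == 1)
  if (!is.finite(bg) || bg <= 0)
    stop("background unit intensity must be positive")
  as.numeric(target_unit) / as.numeric(bg)
}

#' Regular-polygon approximation of a disk
#'
#' Builds a many-sided regular polygon approximating a disk, for use as a
#' cell-body outline or as the nearby circular background region of matched
#' area the quantification formulas call for.
#'
#' @param cx,cy Disk center in pixel coordinates.
#' @param radius Disk radius in pixels (circumradius of the polygon).
#' @param n_vertices Number of vertices (default 64).
#' @return An `roi_polygon`.
#' @export
disk_polygon <- function(cx, cy, radius, n_vertices = 64) {
  stopifnot(radius > 0, n_vertices >= 8)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  roi_polygon(cx + radius * cos(th), cy + radius * sin(th))
}

#' Background disk of area matched to a reference region
#'
#' Builds a disk-shaped background polygon whose rasterized area matches a
#' reference region's area, placed at a caller-given offset. The radius is
#' adjusted iteratively until the pixel-count areas agree within
#' `area_tol` (relative), mirroring the "equivalent size nearby region"
#' convention of background quantification.
#'
#' @param reference_area Target area in pixels.
#' @param cx,cy Center of the background disk.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @param area_tol Relative area tolerance (default 0.05).
#' @return An `roi_polygon`.
#' @export
matched_background_disk <- function(reference_area, cx, cy, dim,
                                    area_tol = 0.05) {
  stopifnot(reference_area > 0)
  r <- sqrt(reference_area / pi)
  for (i in 1:25) {
    poly <- disk_polygon(cx, cy, r)
    a <- sum(polygon_mask(poly, dim))
    if (a > 0 && abs(a - reference_area) / reference_area <= area_tol)
      return(poly)
    # adjust radius toward the target pixel area
    r <- r * sqrt(reference_area / max(a, 1))
  }
  poly
}
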