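# Independent brute-force oracles, deliberately written as plain scalar
# loops so they share no code with the package implementation.

# Even-odd point-in-polygon for a single point (PNPOLY-style loop), with
# points on an edge counted inside -- the same stated inclusion rule as the
# package, independently coded.
oracle_point_in_poly <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < xint) inside <- !inside
    }
    # on-segment check
    ex <- xs[j] - xs[i]; ey <- ys[j] - ys[i]
    len <- sqrt(ex^2 + ey^2)
    if (len > 0) {
      d <- abs(ex * (py - ys[i]) - ey * (px - xs[i])) / len
      tproj <- ((px - xs[i]) * ex + (py - ys[i]) * ey) / len^2
      if (d < 1e-9 && tproj >= -1e-9 && tproj <= 1 + 1e-9) return(TRUE)
    }
    j <- i
  }
  inside
}

# total / area / unit of a polygon region by looping over every pixel
oracle_measure <- function(image, xs, ys) {
  total <- 0; area <- 0L
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (oracle_point_in_poly(j, i, xs, ys)) {
        total <- total + image[i, j]
        area <- area + 1L
      }
    }
  }
  list(total = total, area = area,
       unit = if (area > 0) total / area else NA_real_)
}

# windowed integral of the piecewise-linear interpolant through the trace
# points, evaluated as a trapezoid sum on a dense grid that includes every
# knot (exact for piecewise-linear integrands)
oracle_integral <- function(times, values, window, n_fine = 5000) {
  lo <- max(window[1], min(times)); hi <- min(window[2], max(times))
  grid <- sort(unique(c(seq(lo, hi, length.out = n_fine),
                        times[times > lo & times < hi], lo, hi)))
  v <- approx(times, values, xout = grid)$y
  s <- 0
  for (k in seq_len(length(grid) - 1))
    s <- s + (v[k] + v[k + 1]) / 2 * (grid[k + 1] - grid[k])
  s
}

# grouped mean-of-group-means by an explicit loop
oracle_grouped_mean <- function(counts, size) {
  means <- c()
  i <- 1
  while (i <= length(counts)) {
    j <- min(i + size - 1, length(counts))
    means <- c(means, mean(counts[i:j]))
    i <- j + 1
  }
  list(group_means = means, mean = mean(means))
}

# random convex polygon with non-lattice vertices, inside an nr x nc image
# (convex hull of random points, so scaled copies stay nested)
random_convex_polygon <- function(nr, nc, nv = sample(6:10, 1)) {
  px <- runif(nv, 0.55 + 0.15 * nc, 0.85 * nc)
  py <- runif(nv, 0.55 + 0.15 * nr, 0.85 * nr)
  h <- chull(px, py)
  roi_polygon(px[h], py[h])
}

# nested annulus: a disk polygon plus a shrunken copy about its centroid
random_annulus <- function(nr, nc) {
  outer <- random_convex_polygon(nr, nc, nv = sample(7:10, 1))
  cx <- mean(outer$x); cy <- mean(outer$y)
  s <- runif(1, 0.3, 0.55)
  inner <- roi_polygon(cx + s * (outer$x - cx), cy + s * (outer$y - cy))
  roi_annulus(outer, inner)
}
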