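test_that("uniform and zero images give the closed-form measurements", {
  img <- matrix(2, 8, 8)
  sq <- roi_polygon(c(1.5, 5.5, 5.5, 1.5), c(1.5, 1.5, 5.5, 5.5))
  m <- measure_region(img, sq)
  expect_identical(m$area, 16L)
  expect_equal(m$total_signal, 32)
  expect_equal(m$unit_intensity, 2)

  z <- measure_region(matrix(0, 8, 8), sq)
  expect_equal(z$total_signal, 0)
  expect_equal(z$unit_intensity, 0)
})

test_that("annulus unit intensity matches hand arithmetic", {
  # outer 4x4 block: 4 inner pixels of value 5 (total 20), 12 ring pixels of
  # value 1 -> outer total 32 over 16 px, UPS = (32 - 20) / (16 - 4) = 1
  img <- matrix(0, 8, 8)
  img[2:5, 2:5] <- 1
  img[3:4, 3:4] <- 5
  outer <- roi_polygon(c(1.5, 5.5, 5.5, 1.5), c(1.5, 1.5, 5.5, 5.5))
  inner <- roi_polygon(c(2.5, 4.5, 4.5, 2.5), c(2.5, 2.5, 4.5, 4.5))
  ann <- roi_annulus(outer, inner)
  expect_equal(sum(img[2:5, 2:5]), 32)
  expect_equal(annulus_unit_intensity(img, ann), 1.0)
})

test_that("region and annulus measurements equal the brute-force oracle", {
  set.seed(42)
  for (rep in 1:30) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    img <- matrix(runif(nr * nc, 0, 50), nr, nc)
    poly <- random_convex_polygon(nr, nc)
    m <- measure_region(img, poly)
    o <- oracle_measure(img, poly$x, poly$y)
    expect_identical(m$area, o$area)
    # identical pixel sets; summation order may differ in the last ulp
    expect_equal(m$total_signal, o$total, tolerance = 1e-12)

    ann <- random_annulus(nr, nc)
    oo <- oracle_measure(img, ann$outer$x, ann$outer$y)
    oi <- oracle_measure(img, ann$inner$x, ann$inner$y)
    expect_equal(annulus_unit_intensity(img, ann),
                 (oo$total - oi$total) / (oo$area - oi$area),
                 tolerance = 1e-12)
  }
})

test_that("relative intensity follows the ratio definition and its guards", {
  expect_equal(relative_intensity(1.0, 0.5), 2.0)
  expect_equal(relative_intensity(0.7, 0.7), 1.0)
  expect_error(relative_intensity(1.0, 0), "positive")
  expect_error(relative_intensity(1.0, -2), "positive")

  # uniform image: RPS is exactly 1 for any valid annulus and background
  img <- matrix(7.3, 24, 24)
  ann <- roi_annulus(disk_polygon(12, 12, 6), disk_polygon(12, 12, 3.5))
  bg <- measure_region(img, disk_polygon(5, 5, 3))
  expect_identical(relative_intensity(annulus_unit_intensity(img, ann), bg),
                   1.0)
})

test_that("ratios are scale invariant but offset sensitive", {
  set.seed(7)
  img <- matrix(runif(24 * 24, 1, 10), 24, 24)
  ann <- roi_annulus(disk_polygon(12, 12, 6), disk_polygon(12, 12, 3.5))
  bgp <- disk_polygon(5, 5, 3)
  rps <- function(im) relative_intensity(annulus_unit_intensity(im, ann),
                                         measure_region(im, bgp))
  expect_equal(rps(img * 3.7), rps(img))
  expect_false(isTRUE(all.equal(rps(img + 5), rps(img))))
})

test_that("invalid polygons and annuli are rejected", {
  img <- matrix(1, 10, 10)
  expect_error(roi_polygon(c(1, 2), c(1, 2)), "at least 3")
  expect_error(roi_polygon(c(1, 5, 1, 5), c(1, 5, 5, 1)),
               "self-intersecting")
  expect_error(measure_region(img, roi_polygon(c(5, 20, 5), c(5, 5, 20))),
               "outside")
  # partially overlapping polygons rejected, not clipped
  expect_error(roi_annulus(disk_polygon(5, 5, 3), disk_polygon(8, 5, 3)),
               "inside")
})

test_that("matched background disk hits the requested pixel area", {
  target <- sum(polygon_mask(disk_polygon(16, 16, 7.3), c(48, 48)))
  bg <- matched_background_disk(target, 32, 32, c(48, 48))
  a <- sum(polygon_mask(bg, c(48, 48)))
  expect_lt(abs(a - target) / target, 0.05)
})
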