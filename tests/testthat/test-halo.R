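lab_from_b <- function(b, h = 30, w = 30, L = 60) {
  x <- array(0, c(h, w, 3))
  x[, , 1] <- L
  x[, , 3] <- b
  structure(x, class = "lab_image")
}

test_that("blue_mask applies the strict open b* band", {
  expect_true(all(blue_mask(lab_from_b(-10))))
  expect_false(any(blue_mask(lab_from_b(0))))
  # at and beyond the bounds: strict inequalities
  expect_false(any(blue_mask(lab_from_b(-5))))
  expect_false(any(blue_mask(lab_from_b(-20))))
  expect_false(any(blue_mask(lab_from_b(-25))))
  expect_true(all(blue_mask(lab_from_b(-25),
                            segmentation_params(extend_blue = TRUE))))
  expect_error(segmentation_params(b_lo = -5, b_hi = -20), "b_lo < b_hi")
})

test_that("blue_mask equals a brute-force per-pixel threshold", {
  set.seed(11)
  for (k in 1:10) {
    b <- matrix(runif(20 * 25, -30, 10), 20, 25)
    lab <- array(0, c(20, 25, 3)); lab[, , 3] <- b
    m <- blue_mask(structure(lab, class = "lab_image"))
    brute <- matrix(FALSE, 20, 25)
    for (i in 1:20) for (j in 1:25)
      brute[i, j] <- b[i, j] > -20 && b[i, j] < -5
    expect_identical(m, brute)
  }
})

test_that("a solid disk is detected with its rasterized pixel count", {
  mask <- rasterize_disk(100, 100, c(50, 50), 20)
  lay <- grid_layout(1, 1, 100, 100)
  regions <- detect_halos(mask, lay)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$pixel_count,
               oracle_disk_pixel_count(100, 100, c(50, 50), 20))
  expect_equal(regions$centroid_x, 50, tolerance = 0.1)
  expect_equal(regions$centroid_y, 50, tolerance = 0.1)
  expect_gte(regions$circularity, 0.9)
  expect_equal(regions$cell_id, "r1c1")
})

test_that("an all-false mask yields an empty region table", {
  out <- detect_halos(matrix(FALSE, 40, 40), grid_layout(2, 2, 40, 40))
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 0)
})

test_that("two disjoint disks in different cells each carry their cell id", {
  mask <- rasterize_disk(200, 100, c(50, 50), 15) |
    rasterize_disk(200, 100, c(150, 50), 12)
  expect_equal(max(oracle_label8(mask)), 2)  # fixture really has 2 components
  lay <- grid_layout(1, 2, 200, 100)
  regions <- detect_halos(mask, lay)
  expect_equal(nrow(regions), 2)
  expect_setequal(regions$cell_id, c("r1c1", "r1c2"))
})

test_that("labeling is 8-connected: diagonal contact is one region", {
  mask <- matrix(FALSE, 60, 60)
  mask[10:20, 10:20] <- TRUE
  mask[21:31, 21:31] <- TRUE  # corners touch diagonally at (20,20)/(21,21)
  expect_equal(max(oracle_label8(mask)), 1)
  regions <- detect_halos(mask, NULL,
                          detection_params(closing_radius_px = 0,
                                           min_circularity = 0.1))
  expect_equal(nrow(regions), 1)
  expect_equal(regions$pixel_count, sum(mask))
})

test_that("detection is translation-equivariant", {
  base <- rasterize_disk(120, 120, c(40, 45), 16)
  r0 <- detect_halos(base, NULL, detection_params())
  for (shift in list(c(10, 5), c(-7, 22))) {
    shifted <- rasterize_disk(120, 120, c(40 + shift[1], 45 + shift[2]), 16)
    r1 <- detect_halos(shifted, NULL, detection_params())
    expect_equal(r1$pixel_count, r0$pixel_count)
    expect_equal(r1$centroid_x, r0$centroid_x + shift[1], tolerance = 1e-8)
    expect_equal(r1$centroid_y, r0$centroid_y + shift[2], tolerance = 1e-8)
  }
})

test_that("elongated shapes fail the circularity filter", {
  mask <- matrix(FALSE, 100, 100)
  mask[50:51, 5:95] <- TRUE  # a 2 px grid-line-like stroke
  expect_equal(nrow(detect_halos(mask, NULL, detection_params())), 0)
})

test_that("one region per cell: the largest halo wins", {
  mask <- rasterize_disk(100, 100, c(30, 30), 18) |
    rasterize_disk(100, 100, c(70, 70), 10)
  lay <- grid_layout(1, 1, 100, 100)
  expect_message(regions <- detect_halos(mask, lay), "dropped")
  expect_equal(nrow(regions), 1)
  expect_equal(regions$pixel_count,
               oracle_disk_pixel_count(100, 100, c(30, 30), 18))
})

test_that("pixel_count_in_circle matches brute-force tallies", {
  disk <- rasterize_disk(80, 80, c(40, 40), 20)
  expect_equal(pixel_count_in_circle(disk, c(40, 40), 20),
               oracle_disk_pixel_count(80, 80, c(40, 40), 20))
  expect_equal(pixel_count_in_circle(matrix(FALSE, 50, 50), c(25, 25), 10), 0)
  # circle over half of a positive rectangle
  mask <- matrix(FALSE, 60, 60)
  mask[20:40, 30:60] <- TRUE
  got <- pixel_count_in_circle(mask, c(30, 30), 15)
  brute <- 0L
  for (i in 1:60) for (j in 1:60)
    if (mask[i, j] && (j - 0.5 - 30)^2 + (i - 0.5 - 30)^2 <= 225)
      brute <- brute + 1L
  expect_equal(got, brute)
})

test_that("enlarging a circular mask never decreases the count", {
  set.seed(3)
  mask <- matrix(runif(80 * 80) < 0.3, 80, 80)
  counts <- vapply(seq(5, 40, by = 5),
                   function(r) pixel_count_in_circle(mask, c(40, 40), r), 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("a non-intersecting circle is a parameter error", {
  expect_error(pixel_count_in_circle(matrix(TRUE, 10, 10), c(100, 100), 5),
               "intersect")
  expect_error(pixel_count_in_circle(matrix(TRUE, 10, 10), c(5, 5), 0),
               "radius")
})
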