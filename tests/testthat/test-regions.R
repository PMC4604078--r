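test_that("cell counting recovers planted counts and handles extremes", {
  blank <- matrix(0.05, 64, 64)
  r0 <- count_positive_cells(blank, threshold = 0.5)
  expect_equal(r0$n_objects, 0)

  f <- generate_cell_field(50, c(256, 256), seed = 3)
  r <- count_positive_cells(f$image, threshold = 0.5,
                            min_area_um2 = 5, max_area_um2 = 500)
  expect_equal(r$n_objects, 50)
  expect_equal(r$density_per_mm2, r$n_objects / r$area_mm2)

  sat <- count_positive_cells(matrix(1, 32, 32), threshold = 0.5,
                              max_area_um2 = 1e6)
  expect_true(sat$saturated)
})

test_that("touching blobs count as one object without watershed splitting", {
  img <- matrix(0, 32, 32)
  img[10:14, 10:14] <- 1
  img[14:18, 14:18] <- 1  # shares a pixel: connected
  r <- count_positive_cells(img, threshold = 0.5, min_area_um2 = 1,
                            max_area_um2 = 1e4)
  expect_equal(r$n_objects, 1)
})

test_that("counting is monotone under adding a disjoint object", {
  img <- matrix(0, 64, 64)
  img[5:9, 5:9] <- 1
  n1 <- count_positive_cells(img, threshold = 0.5, min_area_um2 = 1,
                             max_area_um2 = 1e4)$n_objects
  img[40:44, 40:44] <- 1
  n2 <- count_positive_cells(img, threshold = 0.5, min_area_um2 = 1,
                             max_area_um2 = 1e4)$n_objects
  expect_gte(n2, n1)
})

test_that("FOV averaging is the arithmetic mean and checks calibration", {
  mk <- function(d, um = 1) structure(list(density_per_mm2 = d,
                                           um_per_px = um),
                                      class = "count_result")
  expect_equal(average_fov_density(lapply(1:5, mk)), 3)
  expect_equal(average_fov_density(list(mk(7))), 7)
  expect_equal(average_fov_density(lapply(rep(2.5, 5), mk)), 2.5)
  expect_error(average_fov_density(list(mk(1, 1), mk(2, 0.5))),
               "calibration")
})

test_that("area fraction recovers fixture truth and ROI geometry", {
  g <- generate_area_fraction_image(0.25, c(256, 256), mode = "gray",
                                    seed = 7)
  r <- area_fraction(g$image, threshold = 0.5)
  expect_lt(abs(r$percent_positive - 100 * g$realized_fraction), 1)

  zero <- generate_area_fraction_image(0, c(64, 64), mode = "gray", seed = 1)
  expect_equal(area_fraction(zero$image, threshold = 0.5)$percent_positive, 0)

  img <- matrix(0, 40, 60)
  full_roi <- list(cbind(c(0, 60, 60, 0), c(0, 0, 40, 40)))
  expect_equal(area_fraction(img, roi = full_roi)$percent_positive, 100)
  # vertex order reversal leaves the area unchanged
  rev_roi <- list(full_roi[[1]][4:1, ])
  expect_equal(area_fraction(img, roi = rev_roi)$percent_positive, 100)
  expect_error(area_fraction(img, roi = list(cbind(c(-5, 10), c(0, 10)))),
               "outside")
  expect_error(area_fraction(img, threshold = 0.5,
                             section_mask = matrix(FALSE, 40, 60)),
               "empty section")
})

test_that("area fraction is invariant under 90-degree image rotation", {
  g <- generate_area_fraction_image(0.3, c(128, 96), mode = "gray", seed = 5)
  a <- area_fraction(g$image, threshold = 0.5)$percent_positive
  rot <- t(g$image)[, rev(seq_len(nrow(g$image)))]
  b <- area_fraction(rot, threshold = 0.5)$percent_positive
  expect_equal(a, b)
})

test_that("trichrome blue fraction follows the blue-dominance rule", {
  mk_rgb <- function(col, ny = 32, nx = 32) {
    arr <- array(0, c(ny, nx, 3))
    for (ch in 1:3) arr[, , ch] <- col[ch]
    arr
  }
  expect_equal(trichrome_fraction(mk_rgb(c(0.1, 0.2, 0.9)))$percent_positive,
               100)
  expect_equal(trichrome_fraction(mk_rgb(c(0.9, 0.2, 0.1)))$percent_positive,
               0)
  f <- generate_area_fraction_image(0.25, c(256, 256), seed = 7)
  r <- trichrome_fraction(f$image)
  expect_lt(abs(r$percent_positive - 100 * f$realized_fraction), 1)
  # R <-> B channel swap inverts positivity on pure-colour fixtures
  swapped <- f$image[, , c(3, 2, 1)]
  r_swap <- trichrome_fraction(swapped)
  expect_lt(abs(r_swap$percent_positive -
                  (100 - 100 * f$realized_fraction)), 1)
})

test_that("revertant fiber density counts connected components per mm2", {
  mask <- matrix(FALSE, 1000, 1000)  # 1 mm^2 at 1 um/px
  mask[100:110, 100:110] <- TRUE
  mask[500:510, 500:510] <- TRUE
  mask[800:810, 200:210] <- TRUE
  r <- revertant_density(mask, um_per_px = 1)
  expect_equal(r$n_fibers, 3)
  expect_equal(r$density_per_mm2, 3)
  expect_equal(revertant_density(matrix(FALSE, 100, 100))$n_fibers, 0)
  set.seed(2)
  f <- generate_cell_field(12, c(200, 200), seed = 8)
  expect_equal(revertant_density(f$image > 0.5)$n_fibers, 12)
})
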