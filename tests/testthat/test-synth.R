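test_that("single-fiber field is the full rectangle with exact truth", {
  f <- generate_fiber_field(1, c(30, 80), um_per_px = 1, seed = 2)
  expect_equal(nrow(f$truth), 1)
  expect_equal(f$truth$min_feret_um, 30)
  expect_equal(f$truth$area_um2, 30 * 80)
})

test_that("pct_central = 0 plants no central nuclei", {
  f <- generate_fiber_field(20, c(256, 256), pct_central = 0, seed = 3)
  expect_false(any(f$truth$has_central_nucleus))
  expect_true(all(f$truth$n_nuclei == 1L))
})

test_that("fiber-field generation is deterministic per seed", {
  a <- generate_fiber_field(30, c(256, 256), seed = 11)
  b <- generate_fiber_field(30, c(256, 256), seed = 11)
  expect_identical(a, b)
  c_ <- generate_fiber_field(30, c(256, 256), seed = 12)
  expect_false(identical(a$truth, c_$truth))
})

test_that("fiber truth respects geometric invariants", {
  f <- generate_fiber_field(30, c(256, 256), seed = 11)
  expect_true(all(f$truth$area_um2 > 0))
  expect_true(all(f$truth$min_feret_um > 0))
  for (k in f$truth$fiber_id) {
    mx <- max_feret(f$polygons[[k]], type = "polygon")
    expect_lte(f$truth$min_feret_um[k], mx + 1e-9)
  }
  # interior regions are disjoint by construction: label image partitions
  expect_equal(sum(tabulate(f$label[f$label > 0])),
               sum(f$truth$area_um2))
})

test_that("excessive fiber density is rejected with a sizing error", {
  expect_error(generate_fiber_field(500, c(64, 64), seed = 1),
               "density too high")
})

test_that("area-fraction fixtures hit their target fraction", {
  f0 <- generate_area_fraction_image(0, c(64, 64), seed = 1)
  expect_equal(f0$realized_fraction, 0)
  expect_false(any(f0$positive_mask))

  f1 <- generate_area_fraction_image(1, c(64, 64), seed = 1)
  expect_equal(f1$realized_fraction, 1)

  f <- generate_area_fraction_image(0.25, c(256, 256), seed = 7)
  expect_gte(f$realized_fraction, 0.245)
  expect_lte(f$realized_fraction, 0.255)
  # recomputable by direct pixel count
  expect_equal(f$realized_fraction, sum(f$positive_mask) / (256 * 256))
  # gray mode encodes the same mask
  g <- generate_area_fraction_image(0.25, c(256, 256), mode = "gray",
                                    seed = 7)
  expect_equal(sum(g$image > 0.5), sum(g$positive_mask))
})

test_that("cell fields contain exactly the planted number of components", {
  blank <- generate_cell_field(0, c(64, 64), seed = 1)
  expect_false(any(blank$image > 0.5))

  one <- generate_cell_field(1, c(64, 64), seed = 2)
  lab1 <- EBImage::bwlabel(one$image > 0.5)  # independent labelling oracle
  expect_equal(max(lab1), 1)

  f <- generate_cell_field(50, c(256, 256), seed = 3)
  lab <- EBImage::bwlabel(f$image > 0.5)
  expect_equal(max(lab), 50)

  expect_error(generate_cell_field(500, c(64, 64), radius_px = 6, seed = 1),
               "density too high")
})

test_that("trabecular fixtures have exact construction truth", {
  g <- generate_trabecular_volume("parallel_plates", 40, 160, c(32, 32, 50),
                                  um_per_vox = 8, noise_sd = 0, seed = 1)
  expect_equal(g$truth$bvtv, 40 / (40 + 160))

  solid <- generate_trabecular_volume("parallel_plates", 40, 0, c(16, 16, 16),
                                      um_per_vox = 8, noise_sd = 0, seed = 1)
  expect_equal(solid$truth$bvtv, 1)
  expect_true(all(solid$mask))

  rods <- generate_trabecular_volume("rods", 40, 120, c(40, 40, 20),
                                     um_per_vox = 8, noise_sd = 0.05,
                                     seed = 11)
  expect_equal(rods$truth$bvtv, sum(rods$mask) / length(rods$mask))

  expect_error(generate_trabecular_volume("rods", 37, 120, c(16, 16, 16),
                                          um_per_vox = 8, seed = 1),
               "whole numbers")
})

test_that("group measurement fixtures are reproducible and sized", {
  specs <- data.frame(group_name = c("wt", "mdx", "ko"),
                      n = c(2, 5, 7), distribution = "normal",
                      mean = c(0, 1, 2), sd = 1, seed = c(4, 5, 6))
  d1 <- generate_group_measurements(specs)
  d2 <- generate_group_measurements(specs)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), sum(specs$n))
  expect_equal(as.vector(table(d1$group)[specs$group_name]), specs$n)
  expect_error(generate_group_measurements(specs[1, , drop = FALSE]),
               "at least 2")
})

test_that("noise-free Ct tables give geNorm M = 0 for all genes", {
  ct <- generate_ct_table(6, paste0("g", 1:4), stable_refs = 2,
                          noise_sd = 0, seed = 9)
  gs <- genorm_stability(ct)
  expect_true(all(gs$M < 1e-12))
})

test_that("planted FPKM cluster structure is recovered by Ward clustering", {
  fx <- generate_fpkm_matrix(40, 8, seed = 9)
  z <- zscore_log(fx$fpkm)
  hc <- ward_cluster(z$z, "columns")
  cut <- stats::cutree(hc, 2)
  agree <- max(mean(cut == fx$sample_cluster),
               mean(cut == 3 - fx$sample_cluster))
  expect_equal(agree, 1)
  expect_identical(generate_fpkm_matrix(40, 8, seed = 9)$fpkm, fx$fpkm)
})
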