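test_that("background level is the arithmetic mean under the mask", {
  v <- pet_volume(array(1, c(4, 4, 4)))
  m <- array(0, c(4, 4, 4)); m[1:3, 1, 1] <- 1
  bm <- zone_mask("background", m)
  expect_equal(background_level(v, bm), 1.0)
  v2 <- v; v2$data[1, 1, 1] <- 1; v2$data[2, 1, 1] <- 2; v2$data[3, 1, 1] <- 3
  expect_equal(background_level(v2, bm), 2.0)
  single <- array(0, c(4, 4, 4)); single[2, 2, 2] <- 1
  v3 <- v; v3$data[2, 2, 2] <- 0.7
  expect_equal(background_level(v3, zone_mask("background", single)), 0.7)
  expect_error(background_level(v, zone_mask("background",
                                             array(0, c(4, 4, 4)))),
               "empty")
})

test_that("thresholding keeps exactly the voxels above factor x background", {
  zm <- array(0, c(4, 4, 4)); zm[1:2, 1, 1] <- 1
  zone <- zone_mask("frontal", zm)
  base <- array(1, c(4, 4, 4))

  # nothing exceeds: zone at background level
  v <- pet_volume(base)
  gt <- make_ground_truth(v, zone, threshold_rule(1.5, background = 1))
  expect_equal(sum(gt$data), 0)

  # everything exceeds
  v2 <- base; v2[zm == 1] <- 2
  gt2 <- make_ground_truth(pet_volume(v2), zone,
                           threshold_rule(1.5, background = 1))
  expect_equal(gt2$data, zm)
  expect_identical(gt2$zone_id, "frontal")

  # mixed: only the 1.6 voxel survives; 1.5 sits exactly at the threshold
  # and is excluded by the strict inequality
  v3 <- base; v3[1, 1, 1] <- 1.4; v3[2, 1, 1] <- 1.6
  gt3 <- make_ground_truth(pet_volume(v3), zone,
                           threshold_rule(1.5, background = 1))
  expect_equal(which(gt3$data == 1), 2L)
  v4 <- base; v4[1, 1, 1] <- 1.5; v4[2, 1, 1] <- 1.6
  gt4 <- make_ground_truth(pet_volume(v4), zone,
                           threshold_rule(1.5, background = 1))
  expect_equal(which(gt4$data == 1), 2L)
})

test_that("raising the factor never adds voxels and output stays in-zone", {
  set.seed(8)
  spec <- default_phantom_spec(noise_sigma = 0.1, psf_fwhm_mm = 3, seed = 8)
  ph <- generate_phantom(spec)
  norm <- normalize_to_pons(ph$volume, ph$pons)$volume
  bg <- background_level(norm, ph$background)
  zone <- ph$zones$frontal
  prev <- NULL
  for (f in c(1.2, 1.5, 1.8, 2.1)) {
    gt <- make_ground_truth(norm, zone, threshold_rule(f, background = bg))
    expect_true(all(gt$data <= zone$data))   # subset of the delineation
    if (!is.null(prev)) expect_true(all(gt$data <= prev))
    prev <- gt$data
  }
})

test_that("noiseless phantoms above threshold are recovered exactly", {
  spec <- default_phantom_spec(uptake_ratio = 2.0, noise_sigma = 0,
                               psf_fwhm_mm = 0, seed = 2)
  ph <- generate_phantom(spec)
  norm <- normalize_to_pons(ph$volume, ph$pons)$volume
  bg <- background_level(norm, ph$background)
  rule <- threshold_rule(1.5, background = bg)
  for (id in ZONE_IDS) {
    gt <- make_ground_truth(norm, ph$zones[[id]], rule)
    expect_equal(gt$data, ph$zones[[id]]$data)
  }
})

test_that("degenerate thresholding inputs error", {
  zone <- zone_mask("frontal", array(1, c(2, 2, 2)))
  v <- pet_volume(array(1, c(2, 2, 2)))
  expect_error(make_ground_truth(v, zone, threshold_rule(1.5)),
               "background")
  expect_error(make_ground_truth(v, zone,
                                 threshold_rule(1.5, background = 0)),
               "background")
  expect_error(threshold_rule(0), "positive")
})
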