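make_vol <- function(values, dims = c(4, 4, 4)) {
  pet_volume(array(values, dims))
}

test_that("pons normalization scales the reference mean to exactly 1", {
  pons <- array(0, c(4, 4, 4)); pons[1:2, 1, 1] <- 1
  pm <- zone_mask("pons", pons)

  # uniform volume of 2 -> all ones
  out <- normalize_to_pons(make_vol(2), pm)
  expect_equal(out$volume$data, array(1, c(4, 4, 4)))
  expect_equal(out$report$pons_mean, 2.0)
  expect_equal(out$report$scale_applied, 0.5)
  expect_identical(out$report$method, "pons-ratio")

  # hand-computed division: pons voxels {1,2,3} (mean 2), cortical voxel 3
  v <- array(1, c(4, 4, 4))
  v[1, 1, 1] <- 1; v[2, 1, 1] <- 2; v[3, 1, 1] <- 3
  v[4, 4, 4] <- 3
  pons3 <- array(0, c(4, 4, 4)); pons3[1:3, 1, 1] <- 1
  out3 <- normalize_to_pons(pet_volume(v), zone_mask("pons", pons3))
  expect_equal(out3$volume$data[4, 4, 4], 1.5)
  expect_equal(mean(out3$volume$data[pons3 == 1]), 1.0, tolerance = 1e-9)
})

test_that("pons normalization is scale-invariant and idempotent", {
  set.seed(1)
  v <- array(runif(64, 0.5, 3), c(4, 4, 4))
  pons <- array(0, c(4, 4, 4)); pons[2:3, 2, 2] <- 1
  pm <- zone_mask("pons", pons)
  n1 <- normalize_to_pons(pet_volume(v), pm)$volume
  n2 <- normalize_to_pons(pet_volume(v * 7.3), pm)$volume
  expect_equal(n1$data, n2$data, tolerance = 1e-12)
  n11 <- normalize_to_pons(n1, pm)
  expect_equal(n11$volume$data, n1$data, tolerance = 1e-9)
  expect_equal(n11$report$pons_mean, 1.0, tolerance = 1e-9)
})

test_that("pons normalization rejects empty or zero-mean masks", {
  pm0 <- zone_mask("pons", array(0, c(4, 4, 4)))
  expect_error(normalize_to_pons(make_vol(1), pm0), "empty")
  pons <- array(0, c(4, 4, 4)); pons[1, 1, 1] <- 1
  v <- array(1, c(4, 4, 4)); v[1, 1, 1] <- 0
  expect_error(normalize_to_pons(pet_volume(v), zone_mask("pons", pons)),
               "positive")
})

test_that("linear resize follows the closed-form interpolation rule", {
  # constant stays constant
  out <- resize_volume(make_vol(3.7), c(6, 5, 7))
  expect_equal(out$data, array(3.7, c(6, 5, 7)))
  # identity resize
  set.seed(2)
  v <- array(runif(64), c(4, 4, 4))
  expect_equal(resize_volume(pet_volume(v), c(4, 4, 4))$data, v)
  # ramp 0..1 over 2 samples upsampled to 3 -> 0, 0.5, 1 along each axis
  ramp <- array(rep(c(0, 1), each = 1), c(2, 2, 2))
  ramp[2, , ] <- 1; ramp[1, , ] <- 0
  up <- resize_volume(ramp, c(3, 2, 2))
  expect_equal(up[, 1, 1], c(0, 0.5, 1))
  # values never leave the input range
  big <- resize_volume(pet_volume(array(runif(5 * 6 * 7), c(5, 6, 7))),
                       c(9, 4, 11))
  expect_gte(min(big$data), 0)
  expect_lte(max(big$data), 1)
  expect_error(resize_volume(make_vol(1), c(1, 4, 4)), ">= 2")
})

test_that("standardization is exact arithmetic", {
  expect_equal(standardize(make_vol(5), 3, 2), array(1, c(4, 4, 4)))
  expect_equal(standardize(make_vol(2), 0, 1), array(2, c(4, 4, 4)))
  expect_equal(standardize(make_vol(7), 7, 3), array(0, c(4, 4, 4)))
  expect_error(standardize(make_vol(1), 0, 0), "positive")
  expect_error(standardize(make_vol(1), 0, -1), "positive")
})

test_that("identity augmentation returns inputs unchanged", {
  img <- matrix(runif(400), 20, 20)
  msk <- disk_mask(20, 5)
  out <- augment(img, msk, augmentation_params())
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)
})

test_that("translation shifts content by the stated pixel count", {
  img <- matrix(0, 100, 100); img[50, 50] <- 1
  out <- augment(img, NULL,
                 augmentation_params(translate_frac_x = 0.1))
  hot <- which(out$image == max(out$image), arr.ind = TRUE)
  expect_equal(unname(hot[1, 1]), 60)
  expect_equal(unname(hot[1, 2]), 50)
})

test_that("rotation +10 then -10 nearly inverts on a centered disk", {
  msk <- disk_mask(48, 12)
  r1 <- augment(msk, msk, augmentation_params(rotation_deg = 10))
  r2 <- augment(r1$image, r1$mask, augmentation_params(rotation_deg = -10))
  expect_gte(suppressWarnings(iou_metric(r2$mask, msk)), 0.9)
  expect_true(all(r2$mask %in% c(0, 1)))
  # mask cardinality approximately preserved for an interior shape
  expect_lt(abs(sum(r2$mask) - sum(msk)) / sum(msk), 0.1)
})

test_that("augmentation parameters outside the stated ranges are rejected", {
  expect_error(augmentation_params(rotation_deg = 11), "rotation")
  expect_error(augmentation_params(translate_frac_x = 0.2), "translations")
  expect_error(augmentation_params(shear_deg = -12), "shear")
  ap <- sample_augmentation(seed = 99)
  expect_s3_class(ap, "augmentation_params")
  expect_lte(abs(ap$rotation_deg), 10)
})

test_that("dataset split is a seeded partition with the 80/20 sizes", {
  s440 <- split_dataset(seq_len(440), 0.8, seed = 1)
  expect_length(s440$train, 352)
  expect_length(s440$val, 88)
  s5 <- split_dataset(seq_len(5), 0.8, seed = 1)
  expect_length(s5$train, 4)
  expect_length(s5$val, 1)
  # partition: disjoint and exhaustive
  expect_setequal(c(s440$train_idx, s440$val_idx), seq_len(440))
  expect_length(intersect(s440$train_idx, s440$val_idx), 0)
  # determinism
  s440b <- split_dataset(seq_len(440), 0.8, seed = 1)
  expect_identical(s440$train_idx, s440b$train_idx)
  expect_error(split_dataset(list(1)), "at least 2")
})
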