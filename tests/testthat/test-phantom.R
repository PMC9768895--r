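test_that("noiseless phantom places exact uptake values inside and outside zones", {
  zone <- zone_def("frontal",
                   list(ellipsoid(c(20, 20, 20), c(6, 6, 6))),
                   positive = TRUE, uptake_ratio = 2.0)
  spec <- phantom_spec(matrix_size = c(40, 40, 40), zones = list(zone),
                       pons = list(center = c(19.5, 32, 6), radius = 3),
                       noise_sigma = 0, psf_fwhm_mm = 0,
                       background_uptake = 1.0, seed = 1)
  ph <- generate_phantom(spec)
  inz <- ph$zones$frontal$data == 1
  expect_true(sum(inz) > 0)
  expect_equal(unique(ph$volume$data[inz]), 2.0)
  expect_equal(unique(ph$volume$data[!inz]), 1.0)
})

test_that("generation is bit-identical for a fixed seed", {
  spec <- default_phantom_spec(noise_sigma = 0.1, psf_fwhm_mm = 3,
                               seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$zones$striatum$data, b$zones$striatum$data)
})

test_that("background noise obeys its stated Gaussian distribution", {
  spec <- default_phantom_spec(noise_sigma = 0.1, psf_fwhm_mm = 0, seed = 7)
  ph <- generate_phantom(spec)
  allz <- Reduce(`+`, lapply(ph$zones, function(z) z$data)) + ph$pons$data
  bg_vals <- ph$volume$data[allz == 0]
  n <- 1e4
  sample_mean <- mean(bg_vals[seq_len(n)])
  expect_lt(abs(sample_mean - 1.0), 3 * 0.1 / sqrt(n))
})

test_that("zone masks, pons and background are pairwise disjoint", {
  ph <- generate_phantom(default_phantom_spec(seed = 3))
  total <- Reduce(`+`, lapply(ph$zones, function(z) z$data)) +
    ph$pons$data + ph$background$data
  expect_lte(max(total), 1)
  expect_equal(sort(names(ph$zones)), sort(ZONE_IDS))
})

test_that("raising a positive zone's uptake ratio never lowers its mean", {
  m1 <- generate_phantom(default_phantom_spec(uptake_ratio = 2.0,
                                              noise_sigma = 0.05,
                                              psf_fwhm_mm = 3, seed = 5))
  m2 <- generate_phantom(default_phantom_spec(uptake_ratio = 2.5,
                                              noise_sigma = 0.05,
                                              psf_fwhm_mm = 3, seed = 5))
  for (id in ZONE_IDS) {
    z <- m1$zones[[id]]$data == 1
    expect_gte(mean(m2$volume$data[z]), mean(m1$volume$data[z]))
  }
})

test_that("invalid specs are rejected", {
  z1 <- zone_def("frontal", list(ellipsoid(c(20, 20, 20), c(8, 8, 8))))
  z2 <- zone_def("striatum", list(ellipsoid(c(22, 20, 20), c(8, 8, 8))))
  spec <- phantom_spec(matrix_size = c(40, 40, 40), zones = list(z1, z2),
                       pons = list(center = c(19.5, 35, 5), radius = 2))
  expect_error(generate_phantom(spec), "disjoint")
  expect_error(phantom_spec(background_uptake = 0), "positive")
  expect_error(phantom_spec(background_uptake = -1), "positive")
  expect_error(zone_def("frontal", list(ellipsoid(c(1, 1, 1), c(2, 2, 2))),
                        positive = FALSE, uptake_ratio = 1.5),
               "uptake_ratio")
})

test_that("slice extraction indexes the right plane", {
  vol <- array(0, c(4, 4, 4))
  vol[1, 2, 3] <- 9
  v <- pet_volume(vol + 1)
  ax0 <- extract_slices(v, "axial", 1)[[1]]
  expect_equal(ax0, vol[, , 1] + 1)
  expect_equal(dim(ax0), c(4, 4))
  # only the coronal slice through y = 2 holds the hot voxel
  for (j in 1:4) {
    s <- extract_slices(v, "coronal", j)[[1]]
    if (j == 2) expect_true(any(s == 10)) else expect_false(any(s == 10))
  }
  expect_error(extract_slices(v, "axial", 5), "bounds")
  expect_error(extract_slices(v, "sagittal", 0), "bounds")
})

test_that("re-stacking every slice reproduces the volume", {
  set.seed(42)
  vol <- array(runif(5 * 6 * 7), c(5, 6, 7))
  for (plane in c("axial", "coronal", "sagittal")) {
    nidx <- switch(plane, axial = 7, coronal = 6, sagittal = 5)
    sl <- extract_slices(vol, plane, seq_len(nidx))
    expect_equal(stack_slices(sl, plane), vol)
  }
})
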