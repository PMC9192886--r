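test_that("voxelized phantom reproduces the NEMA IEC geometry", {
  spec <- phantom_spec()
  ph <- build_phantom(spec)
  # six spheres, six connected components
  expect_identical(count_components(ph$lesion_mask), 6L)
  # largest sphere voxelization agrees with the analytic volume
  sv <- spectboost:::sphere_voxels(spec)
  vol_mm3 <- length(sv[[1]]) * spec$voxel_size_mm^3
  analytic <- 4 / 3 * pi * (37 / 2)^3
  expect_lt(abs(vol_mm3 - analytic) / analytic, 0.05)
  # voxelized cylinder volume within 2% of the nominal fill volume
  fill_ml <- sum(ph$activity$data > 0) * spec$voxel_size_mm^3 / 1000
  expect_lt(abs(fill_ml - spec$cylinder_volume_ml) / spec$cylinder_volume_ml, 0.02)
  # activity levels: background 1, spheres at the configured ratio
  expect_setequal(unique(as.numeric(ph$activity$data)), c(0, 1, 12))
  expect_true(all(ph$activity$data[ph$lesion_mask$data == 1] == 12))
  # pseudo-CT has exactly three attenuation classes
  expect_identical(sort(unique(as.numeric(ph$pseudo_ct$data))), c(-1000, 0, 120))
})

test_that("ratio-1 phantom has constant activity over background and spheres", {
  ph <- build_phantom(phantom_spec(grid_shape = c(32L, 64L, 64L),
                                   voxel_size_mm = 7.8, activity_ratio = 1))
  inside <- ph$activity$data > 0
  expect_true(all(ph$activity$data[inside] == 1))
})

test_that("phantom geometry errors name the offending dimension", {
  expect_error(build_phantom(phantom_spec(grid_shape = c(20L, 256L, 256L))),
               "slice axis")
  expect_error(build_phantom(phantom_spec(grid_shape = c(200L, 64L, 256L),
                                          voxel_size_mm = 1.95)),
               "row axis")
  expect_error(phantom_spec(sphere_diameters_mm = c(10, 9, 17, 22, 28, 37)),
               "strictly increasing")
  expect_error(phantom_spec(ring_radius_mm = 10), "ring radius")
})

test_that("acquisition simulation follows the Poisson forward model", {
  # zero activity, zero background -> all-zero counts
  act0 <- volume(array(0, c(8, 8, 8)), 4, "activity")
  acq <- acquisition_spec(seconds_per_projection = 20, psf_fwhm_mm = 0,
                          rng_seed = 1)
  expect_true(all(simulate_acquisition(act0, acq)$data == 0))
  # determinism: identical seed gives bit-identical volumes
  act <- volume(array(runif(8^3, 1, 3), c(8, 8, 8)), 4, "activity")
  expect_identical(simulate_acquisition(act, acq)$data,
                   simulate_acquisition(act, acq)$data)
  # counts are integer-valued
  cts <- simulate_acquisition(act, acq)
  expect_true(all(cts$data == round(cts$data)))
  expect_identical(cts$modality, "spect_counts")
})

test_that("expected counts scale linearly with dwell time", {
  act <- volume(array(2, c(20, 20, 20)), 4, "activity")
  means <- vapply(c(3, 10, 20), function(dw) {
    acq <- acquisition_spec(seconds_per_projection = dw, psf_fwhm_mm = 0,
                            rng_seed = 42 + dw)
    mean(simulate_acquisition(act, acq)$data)
  }, numeric(1))
  # mean counts per second of dwell must be constant
  per_s <- means / c(3, 10, 20)
  expect_lt(diff(range(per_s)) / mean(per_s), 0.02)
})

test_that("PSF blur preserves total activity and count totals match expectation", {
  # activity away from the boundary so the normalized kernel loses no mass
  a <- array(0, c(40, 40, 40))
  a[15:25, 15:25, 15:25] <- runif(11^3, 0, 5)
  act <- volume(a, 2, "activity")
  bl <- psf_blur(act, 8)
  expect_lt(abs(sum(bl$data) - sum(a)) / sum(a), 1e-10)
  # count conservation in expectation (3-sigma Poisson bound)
  acq <- acquisition_spec(seconds_per_projection = 20, rng_seed = 9)
  lam <- spectboost:::expected_counts(act, acq)
  cts <- simulate_acquisition(act, acq)
  expect_lt(abs(sum(cts$data) - sum(lam)), 3 * sqrt(sum(lam)))
})

test_that("synthetic subjects are deterministic with the requested lesions", {
  g <- c(24L, 64L, 64L)
  s0 <- generate_synthetic_subject(5, n_lesions = 0, grid_shape = g,
                                   voxel_size_mm = 7.8)
  expect_identical(sum(s0$lesion_mask$data), 0)
  s3 <- generate_synthetic_subject(5, n_lesions = 3, grid_shape = g,
                                   voxel_size_mm = 7.8)
  expect_identical(count_components(s3$lesion_mask), 3L)
  s3b <- generate_synthetic_subject(5, n_lesions = 3, grid_shape = g,
                                    voxel_size_mm = 7.8)
  expect_identical(s3$activity$data, s3b$activity$data)
  expect_identical(s3$pseudo_ct$data, s3b$pseudo_ct$data)
  # lesions sit inside the body; CT shares the structural geometry
  expect_true(all(s3$activity$data[s3$lesion_mask$data == 1] > 1))
  expect_true(any(s3$pseudo_ct$data == 700))
})

test_that("paired datasets are aligned with independent noise realizations", {
  quads <- make_paired_dataset(ds_fast_acq(), ds_std_acq(), n_subjects = 1,
                               seed = 3, grid_shape = c(32L, 64L, 64L),
                               voxel_size_mm = 7.8)
  expect_length(quads, 1)
  q <- quads[[1]]
  expect_identical(dim(q$fast$data), dim(q$standard$data))
  expect_identical(dim(q$ct$data), dim(q$mask$data))
  # residuals of fast and standard about their own expectations are
  # uncorrelated (independent Poisson draws); residuals are standardized by
  # sqrt(lambda) so a few high-count voxels cannot dominate the estimate
  lam_f <- spectboost:::expected_counts(q$activity, ds_fast_acq())
  lam_s <- spectboost:::expected_counts(q$activity, ds_std_acq())
  rf <- (q$fast$data - lam_f) / sqrt(lam_f + 1e-9)
  rs <- (q$standard$data - lam_s) / sqrt(lam_s + 1e-9)
  expect_gte(length(rf), 1e5)
  expect_lt(abs(cor(as.numeric(rf), as.numeric(rs))), 0.02)
  # specs that differ beyond dwell are rejected
  bad <- ds_std_acq(); bad$psf_fwhm_mm <- 12
  expect_error(make_paired_dataset(ds_fast_acq(), bad, n_subjects = 1, seed = 1,
                                   grid_shape = c(24L, 64L, 64L),
                                   voxel_size_mm = 7.8),
               "differ only in dwell")
})

test_that("phantom quadruplet reuses the analytic phantom mask", {
  ph <- phantom_spec(grid_shape = c(32L, 64L, 64L), voxel_size_mm = 7.8)
  quads <- make_paired_dataset(ds_fast_acq(), ds_std_acq(), n_subjects = 0,
                               seed = 2, phantom = ph)
  expect_length(quads, 1)
  expect_identical(quads[[1]]$mask$data, build_phantom(ph)$lesion_mask$data)
})
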