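set.seed(202)

test_that("PSNR follows the printed formula", {
  # MAX = 100, MSE = 1 -> exactly 40 dB: a gt touching 100 and a unit-offset pred
  gt <- matrix(50, 10, 10); gt[1, 1] <- 100
  pred <- gt + 1
  expect_equal(psnr(pred, gt), 40, tolerance = 1e-12)
  # naive double-loop oracle on a random pair
  p <- array(runif(6^3, 0, 9), c(6, 6, 6))
  g <- array(runif(6^3, 0, 9), c(6, 6, 6))
  expect_equal(psnr(p, g), naive_psnr(p, g), tolerance = 1e-9)
  # scale invariance: MAX^2 and MSE both scale with c^2
  expect_equal(psnr(3 * p, 3 * g), psnr(p, g), tolerance = 1e-9)
  expect_message(v <- psnr(g, g), "identical")
  expect_identical(v, Inf)
  expect_error(psnr(p, array(0, dim(g))), "all zero")
})

test_that("SSIM matches the oracle and the loss-module implementation", {
  p <- matrix(runif(64, 0, 7), 8, 8)
  g <- matrix(runif(64, 0, 7), 8, 8)
  expect_equal(ssim(g, g, window = 5), 1, tolerance = 1e-12)
  expect_lt(ssim(-g, g, window = 5), 1)
  expect_equal(ssim(p, g, window = 5), naive_ssim(p, g, k = 5),
               tolerance = 1e-6)
  # single shared implementation: evaluation ssim and loss ssim agree
  expect_equal(1 - ssim(p, g, window = 5),
               ssim_loss(p, g, weights = loss_weights(ssim_window = 5)),
               tolerance = 1e-8)
  expect_error(ssim(p, g, window = 21), "larger than image")
})

test_that("SUV conversion is the printed linear formula", {
  v <- volume(array(50, c(4, 4, 4)), 2, "spect_counts")
  s <- to_suv(v, weight_g = 9700, dose_mbq = 485)
  expect_true(all(s$data == 1000))
  expect_identical(s$modality, "suv")
  z <- to_suv(volume(array(0, c(4, 4, 4)), 2, "spect_counts"), 9700, 485)
  expect_true(all(z$data == 0))
  expect_equal(to_suv(volume(v$data * 2, 2, "spect_counts"), 9700, 485)$data,
               2 * s$data)
  expect_error(to_suv(v, 0, 485), "positive")
})

test_that("sphere statistics recover the simulator ground truth", {
  spec <- phantom_spec(grid_shape = c(32L, 64L, 64L), voxel_size_mm = 7.8)
  ph <- build_phantom(spec)
  # noiseless, unblurred ratio-12 phantom as a pseudo-SUV volume
  suv <- volume(ph$activity$data, 7.8, "suv")
  st <- sphere_stats(suv, spec)
  expect_identical(st$sphere_id, 1:6)
  expect_identical(st$diameter_mm, sort(spec$sphere_diameters_mm, decreasing = TRUE))
  expect_equal(st$suv_mean / attr(st, "background_mean"), rep(12, 6),
               tolerance = 1e-6)
  expect_true(all(st$suv_max >= st$suv_mean))
  expect_identical(count_detectable_spheres(suv, spec), 6L)
  # constant volume: every sphere mean equals the constant, nothing detectable
  k <- volume(array(3.5, dim(ph$activity$data)), 7.8, "suv")
  stk <- sphere_stats(k, spec)
  expect_true(all(stk$suv_max == 3.5 & stk$suv_mean == 3.5))
  expect_identical(count_detectable_spheres(k, spec), 0L)
  # ratio-1 phantom: zero contrast, zero detectable spheres
  ph1 <- build_phantom(phantom_spec(grid_shape = c(32L, 64L, 64L),
                                    voxel_size_mm = 7.8, activity_ratio = 1))
  expect_identical(count_detectable_spheres(
    volume(ph1$activity$data, 7.8, "suv"), spec), 0L)
})

test_that("longer dwell never reduces detectability (paired seeds)", {
  spec <- phantom_spec(grid_shape = c(32L, 64L, 64L), voxel_size_mm = 7.8)
  ph <- build_phantom(spec)
  wins <- 0L
  for (s in 1:3) {
    fa <- ds_fast_acq(); fa$rng_seed <- 100 + s
    sa <- ds_std_acq(); sa$rng_seed <- 200 + s
    nf <- count_detectable_spheres(simulate_acquisition(ph$activity, fa), spec)
    nstd <- count_detectable_spheres(simulate_acquisition(ph$activity, sa), spec)
    wins <- wins + (nstd >= nf)
  }
  expect_gte(wins, 2L)
})

test_that("standard realizations are mutually closer than fast is to standard", {
  spec <- phantom_spec(grid_shape = c(32L, 64L, 64L), voxel_size_mm = 7.8)
  ph <- build_phantom(spec)
  sa1 <- ds_std_acq(); sa1$rng_seed <- 31
  sa2 <- ds_std_acq(); sa2$rng_seed <- 32
  fa <- ds_fast_acq(); fa$rng_seed <- 33
  s1 <- simulate_acquisition(ph$activity, sa1)
  s2 <- simulate_acquisition(ph$activity, sa2)
  f1 <- simulate_acquisition(ph$activity, fa)
  # compare on the count-rate scale so dwell time does not confound the MSE
  expect_gt(psnr(rate_data(s1, ds_std_time), rate_data(s2, ds_std_time)),
            psnr(rate_data(f1, ds_fast_time), rate_data(s2, ds_std_time)))
})

test_that("difference maps are signed, antisymmetric and linear in the mean", {
  a <- volume(array(runif(6^3), c(6, 6, 6)), 2, "spect_counts")
  b <- volume(array(runif(6^3), c(6, 6, 6)), 2, "spect_counts")
  expect_true(all(difference_map(a, a)$data == 0))
  expect_equal(difference_map(a, b)$data, -difference_map(b, a)$data)
  expect_equal(mean(difference_map(a, b)$data), mean(b$data) - mean(a$data),
               tolerance = 1e-12)
  bounds <- attr(difference_map(a, b), "display_bounds")
  expect_equal(bounds[1], -bounds[2])
})

test_that("per-slice metrics reports carry one row per slice", {
  p <- volume(array(runif(4 * 16 * 16, 1, 2), c(4, 16, 16)), 2, "spect_counts")
  g <- volume(array(runif(4 * 16 * 16, 1, 2), c(4, 16, 16)), 2, "spect_counts")
  rep <- metrics_report(p, g, window = 5, per_slice = TRUE)
  expect_identical(nrow(rep), 5L)
  expect_identical(rep$scope[1], "volume")
  expect_true(all(rep$ssim <= 1))
})
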