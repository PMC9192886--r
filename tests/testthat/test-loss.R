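set.seed(101)

test_that("L1 loss matches its elementwise definition", {
  p <- matrix(rnorm(64), 8, 8)
  t <- matrix(rnorm(64), 8, 8)
  expect_identical(l1_loss(t, t), 0)
  expect_equal(l1_loss(t + 0.5, t), 0.5, tolerance = 1e-12)
  # brute-force elementwise oracle
  expect_equal(l1_loss(p, t), sum(abs(p - t)) / 64, tolerance = 1e-7)
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_equal(l1_loss(p, t, m), sum(abs(p - t) * m) / sum(m), tolerance = 1e-7)
  expect_message(v0 <- l1_loss(p, t, matrix(0, 8, 8)), "empty")
  expect_identical(v0, 0)
})

test_that("SSIM loss agrees with the direct windowed-formula oracle", {
  w5 <- loss_weights(ssim_window = 5)
  t <- matrix(runif(64, 0, 10), 8, 8)
  expect_equal(ssim_loss(t, t, weights = w5), 0, tolerance = 1e-12)
  p <- matrix(runif(64, 0, 10), 8, 8)
  l <- ssim_loss(p, t, weights = w5)
  expect_gt(l, 0); expect_lte(l, 2)
  expect_equal(l, 1 - naive_ssim(p, t, k = 5), tolerance = 1e-6)
  expect_error(loss_weights(ssim_window = 10), "odd")
  expect_error(ssim_loss(matrix(0, 4, 4), matrix(0, 4, 4),
                         weights = loss_weights(ssim_window = 11)), "window")
})

test_that("composite loss is L1 + alpha * SSIM with the documented degeneracies", {
  p <- matrix(runif(144, 0, 5), 12, 12)
  t <- matrix(runif(144, 0, 5), 12, 12)
  w <- loss_weights(alpha = 0.5, ssim_window = 5)
  expect_equal(combined_loss(t, t, w), 0, tolerance = 1e-12)
  w0 <- loss_weights(alpha = 0, ssim_window = 5)
  expect_equal(combined_loss(p, t, w0), l1_loss(p, t), tolerance = 1e-12)
  # arithmetic from independently computed components
  expect_equal(combined_loss(p, t, w),
               l1_loss(p, t) + 0.5 * ssim_loss(p, t, weights = w),
               tolerance = 1e-12)
})

test_that("lesion attention adds beta times the mask-restricted loss", {
  p <- matrix(runif(144, 0, 5), 12, 12)
  t <- matrix(runif(144, 0, 5), 12, 12)
  w <- loss_weights(beta = 100, ssim_window = 5)
  # empty mask: l == L
  expect_equal(lesion_attention_loss(p, t, matrix(0, 12, 12), w),
               combined_loss(p, t, w), tolerance = 1e-12)
  # full mask: masked region is the whole image, so l == (1 + beta) L
  expect_equal(lesion_attention_loss(p, t, matrix(1, 12, 12), w),
               (1 + 100) * combined_loss(p, t, w), tolerance = 1e-9)
  expect_equal(lesion_attention_loss(t, t, matrix(rbinom(144, 1, .5), 12, 12), w),
               0, tolerance = 1e-12)
})

test_that("deep-supervision total follows the printed weighted sum", {
  p <- matrix(runif(144, 0, 5), 12, 12)
  t <- matrix(runif(144, 0, 5), 12, 12)
  m <- matrix(rbinom(144, 1, 0.2), 12, 12)
  w <- loss_weights(ssim_window = 5)
  sides <- replicate(6, p, simplify = FALSE)
  expect_equal(total_loss(t, replicate(6, t, simplify = FALSE), t, m, w), 0,
               tolerance = 1e-12)
  # identical outputs with unit weights: total == 7 * lesion loss
  expect_equal(total_loss(p, sides, t, m, w),
               7 * lesion_attention_loss(p, t, m, w), tolerance = 1e-9)
  wz <- loss_weights(w_side = rep(0, 6), ssim_window = 5)
  expect_equal(total_loss(p, sides, t, m, wz),
               lesion_attention_loss(p, t, m, wz), tolerance = 1e-12)
  expect_error(total_loss(p, sides[1:5], t, m, w), "6 side outputs")
})

test_that("losses respond monotonically to increasing noise amplitude", {
  t <- matrix(rep(sin(seq(0, 4 * pi, length.out = 16)), 16), 16, 16) + 2
  eps <- matrix(rnorm(256), 16, 16)
  w <- loss_weights(ssim_window = 7)
  amps <- c(0.05, 0.2, 0.5, 1)
  l1s <- vapply(amps, function(a) l1_loss(t + a * eps, t), numeric(1))
  sss <- vapply(amps, function(a) ssim_loss(t + a * eps, t, weights = w),
                numeric(1))
  expect_true(all(diff(l1s) > 0))
  expect_true(all(diff(sss) > 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  t <- matrix(runif(64, 0, 4), 8, 8)
  p <- t + 0.3 + 0.2 * matrix(rnorm(64), 8, 8) # keep |p - t| away from 0
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  w <- loss_weights(ssim_window = 5)
  for (ty in c("l1", "ssim", "combined")) {
    an <- loss_with_gradient(p, t, weights = w, type = ty)
    fd <- fd_gradient(function(x) switch(ty,
      l1 = l1_loss(x, t), ssim = ssim_loss(x, t, weights = w),
      combined = combined_loss(x, t, w)), p)
    expect_lt(max(abs(an$gradient - fd)) / max(abs(fd)), 1e-4)
  }
  an <- loss_with_gradient(p, t, m, w, type = "lesion")
  fd <- fd_gradient(function(x) lesion_attention_loss(x, t, m, w), p)
  expect_lt(max(abs(an$gradient - fd)) / max(abs(fd)), 1e-4)
})
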