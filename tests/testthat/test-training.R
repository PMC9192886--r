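# Small-scale optimization checks: 32 x 32 slices, narrow model, few epochs.

tiny_samples <- function(n = 4, seed = 77) {
  quads <- cache_get("tinyquads", function()
    make_paired_dataset(ds_fast_acq(), ds_std_acq(), n_subjects = 1,
                        seed = seed, grid_shape = c(8L, 32L, 32L),
                        voxel_size_mm = 15.6))
  q <- quads[[1]]
  make_samples(q$fast, q$ct, q$standard, q$mask)[seq_len(n)]
}

test_that("the learning-rate schedule divides the rate at the drop epoch", {
  m <- build_u2net(u2net_config(2, 4), seed = 1)
  cfg <- train_config(epochs = 3, batch_size = 4, lr = 2e-4,
                      lr_drop_epoch = 2, lr_drop_factor = 10, seed = 1)
  fit <- train(m, tiny_samples(), loss_weights(ssim_window = 7), cfg)
  expect_equal(fit$history$lr, c(2e-4, 2e-5, 2e-5))
  expect_identical(nrow(fit$history), 3L)
  expect_error(train_config(epochs = 10, lr_drop_epoch = 20), "lr_drop_epoch")
})

test_that("training is reproducible from the seed", {
  w <- loss_weights(ssim_window = 7)
  cfg <- desk_train_config(epochs = 2, seed = 5)
  f1 <- train(build_u2net(u2net_config(2, 4), seed = 2), tiny_samples(), w, cfg)
  f2 <- train(build_u2net(u2net_config(2, 4), seed = 2), tiny_samples(), w, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("volume enhancement keeps the grid, clamps negatives and inverts
          normalization through the fast divisor", {
  quads <- make_paired_dataset(ds_fast_acq(), ds_std_acq(), n_subjects = 1,
                               seed = 12, grid_shape = c(8L, 64L, 64L),
                               voxel_size_mm = 7.8)
  q <- quads[[1]]
  # a freshly built model has a zero fusion head: the generator is exactly
  # the identity through its long skip, so enhancement must reproduce the
  # fast volume through the normalize/denormalize round trip
  m <- build_u2net(u2net_config(2, 8), seed = 3)
  out <- enhance_volume(m, q$fast, q$ct)
  expect_identical(dim(out$data), dim(q$fast$data))
  expect_lt(max(abs(out$data - q$fast$data)) / max(q$fast$data), 1e-5)
  expect_gte(min(out$data), 0)
  # channel mismatch and grid mismatch are caught
  expect_error(enhance_volume(m, q$fast, q$ct, use_ct = FALSE), "channels")
  small_ct <- volume(q$ct$data[1:4, , ], 7.8, "ct")
  expect_error(enhance_volume(m, q$fast, small_ct), "same grid")
})

test_that("demo configs merge overrides and round-trip through YAML", {
  cfg <- demo_config()
  over <- spectboost:::modify_list(cfg, list(train = list(epochs = 2), seed = 3))
  expect_identical(over$train$epochs, 2)
  expect_identical(over$seed, 3)
  expect_identical(over$simulate$grid_shape, cfg$simulate$grid_shape)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  back <- yaml::read_yaml(f)
  expect_equal(back$loss$beta, cfg$loss$beta)
  expect_equal(unlist(back$simulate), unlist(cfg$simulate))
  unlink(f)
})
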