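ns <- asNamespace("spectboost")

test_that("RSU blocks preserve spatial shape (pooled and dilated variants)", {
  cfg7 <- rsu_config(7, 2, 2, 4)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  y <- rsu_forward(cfg7, x, seed = 1)
  expect_identical(dim(y), c(64L, 64L, 4L))
  # dilated RS-4 imposes no divisibility constraint (13 x 13 passes through)
  cfg4f <- rsu_config(4, 3, 2, 3, dilated = TRUE)
  xd <- array(rnorm(13 * 13 * 3), c(13, 13, 3))
  expect_identical(dim(rsu_forward(cfg4f, xd, seed = 1)), c(13L, 13L, 3L))
  # non-dilated blocks refuse incompatible sizes with a divisibility message
  expect_error(rsu_forward(cfg7, array(0, c(33, 33, 2)), seed = 1),
               "divisible by 32")
})

test_that("zeroed inner-U reduces an RSU block to its input-convolution branch", {
  cfg <- rsu_config(5, 2, 3, 4)
  p <- rsu_parameters(cfg, seed = 2)
  for (nm in names(p))
    if (!startsWith(nm, "rsu.convin")) p[[nm]] <- p[[nm]] * 0
  x <- array(rnorm(32 * 32 * 2 * 1), c(32, 32, 2, 1))
  out <- rsu_forward(cfg, x, params = p)
  # the residual summand is zero, so output == conv-norm-relu of the input
  tape <- ns$new_tape()
  P <- lapply(p, function(v) ns$ag_leaf(tape, v))
  ref <- ns$cbr(list(tape = tape, P = P), "rsu.convin", ns$ag_leaf(tape, x))
  expect_equal(out, ref$value, tolerance = 1e-12)
})

test_that("the generator has the published stage layout", {
  cfg <- u2net_config(in_channels = 2, base_channels = 8)
  st <- u2net_stages(cfg)
  expect_identical(nrow(st), 11L)
  expect_identical(sum(st$dilated), 3L)                      # En5, En6, De5
  expect_identical(st$stage[st$dilated], c("en5", "en6", "de5"))
  expect_identical(st$height[st$role == "encoder"], c(7L, 6L, 5L, 4L, 4L, 4L))
  expect_identical(st$height[st$role == "decoder"], c(4L, 4L, 5L, 6L, 7L))
  expect_identical(cfg$n_side_outputs, 6L)
  expect_error(u2net_config(base_channels = 6), "multiple of 4")
  expect_error(u2net_config(in_channels = 3), "1 or 2")
})

test_that("all seven outputs match the input spatial shape", {
  m <- build_u2net(u2net_config(2, 8), seed = 4)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  out <- u2net_forward(m, x)
  expect_identical(dim(out$final), c(64L, 64L))
  expect_length(out$side_outputs, 6L)
  for (s in out$side_outputs) expect_identical(dim(s), c(64L, 64L))
  # single-channel (no-CT ablation) model accepts 1-channel input
  m1 <- build_u2net(u2net_config(1, 8), seed = 4)
  out1 <- u2net_forward(m1, array(rnorm(64 * 64), c(64, 64, 1)))
  expect_identical(dim(out1$final), c(64L, 64L))
  # contract errors
  expect_error(u2net_forward(m, array(0, c(48, 48, 2))), "divisible by 32")
  expect_error(u2net_forward(m, array(0, c(64, 64, 1))), "channels")
})

test_that("encoder and decoder stages run at mirrored resolutions", {
  m <- build_u2net(u2net_config(2, 8), seed = 1)
  g <- ns$u2net_graph(m, array(rnorm(64 * 64 * 2), c(64, 64, 2, 1)))
  sz <- g$stage_sizes # e1..e6, d5..d1
  expect_identical(vapply(sz[1:6], `[`, integer(1), 1), c(64L, 32L, 16L, 8L, 4L, 2L))
  expect_identical(vapply(sz[7:11], `[`, integer(1), 1), c(4L, 8L, 16L, 32L, 64L))
})

test_that("width scaling shrinks convolution parameters quadratically", {
  n16 <- count_parameters(build_u2net(u2net_config(2, 16), seed = 1), conv_only = TRUE)
  n4 <- count_parameters(build_u2net(u2net_config(2, 4), seed = 1), conv_only = TRUE)
  expect_gt(n16 / n4, 12)   # ~16x fewer conv weights at 4x narrower,
  expect_lt(n16 / n4, 16.5) # slightly less because input channels are fixed
})

test_that("zeroed fusion head isolates the long skip", {
  m <- build_u2net(u2net_config(2, 8), seed = 9)
  m$params[["fuse.w"]] <- m$params[["fuse.w"]] * 0
  m$params[["fuse.b"]] <- m$params[["fuse.b"]] * 0
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  out <- u2net_forward(m, x)
  expect_equal(out$final, x[, , 1], tolerance = 1e-12)
})

test_that("inference is deterministic and initialization is seed-controlled", {
  m <- build_u2net(u2net_config(2, 8), seed = 11)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  expect_identical(u2net_forward(m, x)$final, u2net_forward(m, x)$final)
  m2 <- build_u2net(u2net_config(2, 8), seed = 11)
  expect_identical(m$params, m2$params)
  m3 <- build_u2net(u2net_config(2, 8), seed = 12)
  expect_false(identical(m$params, m3$params))
})

test_that("every parameter receives gradient for a generic input", {
  m <- build_u2net(u2net_config(2, 4), seed = 3)
  x <- array(rnorm(64 * 64 * 2 * 1), c(64, 64, 2, 1))
  tgt <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  msk <- array(rbinom(64 * 64, 1, 0.1), c(64, 64, 1, 1))
  g <- ns$u2net_graph(m, x, train = TRUE)
  lw <- loss_weights()
  tot <- ns$ag_lesion(g$tape, g$final, tgt, msk, lw)$loss
  for (i in 1:6)
    tot <- ns$ag_add(g$tape, tot,
                     ns$ag_lesion(g$tape, g$sides[[i]], tgt, msk, lw)$loss)
  ns$ag_backward(g$tape, tot)
  dead <- names(m$params)[vapply(names(m$params), function(nm) {
    gr <- g$param_nodes[[nm]]$grad
    is.null(gr) || all(gr == 0)
  }, logical(1))]
  expect_identical(dead, character(0))
})

test_that("checkpoints round-trip the model", {
  m <- build_u2net(u2net_config(2, 4), seed = 6)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m$params, m2$params)
  expect_identical(m$config, m2$config)
  unlink(f)
})
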