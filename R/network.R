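#' Residual U-block configuration
#'
#' An RSU block is a small U-Net of height `L` wrapped in a residual
#' connection: an input convolution lifts the feature map to `out_channels`,
#' an encoder-decoder of `mid_channels`-wide stages extracts multi-scale
#' features, and the result is summed with the input-convolution branch. In
#' the dilated variant ("RS-L") pooling/upsampling is replaced by dilated
#' convolutions so the spatial size never changes.
#'
#' @param height_L block height (>= 2), e.g. 7, 6, 5, 4.
#' @param in_channels,mid_channels,out_channels positive channel counts.
#' @param dilated logical; `TRUE` for the RS-L (dilated) variant.
#' @return an `rsu_config` list.
#' @export
rsu_config <- function(height_L, in_channels, mid_channels, out_channels,
                       dilated = FALSE) {
  if (height_L < 2) stop("RSU height must be >= 2")
  if (any(c(in_channels, mid_channels, out_channels) < 1))
    stop("channel counts must be positive")
  structure(list(height_L = as.integer(height_L),
                 in_channels = as.integer(in_channels),
                 mid_channels = as.integer(mid_channels),
                 out_channels = as.integer(out_channels),
                 dilated = isTRUE(dilated)),
            class = "rsu_config")
}

#' Nested-U generator configuration
#'
#' The generator has a 6-stage encoder (RSU-7, RSU-6, RSU-5, RSU-4 followed
#' by two dilated RS-4 blocks at the bottom) and a 5-stage decoder (a dilated
#' RS-4 followed by RSU-4, RSU-5, RSU-6, RSU-7), with max-pool downsampling
#' between encoder stages and bilinear upsampling between decoder stages.
#' Six side outputs (the five decoder stages plus the deepest encoder stage)
#' are projected to one channel, upsampled to the input size and fused by a
#' 1x1 convolution; a long skip connection adds the fast-SPECT input channel
#' to the fused image. All outputs are linear (unbounded intensities).
#'
#' `base_channels` scales every stage width; 64 reproduces the full-size
#' network, 8 is the desk-scale preset.
#'
#' @param in_channels 2 (fast SPECT + CT) or 1 (SPECT-only ablation).
#' @param base_channels width multiple of 4.
#' @return a `u2net_config` list.
#' @export
u2net_config <- function(in_channels = 2, base_channels = 64) {
  if (!in_channels %in% 1:2) stop("in_channels must be 1 or 2")
  bc <- as.integer(base_channels)
  if (bc < 4 || bc %% 4L != 0L) stop("base_channels must be a positive multiple of 4")
  enc <- list(
    en1 = rsu_config(7, in_channels, bc / 2, bc),
    en2 = rsu_config(6, bc, bc / 2, 2 * bc),
    en3 = rsu_config(5, 2 * bc, bc, 4 * bc),
    en4 = rsu_config(4, 4 * bc, 2 * bc, 8 * bc),
    en5 = rsu_config(4, 8 * bc, 4 * bc, 8 * bc, dilated = TRUE),
    en6 = rsu_config(4, 8 * bc, 4 * bc, 8 * bc, dilated = TRUE))
  dec <- list(
    de5 = rsu_config(4, 16 * bc, 4 * bc, 8 * bc, dilated = TRUE),
    de4 = rsu_config(4, 16 * bc, 2 * bc, 4 * bc),
    de3 = rsu_config(5, 8 * bc, bc, 2 * bc),
    de2 = rsu_config(6, 4 * bc, bc / 2, bc),
    de1 = rsu_config(7, 2 * bc, max(bc / 4, 1), bc))
  structure(list(in_channels = as.integer(in_channels), base_channels = bc,
                 encoder_blocks = enc, decoder_blocks = dec,
                 n_side_outputs = 6L),
            class = "u2net_config")
}

#' Stage table of a generator configuration
#'
#' @param cfg a [u2net_config()] or model.
#' @return data.frame with one row per encoder/decoder stage.
#' @export
u2net_stages <- function(cfg) {
  if (inherits(cfg, "u2net_model")) cfg <- cfg$config
  blocks <- c(cfg$encoder_blocks, cfg$decoder_blocks)
  data.frame(stage = names(blocks),
             role = rep(c("encoder", "decoder"), c(6, 5)),
             height = vapply(blocks, `[[`, integer(1), "height_L"),
             dilated = vapply(blocks, `[[`, logical(1), "dilated"),
             in_channels = vapply(blocks, `[[`, integer(1), "in_channels"),
             mid_channels = vapply(blocks, `[[`, integer(1), "mid_channels"),
             out_channels = vapply(blocks, `[[`, integer(1), "out_channels"),
             row.names = NULL)
}

# ---- parameters ----------------------------------------------------------

# Kaiming fan-in init; the output heads use reduced gain (side taps) or zero
# (fusion conv) so the model starts at the identity mapping carried by the
# long skip connection instead of adding random side content to the output.
param_conv <- function(store, name, kh, kw, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (kh * kw * cin))
  store[[paste0(name, ".w")]] <- array(stats::rnorm(kh * kw * cin * cout, 0, sd),
                                       c(kh, kw, cin, cout))
  store[[paste0(name, ".b")]] <- numeric(cout)
  invisible(NULL)
}

# conv + norm + relu parameters; the convolution carries no bias because the
# following normalization subtracts any channel constant (the norm's shift
# plays that role).
param_cbr <- function(store, name, cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  store[[paste0(name, ".w")]] <- array(stats::rnorm(9 * cin * cout, 0, sd),
                                       c(3, 3, cin, cout))
  store[[paste0(name, ".g")]] <- rep(1, cout)
  store[[paste0(name, ".s")]] <- rep(0, cout)
  invisible(NULL)
}

rsu_param_defs <- function(store, name, cfg) {
  L <- cfg$height_L
  param_cbr(store, paste0(name, ".convin"), cfg$in_channels, cfg$out_channels)
  param_cbr(store, paste0(name, ".enc1"), cfg$out_channels, cfg$mid_channels)
  if (L > 2)
    for (d in 2:(L - 1))
      param_cbr(store, paste0(name, ".enc", d), cfg$mid_channels, cfg$mid_channels)
  param_cbr(store, paste0(name, ".enc", L), cfg$mid_channels, cfg$mid_channels)
  if (L > 2)
    for (d in (L - 1):2)
      param_cbr(store, paste0(name, ".dec", d), 2 * cfg$mid_channels, cfg$mid_channels)
  param_cbr(store, paste0(name, ".dec1"), 2 * cfg$mid_channels, cfg$out_channels)
}

#' Build the nested-U generator
#'
#' Allocates and initializes all parameters (Kaiming fan-in, seed-controlled;
#' output heads at reduced gain so the network starts near the identity
#' through its long skip connection).
#'
#' @param cfg a [u2net_config()].
#' @param seed integer seed for the initialization.
#' @return a `u2net_model` (config + named parameter list).
#' @export
build_u2net <- function(cfg = u2net_config(), seed = 1) {
  stopifnot(inherits(cfg, "u2net_config"))
  blocks <- c(cfg$encoder_blocks, cfg$decoder_blocks)
  if (length(cfg$encoder_blocks) != 6L || length(cfg$decoder_blocks) != 5L)
    stop("invalid stage list: need 6 encoder and 5 decoder stages")
  if (sum(vapply(blocks, `[[`, logical(1), "dilated")) != 3L)
    stop("invalid stage list: exactly 3 dilated stages are required")
  store <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (nm in names(blocks)) rsu_param_defs(store, nm, blocks[[nm]])
    side_src <- c("de1", "de2", "de3", "de4", "de5", "en6")
    for (i in seq_along(side_src)) {
      cout <- blocks[[side_src[i]]]$out_channels
      param_conv(store, paste0("side", i), 3, 3, cout, 1, gain = 0.1)
    }
    param_conv(store, "fuse", 1, 1, 6, 1, gain = 0) # zero-init: start at identity
  })
  params <- as.list(store)
  params <- params[order(names(params))]
  structure(list(config = cfg, params = params), class = "u2net_model")
}

#' @export
print.u2net_model <- function(x, ...) {
  cat(sprintf("<u2net_model> in_channels=%d base_channels=%d, %d parameters\n",
              x$config$in_channels, x$config$base_channels,
              count_parameters(x)))
  invisible(x)
}

#' Count model parameters
#'
#' @param model a `u2net_model`.
#' @param conv_only count only convolution weights (no biases or
#'   normalization gains).
#' @return integer parameter count.
#' @export
count_parameters <- function(model, conv_only = FALSE) {
  p <- model$params
  if (conv_only) p <- p[grepl("\\.w$", names(p))]
  sum(vapply(p, length, numeric(1)))
}

# ---- forward pass --------------------------------------------------------

cbr <- function(ctx, name, x, dil = 1L) {
  w <- ctx$P[[paste0(name, ".w")]]
  zero_b <- ag_leaf(ctx$tape, numeric(dim(w$value)[4])) # bias-free conv: the
  y <- ag_conv2d(ctx$tape, x, w, zero_b, pad = dil, dil = dil) # norm shifts
  y <- ag_norm(ctx$tape, y, ctx$P[[paste0(name, ".g")]], ctx$P[[paste0(name, ".s")]])
  ag_relu(ctx$tape, y)
}

rsu_block <- function(ctx, name, cfg, x) {
  L <- cfg$height_L
  if (cfg$dilated) {
    xin <- cbr(ctx, paste0(name, ".convin"), x)
    e <- vector("list", L)
    e[[1]] <- cbr(ctx, paste0(name, ".enc1"), xin, dil = 1L)
    for (d in 2:L)
      e[[d]] <- cbr(ctx, paste0(name, ".enc", d), e[[d - 1]], dil = 2L^(d - 1))
    h <- e[[L]]
    if (L > 2)
      for (d in (L - 1):2)
        h <- cbr(ctx, paste0(name, ".dec", d), ag_concat(ctx$tape, list(h, e[[d]])),
                 dil = 2L^(d - 1))
    h <- cbr(ctx, paste0(name, ".dec1"), ag_concat(ctx$tape, list(h, e[[1]])))
    return(ag_add(ctx$tape, h, xin))
  }
  d0 <- dim4(x$value)
  need <- 2L^(L - 2L)
  if (d0[1] %% need != 0L || d0[2] %% need != 0L)
    stop("RSU-", L, " needs spatial sides divisible by ", need,
         ", got ", d0[1], "x", d0[2])
  xin <- cbr(ctx, paste0(name, ".convin"), x)
  e <- vector("list", L - 1L)
  sizes <- vector("list", L - 1L)
  e[[1]] <- cbr(ctx, paste0(name, ".enc1"), xin)
  sizes[[1]] <- dim4(e[[1]]$value)[1:2]
  h <- e[[1]]
  if (L > 2) {
    for (d in 2:(L - 1)) {
      h <- ag_maxpool2(ctx$tape, h)
      e[[d]] <- cbr(ctx, paste0(name, ".enc", d), h)
      sizes[[d]] <- dim4(e[[d]]$value)[1:2]
      h <- e[[d]]
    }
  }
  h <- cbr(ctx, paste0(name, ".enc", L), h, dil = 2L) # bottom, dilated, no pool
  if (L > 2) {
    for (d in (L - 1):2) {
      h <- cbr(ctx, paste0(name, ".dec", d), ag_concat(ctx$tape, list(h, e[[d]])))
      h <- ag_resize(ctx$tape, h, sizes[[d - 1]][1], sizes[[d - 1]][2])
    }
  }
  h <- cbr(ctx, paste0(name, ".dec1"), ag_concat(ctx$tape, list(h, e[[1]])))
  ag_add(ctx$tape, h, xin)
}

# Full forward pass on a (H, W, C, N) array. Returns autograd nodes.
u2net_graph <- function(model, x, train = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) != 4L) stop("input must be a (H, W, C, N) array")
  if (d[3] != cfg$in_channels)
    stop("model expects ", cfg$in_channels, " input channels, got ", d[3])
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial sides must be divisible by 32, got ", d[1], "x", d[2])
  tape <- new_tape()
  P <- lapply(model$params, function(v) ag_leaf(tape, v, requires_grad = train))
  ctx <- list(tape = tape, P = P)
  xin <- ag_leaf(tape, x)
  eb <- cfg$encoder_blocks
  db <- cfg$decoder_blocks
  e1 <- rsu_block(ctx, "en1", eb$en1, xin)
  e2 <- rsu_block(ctx, "en2", eb$en2, ag_maxpool2(tape, e1))
  e3 <- rsu_block(ctx, "en3", eb$en3, ag_maxpool2(tape, e2))
  e4 <- rsu_block(ctx, "en4", eb$en4, ag_maxpool2(tape, e3))
  e5 <- rsu_block(ctx, "en5", eb$en5, ag_maxpool2(tape, e4))
  e6 <- rsu_block(ctx, "en6", eb$en6, ag_maxpool2(tape, e5))
  sz <- function(nd) dim4(nd$value)[1:2]
  up <- function(nd, ref) ag_resize(tape, nd, sz(ref)[1], sz(ref)[2])
  d5 <- rsu_block(ctx, "de5", db$de5, ag_concat(tape, list(up(e6, e5), e5)))
  d4 <- rsu_block(ctx, "de4", db$de4, ag_concat(tape, list(up(d5, e4), e4)))
  d3 <- rsu_block(ctx, "de3", db$de3, ag_concat(tape, list(up(d4, e3), e3)))
  d2 <- rsu_block(ctx, "de2", db$de2, ag_concat(tape, list(up(d3, e2), e2)))
  d1 <- rsu_block(ctx, "de1", db$de1, ag_concat(tape, list(up(d2, e1), e1)))
  taps <- list(d1, d2, d3, d4, d5, e6)
  sides <- vector("list", 6L)
  for (i in 1:6) {
    s <- ag_conv2d(tape, taps[[i]], P[[paste0("side", i, ".w")]],
                   P[[paste0("side", i, ".b")]], pad = 1L)
    sides[[i]] <- ag_resize(tape, s, d[1], d[2])
  }
  fused <- ag_conv2d(tape, ag_concat(tape, sides), P[["fuse.w"]],
                     P[["fuse.b"]], pad = 0L)
  final <- ag_add(tape, fused, ag_channel(tape, xin, 1L))
  list(final = final, sides = sides, tape = tape, param_nodes = P,
       stage_sizes = lapply(list(e1, e2, e3, e4, e5, e6, d5, d4, d3, d2, d1), sz))
}

#' Run the generator on an input slab
#'
#' @param model a `u2net_model`.
#' @param x input array `(H, W, C)` for a single slice or `(H, W, C, N)` for a
#'   batch; spatial sides must be divisible by 32.
#' @return list with `final` (`(H, W)` matrix, or `(H, W, N)` for a batch) and
#'   `side_outputs` (list of 6 arrays of the same spatial shape).
#' @export
u2net_forward <- function(model, x) {
  stopifnot(inherits(model, "u2net_model"))
  d <- dim(x)
  single <- length(d) == 3L
  if (single) dim(x) <- c(d, 1L)
  g <- u2net_graph(model, x, train = FALSE)
  squeeze <- function(a) {
    dd <- dim(a)
    if (dd[4] == 1L) matrix(a, dd[1], dd[2]) else array(a, dd[c(1, 2, 4)])
  }
  list(final = squeeze(g$final$value),
       side_outputs = lapply(g$sides, function(s) squeeze(s$value)))
}

#' Run a standalone residual U-block
#'
#' Mostly useful for inspection and testing: builds a single RSU (or dilated
#' RS) block with seeded parameters and applies it to `x`.
#'
#' @param cfg an [rsu_config()].
#' @param x `(H, W, C)` or `(H, W, C, N)` input array.
#' @param params optional named parameter list (as produced by
#'   [rsu_parameters()]); freshly initialized when omitted.
#' @param seed seed for fresh initialization.
#' @return array of the input's spatial shape with `cfg$out_channels`
#'   channels.
#' @export
rsu_forward <- function(cfg, x, params = NULL, seed = 1) {
  stopifnot(inherits(cfg, "rsu_config"))
  d <- dim(x)
  single <- length(d) == 3L
  if (single) dim(x) <- c(d, 1L)
  if (dim(x)[3] != cfg$in_channels)
    stop("input has ", dim(x)[3], " channels, config expects ", cfg$in_channels)
  if (is.null(params)) params <- rsu_parameters(cfg, seed)
  tape <- new_tape()
  P <- lapply(params, function(v) ag_leaf(tape, v))
  ctx <- list(tape = tape, P = P)
  out <- rsu_block(ctx, "rsu", cfg, ag_leaf(tape, x))
  y <- out$value
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Initialize parameters for a standalone RSU block
#'
#' @param cfg an [rsu_config()].
#' @param seed integer seed.
#' @return named list of parameter arrays (prefix `rsu.`).
#' @export
rsu_parameters <- function(cfg, seed = 1) {
  store <- new.env(parent = emptyenv())
  with_seed(seed, rsu_param_defs(store, "rsu", cfg))
  p <- as.list(store)
  p[order(names(p))]
}
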