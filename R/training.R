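#' Training configuration
#'
#' Full-scale defaults: 100 epochs, batch size 4 (axial slices), Adam with
#' learning rate 2e-4 divided by 10 from epoch 80. The desk preset shrinks
#' the schedule for CPU-scale experiments without changing the optimizer.
#'
#' @param epochs number of epochs.
#' @param batch_size slices per optimization step.
#' @param lr Adam learning rate.
#' @param lr_drop_epoch epoch from which the rate is divided.
#' @param lr_drop_factor division factor.
#' @param seed seed controlling shuffling (and any model init done here).
#' @param use_ct include the CT channel.
#' @param desk_preset logical; `desk_train_config()` builds a reduced
#'   schedule.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 4, lr = 2e-4,
                         lr_drop_epoch = 80, lr_drop_factor = 10,
                         seed = 1, use_ct = TRUE, desk_preset = FALSE) {
  if (lr <= 0) stop("lr must be > 0")
  if (lr_drop_epoch > epochs) stop("lr_drop_epoch must be <= epochs")
  if (batch_size < 1 || epochs < 1) stop("epochs and batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_drop_factor = lr_drop_factor, seed = as.integer(seed),
                 use_ct = isTRUE(use_ct), desk_preset = isTRUE(desk_preset)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... overrides passed to [train_config()].
#' @export
desk_train_config <- function(epochs = 8, batch_size = 4, lr = 2e-4, ...) {
  train_config(epochs = epochs, batch_size = batch_size, lr = lr,
               lr_drop_epoch = epochs, desk_preset = TRUE, ...)
}

#' Train the generator
#'
#' Adam optimization of the deep-supervision lesion-attention total loss over
#' shuffled mini-batches of paired axial slices. Shuffling is seeded and
#' single-threaded, so a fixed seed reproduces the loss history exactly.
#' Training aborts with diagnostics if the loss becomes non-finite.
#'
#' @param model a `u2net_model`.
#' @param samples list of `paired_sample`s (see [make_samples()]).
#' @param weights a [loss_weights()].
#' @param cfg a [train_config()].
#' @param verbose print a line per epoch.
#' @return list with `model` (trained) and `history` (data.frame: epoch, lr,
#'   total, l1, ssim, lesion).
#' @export
train <- function(model, samples, weights = loss_weights(),
                  cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "u2net_model"), inherits(cfg, "train_config"))
  if (length(samples) < 1) stop("need at least one training sample")
  params <- model$params
  mstate <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  vstate <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  step <- 0L
  hist <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- if (ep >= cfg$lr_drop_epoch) cfg$lr / cfg$lr_drop_factor else cfg$lr
      ord <- sample.int(length(samples))
      comp <- c(total = 0, l1 = 0, ssim = 0, lesion = 0)
      nb <- 0L
      for (b0 in seq(1L, length(samples), by = cfg$batch_size)) {
        idx <- ord[b0:min(length(samples), b0 + cfg$batch_size - 1L)]
        batch <- assemble_batch(samples[idx], use_ct = cfg$use_ct)
        g <- u2net_graph(model, batch$x, train = TRUE)
        lf <- ag_lesion(g$tape, g$final, batch$target, batch$mask, weights)
        tot <- ag_scale_shift(g$tape, lf$loss, weights$w_final, 0)
        for (i in 1:6) {
          ls <- ag_lesion(g$tape, g$sides[[i]], batch$target, batch$mask, weights)
          tot <- ag_add(g$tape, tot,
                        ag_scale_shift(g$tape, ls$loss, weights$w_side[i], 0))
        }
        tv <- as.numeric(tot$value)
        if (!is.finite(tv))
          stop(sprintf("non-finite loss at epoch %d batch %d (l1=%.4g ssim=%.4g)",
                       ep, nb + 1L, as.numeric(lf$whole$l1$value),
                       as.numeric(lf$whole$ssim$value)))
        ag_backward(g$tape, tot)
        step <- step + 1L
        for (nm in names(params)) {
          gr <- g$param_nodes[[nm]]$grad
          if (is.null(gr)) next
          mstate[[nm]] <- 0.9 * mstate[[nm]] + 0.1 * gr
          vstate[[nm]] <- 0.999 * vstate[[nm]] + 0.001 * gr^2
          mhat <- mstate[[nm]] / (1 - 0.9^step)
          vhat <- vstate[[nm]] / (1 - 0.999^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
        model$params <- params
        comp <- comp + c(tv, as.numeric(lf$whole$l1$value),
                         as.numeric(lf$whole$ssim$value),
                         as.numeric(lf$lesion$loss$value))
        nb <- nb + 1L
      }
      comp <- comp / nb
      hist[[ep]] <- data.frame(epoch = ep, lr = lr, total = comp[1],
                               l1 = comp[2], ssim = comp[3], lesion = comp[4])
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  total %.5f  l1 %.5f  ssim %.5f",
                        ep, lr, comp[1], comp[2], comp[3]))
    }
  })
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(model = model, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enhance a fast-scan volume
#'
#' Normalizes the fast SPECT (and CT) by their own volume means, runs the
#' generator slice by slice in the axial plane, keeps only the final output,
#' restacks, returns to the count scale with the fast volume's divisor (the
#' only normalizer available at deployment) and clamps negatives to zero.
#'
#' @param model a trained `u2net_model`.
#' @param fast fast-scan SPECT volume.
#' @param ct CT volume on the SPECT grid (ignored when `use_ct = FALSE`).
#' @param use_ct must match the model's input channels.
#' @return enhanced `spect_counts`-scale volume on the input grid.
#' @export
enhance_volume <- function(model, fast, ct = NULL, use_ct = TRUE) {
  stopifnot_volume(fast)
  want <- if (use_ct) 2L else 1L
  if (model$config$in_channels != want)
    stop("model expects ", model$config$in_channels,
         " channels but use_ct implies ", want)
  nf <- normalize_by_mean(fast)
  if (use_ct) {
    stopifnot_volume(ct)
    if (!same_grid(fast, ct)) stop("fast and CT volumes are not on the same grid")
    nc <- normalize_by_mean(ct_shift(ct))
  }
  d <- dim(fast$data)
  out <- array(0, d)
  chunk <- max(1L, min(d[1], floor(2^22 / (d[2] * d[3]))))
  for (s0 in seq(1L, d[1], by = chunk)) {
    sl <- s0:min(d[1], s0 + chunk - 1L)
    fs <- aperm(array(nf$volume$data[sl, , ], c(length(sl), d[2], d[3])), c(2, 3, 1))
    if (use_ct) {
      cs <- aperm(array(nc$volume$data[sl, , ], c(length(sl), d[2], d[3])), c(2, 3, 1))
      x <- array(0, c(d[2], d[3], 2L, length(sl)))
      x[, , 1L, ] <- fs
      x[, , 2L, ] <- cs
    } else {
      x <- array(fs, c(d[2], d[3], 1L, length(sl)))
    }
    g <- u2net_graph(model, x, train = FALSE)
    y <- g$final$value # (H, W, 1, n)
    for (j in seq_along(sl)) out[sl[j], , ] <- y[, , 1L, j]
  }
  out <- out * nf$divisor
  out[out < 0] <- 0
  volume(out, fast$voxel_size_mm, "spect_counts")
}
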