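# Shared fixtures and independent oracles. Everything is generated in code at
# test time; training runs are memoized so several tests can share one fit.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent brute-force oracles -------------------------------------

# PSNR recomputed from scratch with an explicit loop-free MSE kept deliberately
# naive (no reuse of package internals).
naive_psnr <- function(pred, gt) {
  stopifnot(identical(dim(pred), dim(gt)))
  mse <- 0
  n <- length(gt)
  for (i in seq_len(n)) mse <- mse + (pred[i] - gt[i])^2
  mse <- mse / n
  10 * log10(max(gt)^2 / mse)
}

# SSIM recomputed by sliding an explicit window and applying the printed
# formula directly at every valid position (box window, population variance).
naive_ssim <- function(pred, gt, k = 11, k1 = 0.01, k2 = 0.03) {
  r <- max(gt) - min(gt); if (r == 0) r <- 1
  c1 <- (k1 * r)^2; c2 <- (k2 * r)^2
  H <- nrow(gt); W <- ncol(gt)
  vals <- c()
  for (i in seq_len(H - k + 1)) {
    for (j in seq_len(W - k + 1)) {
      x <- pred[i:(i + k - 1), j:(j + k - 1)]
      y <- gt[i:(i + k - 1), j:(j + k - 1)]
      mx <- mean(x); my <- mean(y)
      vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
      cxy <- mean((x - mx) * (y - my))
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# Central finite-difference gradient of a scalar loss with respect to pred.
fd_gradient <- function(f, pred, eps = 1e-6) {
  g <- array(0, dim(pred))
  for (i in seq_along(pred)) {
    p1 <- pred; p1[i] <- pred[i] + eps
    p2 <- pred; p2[i] <- pred[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}

# ---- desk-scale study conditions ------------------------------------------

# 64 x 64 axial slices at 7.8 mm (clinical in-plane FOV at quarter
# resolution), 32 slices; standard dwell 20 s, fast 3 s, 60 projections.
ds_grid <- c(32L, 64L, 64L)
ds_vox <- 7.8
ds_fast_acq <- function() acquisition_spec(seconds_per_projection = 3)
ds_std_acq <- function() acquisition_spec(seconds_per_projection = 20)
ds_fast_time <- 3 * 60
ds_std_time <- 20 * 60
ds_epochs <- 5L

rate_data <- function(vol, total_time) vol$data / total_time

.spectboost_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.spectboost_cache[[key]])) .spectboost_cache[[key]] <- builder()
  .spectboost_cache[[key]]
}

# One desk dataset per seed: phantom + 2 synthetic subjects (last held out)
# plus a dedicated CT-ablation subject whose skeletal structure is bright in
# CT but nearly invisible in the fast SPECT (low uptake, drowned by Poisson
# noise at 3 s dwell).
desk_dataset <- function(seed) {
  cache_get(paste0("data", seed), function() {
    ph <- phantom_spec(grid_shape = ds_grid, voxel_size_mm = ds_vox)
    quads <- make_paired_dataset(ds_fast_acq(), ds_std_acq(), n_subjects = 2,
                                 seed = seed, phantom = ph,
                                 grid_shape = ds_grid, voxel_size_mm = ds_vox)
    smp_ph <- make_samples(quads[[1]]$fast, quads[[1]]$ct,
                           quads[[1]]$standard, quads[[1]]$mask)
    smp_s1 <- make_samples(quads[[2]]$fast, quads[[2]]$ct,
                           quads[[2]]$standard, quads[[2]]$mask)
    train_samples <- c(smp_ph[(ds_grid[1] %/% 2 + 1):ds_grid[1]], smp_s1)
    ab <- generate_synthetic_subject(rng_seed = seed + 555L, n_lesions = 2,
                                     grid_shape = ds_grid, voxel_size_mm = ds_vox,
                                     bone_uptake = 1.5)
    fa <- ds_fast_acq(); fa$rng_seed <- seed + 901L
    sa <- ds_std_acq(); sa$rng_seed <- seed + 902L
    list(phantom_spec = ph, phantom = quads[[1]], test = quads[[3]],
         train_samples = train_samples,
         ablation = list(fast = simulate_acquisition(ab$activity, fa),
                         standard = simulate_acquisition(ab$activity, sa),
                         ct = ab$pseudo_ct, mask = ab$lesion_mask))
  })
}

# Train one arm (use_ct x beta) under the desk schedule and evaluate it on
# the held-out subject, the CT-ablation subject and the held-out phantom
# half. Memoized so the enhancement and ablation criteria share fits.
trained_arm <- function(seed, use_ct = TRUE, beta = 100) {
  key <- paste0("arm", seed, "_", use_ct, "_", beta)
  cache_get(key, function() {
    d <- desk_dataset(seed)
    model <- build_u2net(u2net_config(in_channels = if (use_ct) 2 else 1,
                                      base_channels = 8), seed = seed)
    fit <- train(model, d$train_samples, loss_weights(beta = beta),
                 desk_train_config(epochs = ds_epochs, seed = seed,
                                   use_ct = use_ct))
    te <- d$test
    enh <- enhance_volume(fit$model, te$fast, te$ct, use_ct = use_ct)
    fr <- rate_data(te$fast, ds_fast_time)
    er <- rate_data(enh, ds_fast_time)
    sr <- rate_data(te$standard, ds_std_time)
    mk <- te$mask$data
    ab <- d$ablation
    ab_enh <- enhance_volume(fit$model, ab$fast, ab$ct, use_ct = use_ct)
    bone <- which(ab$ct$data >= 500, arr.ind = TRUE)
    bb <- apply(bone, 2, range)
    crop <- function(a) a[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3]]
    ph <- d$phantom
    ph_enh <- enhance_volume(fit$model, ph$fast, ph$ct, use_ct = use_ct)
    suv_tab <- function(v, total_time) {
      sphere_stats(volume(rate_data(v, total_time), ds_vox, "suv"),
                   d$phantom_spec)$suv_mean
    }
    suv_std <- suv_tab(ph$standard, ds_std_time)
    list(history = fit$history,
         psnr_fast = psnr(fr, sr), psnr_enh = psnr(er, sr),
         ssim_fast = ssim(fr, sr), ssim_enh = ssim(er, sr),
         ml1_fast = mean(abs(fr - sr)[mk == 1]),
         ml1_enh = mean(abs(er - sr)[mk == 1]),
         bbox_ssim = ssim(crop(rate_data(ab_enh, ds_fast_time)),
                          crop(rate_data(ab$standard, ds_std_time))),
         suv_err_fast = abs(suv_tab(ph$fast, ds_fast_time) - suv_std)[1:3],
         suv_err_enh = abs(suv_tab(ph_enh, ds_fast_time) - suv_std)[1:3])
  })
}
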