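#' Default desk-scale demo configuration
#'
#' The desk preset runs the whole simulate / train / enhance / evaluate
#' workflow on one CPU in minutes: 64 x 64 axial slices (7.8 mm voxels, the
#' clinical in-plane field of view at quarter resolution), a voxelized NEMA
#' IEC phantom plus synthetic subjects, a base-width-8 generator and a short
#' fixed training schedule. All values can be overridden through `...` of
#' [run_demo()] or the configuration file of the command-line tool.
#'
#' @return nested configuration list.
#' @export
demo_config <- function() {
  list(
    seed = 7,
    desk_preset = TRUE,
    simulate = list(
      grid_shape = c(32L, 64L, 64L),
      voxel_size_mm = 7.8,
      n_subjects = 3,
      n_lesions = 3,
      fast_dwell_s = 3,
      std_dwell_s = 20,
      n_projections = 60,
      psf_fwhm_mm = 8,
      include_phantom = TRUE),
    preprocess = list(use_ct = TRUE, inference_plane = "axial"),
    network = list(base_channels = 8),
    loss = list(alpha = 0.5, beta = 100, w_side = rep(1, 6), w_final = 1,
                ssim_window = 11),
    train = list(epochs = 6, batch_size = 4, lr = 2e-4),
    evaluate = list(ssim_window = 11, cnr_threshold = 4,
                    phantom_dose_mbq = 485))
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]))
      modify_list(base[[nm]], new[[nm]]) else new[[nm]]
  }
  base
}

#' Run the end-to-end demo workflow
#'
#' Simulates a paired fast/standard dataset (phantom + synthetic subjects),
#' trains the generator, enhances the held-out test volumes and writes the
#' full evaluation: PSNR/SSIM for fast and enhanced against the standard
#' scan, the per-sphere SUV table, difference maps, the loss history and the
#' fully resolved configuration. The held-out phantom half is the one
#' containing the sphere-centre plane. Deterministic given the seed.
#'
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param config nested configuration list; defaults from [demo_config()].
#' @param ... shallow overrides merged into the configuration (e.g.
#'   `seed = 3`, `train = list(epochs = 2)`).
#' @return (invisibly) list with `report` (metrics data.frame), `spheres`
#'   (SUV table), `history`, `model`, and the resolved `config`.
#' @export
run_demo <- function(out_dir = NULL, config = demo_config(), ...) {
  config <- modify_list(config, list(...))
  sim <- config$simulate
  seed <- config$seed
  fast_acq <- acquisition_spec(seconds_per_projection = sim$fast_dwell_s,
                               n_projections = sim$n_projections,
                               psf_fwhm_mm = sim$psf_fwhm_mm)
  std_acq <- acquisition_spec(seconds_per_projection = sim$std_dwell_s,
                              n_projections = sim$n_projections,
                              psf_fwhm_mm = sim$psf_fwhm_mm)
  ph_spec <- if (isTRUE(sim$include_phantom))
    phantom_spec(grid_shape = sim$grid_shape, voxel_size_mm = sim$voxel_size_mm)
  else NULL
  quads <- make_paired_dataset(fast_acq, std_acq, n_subjects = sim$n_subjects,
                               seed = seed, phantom = ph_spec,
                               grid_shape = sim$grid_shape,
                               voxel_size_mm = sim$voxel_size_mm,
                               n_lesions = sim$n_lesions)
  n_slices <- sim$grid_shape[1]
  # train/test split: last subject is held out entirely; the phantom is split
  # by slice range with the sphere-centre half held out
  use_ct <- isTRUE(config$preprocess$use_ct)
  train_samples <- list()
  for (q in seq_along(quads)) {
    s <- quads[[q]]
    smp <- make_samples(s$fast, s$ct, s$standard, s$mask)
    if (!is.null(ph_spec) && q == 1) {
      train_samples <- c(train_samples, smp[(n_slices %/% 2 + 1):n_slices])
    } else if (q < length(quads)) {
      train_samples <- c(train_samples, smp)
    }
  }
  test_subject <- quads[[length(quads)]]
  lw <- do.call(loss_weights, config$loss)
  model <- build_u2net(u2net_config(in_channels = if (use_ct) 2 else 1,
                                    base_channels = config$network$base_channels),
                       seed = seed)
  cfg <- desk_train_config(epochs = config$train$epochs,
                           batch_size = config$train$batch_size,
                           lr = config$train$lr, seed = seed, use_ct = use_ct)
  fit <- train(model, train_samples, lw, cfg)
  enhanced <- enhance_volume(fit$model, test_subject$fast,
                             test_subject$ct, use_ct = use_ct)
  win <- config$evaluate$ssim_window
  # image-quality comparisons are made on the count-rate scale (counts per
  # second of total acquisition) so that dwell time does not confound them
  fast_time <- sim$fast_dwell_s * sim$n_projections
  std_time <- sim$std_dwell_s * sim$n_projections
  as_rate <- function(v, t) volume(v$data / t, v$voxel_size_mm, "activity")
  std_rate <- as_rate(test_subject$standard, std_time)
  report <- rbind(
    cbind(image = "fast",
          metrics_report(as_rate(test_subject$fast, fast_time), std_rate,
                         window = win)),
    cbind(image = "enhanced",
          metrics_report(as_rate(enhanced, fast_time), std_rate, window = win)))
  spheres <- NULL
  if (!is.null(ph_spec)) {
    ph <- quads[[1]]
    ph_enh <- enhance_volume(fit$model, ph$fast, ph$ct, use_ct = use_ct)
    dose <- config$evaluate$phantom_dose_mbq
    wt <- ph_spec$cylinder_volume_ml # 1 g/ml water-equivalent
    tabs <- lapply(list(fast = as_rate(ph$fast, fast_time),
                        enhanced = as_rate(ph_enh, fast_time),
                        standard = as_rate(ph$standard, std_time)),
                   function(v) sphere_stats(to_suv(v, wt, dose), ph_spec,
                                            config$evaluate$cnr_threshold))
    spheres <- do.call(rbind, Map(cbind, image = names(tabs), tabs))
    rownames(spheres) <- NULL
  }
  out <- list(report = report, spheres = spheres, history = fit$history,
              model = fit$model, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(test_subject$fast, file.path(out_dir, "test_fast.nii.gz"))
    write_volume(test_subject$standard, file.path(out_dir, "test_standard.nii.gz"))
    write_volume(enhanced, file.path(out_dir, "test_enhanced.nii.gz"))
    write_volume(difference_map(as_rate(enhanced, fast_time), std_rate),
                 file.path(out_dir, "test_difference.nii.gz"))
    utils::write.csv(fit$history, file.path(out_dir, "loss_history.csv"),
                     row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(spheres))
      utils::write.csv(spheres, file.path(out_dir, "sphere_suv.csv"),
                       row.names = FALSE)
    save_checkpoint(fit$model, file.path(out_dir, "model.rds"))
    yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
    jsonlite::write_json(list(metrics = report, spheres = spheres),
                         file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
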