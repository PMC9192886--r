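as_data3d <- function(x) {
  if (is_volume(x)) x <- x$data
  d <- dim(x)
  if (is.null(d)) stop("expected a volume, array or matrix")
  if (length(d) == 2L) dim(x) <- c(1L, d)
  x
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(MAX_gt^2 / MSE)` with `MAX_gt` the maximum value of the
#' ground-truth image and MSE the mean squared error over all voxels.
#' Identical images give `Inf` (with a note); an all-zero ground truth is a
#' domain error.
#'
#' @param pred,gt volumes, arrays or matrices of equal shape.
#' @return PSNR in dB.
#' @export
psnr <- function(pred, gt) {
  p <- as_data3d(pred); g <- as_data3d(gt)
  if (!identical(dim(p), dim(g))) stop("pred and gt shapes differ")
  if (all(g == 0)) stop("ground truth is all zero; PSNR undefined")
  mse <- mean((p - g)^2)
  if (mse == 0) {
    message("psnr: images are identical; returning Inf")
    return(Inf)
  }
  10 * log10(max(g)^2 / mse)
}

#' Structural similarity index
#'
#' Mean of the local windowed SSIM map (valid window positions, box window),
#' using the same map implementation as the SSIM loss; for 3-D inputs the map
#' is computed per axial slice and averaged over all positions, with the
#' stability constants derived once from the ground truth's dynamic range.
#'
#' @param pred,gt volumes, arrays or matrices of equal shape.
#' @param window odd window side (default 11).
#' @param k1,k2 stabilizer constants.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(pred, gt, window = 11, k1 = 0.01, k2 = 0.03) {
  p <- as_data3d(pred); g <- as_data3d(gt)
  if (!identical(dim(p), dim(g))) stop("pred and gt shapes differ")
  d <- dim(p)
  if (window > d[2] || window > d[3])
    stop("ssim window (", window, ") larger than image side")
  if (window %% 2 == 0) stop("ssim window must be odd")
  w <- loss_weights(ssim_window = window, ssim_k1 = k1, ssim_k2 = k2)
  cc <- ssim_constants(g, w)
  tot <- 0; n <- 0
  chunk <- max(1L, min(d[1], floor(4e6 / (d[2] * d[3]))))
  for (s0 in seq(1L, d[1], by = chunk)) {
    sl <- s0:min(d[1], s0 + chunk - 1L)
    ps <- aperm(array(p[sl, , ], c(length(sl), d[2], d[3])), c(2, 3, 1))
    gs <- aperm(array(g[sl, , ], c(length(sl), d[2], d[3])), c(2, 3, 1))
    dim(ps) <- c(d[2], d[3], 1L, length(sl))
    dim(gs) <- c(d[2], d[3], 1L, length(sl))
    tape <- new_tape()
    map <- ag_ssim_map(tape, ag_leaf(tape, ps), gs, window, cc["c1"], cc["c2"])
    tot <- tot + sum(map$value); n <- n + length(map$value)
  }
  tot / n
}

#' Whole-volume image-quality report
#'
#' @param pred,gt volumes on the same grid.
#' @param window SSIM window.
#' @param per_slice also compute per-axial-slice PSNR/SSIM rows.
#' @return data.frame with columns `scope`, `psnr_db`, `ssim`.
#' @export
metrics_report <- function(pred, gt, window = 11, per_slice = FALSE) {
  p <- as_data3d(pred); g <- as_data3d(gt)
  out <- data.frame(scope = "volume",
                    psnr_db = psnr(p, g),
                    ssim = ssim(p, g, window = window),
                    stringsAsFactors = FALSE)
  if (per_slice) {
    rows <- lapply(seq_len(dim(p)[1]), function(s) {
      gs <- g[s, , ]
      data.frame(scope = paste0("slice_", s),
                 psnr_db = if (all(gs == 0)) NA_real_
                           else suppressMessages(psnr(p[s, , ], gs)),
                 ssim = ssim(p[s, , ], gs, window = window),
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  out
}

#' Convert counts (or calibrated activity) to standardized uptake values
#'
#' `SUV = voxel value x weight in grams / total dose in MBq`, applied
#' voxelwise. For the phantom, the weight is the fill volume in ml times
#' 1 g/ml.
#'
#' @param vol input volume.
#' @param weight_g subject or phantom weight in grams.
#' @param dose_mbq injected (instilled) dose in MBq.
#' @return a `suv` volume.
#' @export
to_suv <- function(vol, weight_g, dose_mbq) {
  stopifnot_volume(vol)
  if (weight_g <= 0 || dose_mbq <= 0) stop("weight and dose must be positive")
  volume(vol$data * weight_g / dose_mbq, vol$voxel_size_mm, "suv")
}

# Background region of the phantom: inside the cylinder, within +-25 mm of
# the sphere plane, at least 15 mm clear of every sphere surface and 10 mm
# clear of the wall.
phantom_background_voxels <- function(spec) {
  g <- phantom_geometry(spec)
  v <- spec$voxel_size_mm
  dims <- spec$grid_shape
  zc <- (seq_len(dims[1]) - 0.5) * v
  yc <- (seq_len(dims[2]) - 0.5) * v
  xc <- (seq_len(dims[3]) - 0.5) * v
  zi <- which(abs(zc - g$sphere_centers[1, "z"]) <= 25)
  r2 <- outer((yc - g$center_y)^2, (xc - g$center_x)^2, `+`)
  inplane <- which(r2 <= (g$r_cyl - 10)^2, arr.ind = TRUE)
  idx <- as.vector(outer(zi, dims[1] * (inplane[, 1] - 1) +
                           dims[1] * dims[2] * (inplane[, 2] - 1), `+`))
  ai <- arrayInd(idx, dims)
  pos <- cbind(zc[ai[, 1]], yc[ai[, 2]], xc[ai[, 3]])
  keep <- rep(TRUE, nrow(pos))
  for (s in seq_along(g$sphere_diameters)) {
    ctr <- g$sphere_centers[s, ]
    d <- sqrt((pos[, 1] - ctr["z"])^2 + (pos[, 2] - ctr["y"])^2 +
                (pos[, 3] - ctr["x"])^2)
    keep <- keep & d > (g$sphere_diameters[s] / 2 + 15)
  }
  idx[keep]
}

#' Per-sphere SUV statistics
#'
#' For each sphere of the phantom (numbered 1..6 from the largest diameter
#' down, matching the partial-volume ordering of the reported tables), takes
#' the voxels inside the known analytic sphere geometry as the ROI and
#' reports SUVmax, SUVmean, the contrast-to-noise ratio against an annular
#' background region, and a Rose-criterion detectability flag.
#'
#' @param suv a volume on the phantom grid (any modality).
#' @param spec the [phantom_spec()] describing the geometry.
#' @param cnr_threshold Rose detectability threshold (default 4).
#' @return data.frame with columns `sphere_id`, `diameter_mm`, `suv_max`,
#'   `suv_mean`, `cnr`, `detectable`.
#' @export
sphere_stats <- function(suv, spec, cnr_threshold = 4) {
  stopifnot_volume(suv)
  if (!identical(dim(suv$data), as.integer(spec$grid_shape)))
    stop("volume is not on the phantom grid")
  rois <- sphere_voxels(spec)
  bg <- phantom_background_voxels(spec)
  mu_bg <- mean(suv$data[bg])
  sd_bg <- stats::sd(suv$data[bg])
  dia <- sort(spec$sphere_diameters_mm, decreasing = TRUE)
  rows <- lapply(seq_along(rois), function(s) {
    vals <- suv$data[rois[[s]]]
    contrast <- mean(vals) - mu_bg
    if (is.na(sd_bg) || sd_bg == 0) {
      cnr <- Inf * sign(contrast)
      det <- contrast > 1e-9 * max(1, abs(mu_bg))
    } else {
      cnr <- contrast / sd_bg
      det <- cnr > cnr_threshold
    }
    data.frame(sphere_id = s, diameter_mm = dia[s], suv_max = max(vals),
               suv_mean = mean(vals), cnr = cnr, detectable = det)
  })
  out <- do.call(rbind, rows)
  attr(out, "background_mean") <- mu_bg
  attr(out, "background_sd") <- sd_bg
  out
}

#' Count detectable spheres
#'
#' A sphere counts as detectable when its contrast-to-noise ratio
#' `(mean_ROI - mean_bg) / sd_bg` against an annular background region
#' exceeds the Rose-criterion threshold (default 4). With a degenerate
#' (zero-variance) background the absolute contrast is used instead.
#'
#' @inheritParams sphere_stats
#' @param vol volume on the phantom grid.
#' @return integer number of detectable spheres.
#' @export
count_detectable_spheres <- function(vol, spec, cnr_threshold = 4) {
  sum(sphere_stats(vol, spec, cnr_threshold)$detectable)
}
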