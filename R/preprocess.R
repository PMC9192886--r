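#' Normalize a volume by its own mean
#'
#' Every network input and target is divided by its own volume-wide average
#' (all voxels, zeros included) so that training operates on mean-1
#' intensities regardless of count level. The divisor is returned so the
#' operation is invertible with [denormalize()].
#'
#' @param vol a volume.
#' @return list with `volume` (mean 1) and `divisor` (the input mean).
#' @export
normalize_by_mean <- function(vol) {
  stopifnot_volume(vol)
  m <- mean(vol$data)
  if (m <= 0) stop("cannot normalize a volume with non-positive mean")
  out <- vol
  out$data <- vol$data / m
  list(volume = out, divisor = m)
}

#' Invert mean normalization
#'
#' @param vol a normalized volume.
#' @param divisor the mean recorded by [normalize_by_mean()].
#' @return volume multiplied voxelwise by `divisor`.
#' @export
denormalize <- function(vol, divisor) {
  stopifnot_volume(vol)
  if (divisor <= 0) stop("divisor must be > 0")
  out <- vol
  out$data <- vol$data * divisor
  out
}

#' Slice aligned volumes into paired training samples
#'
#' Normalizes the fast SPECT, CT and standard SPECT each by their own
#' volume-wide mean (divisors recorded once per volume, not per slice) and
#' cuts the four volumes into axial slices. One `paired_sample` per slice, in
#' slice order.
#'
#' @param fast fast-scan SPECT volume.
#' @param ct CT volume already resampled to the SPECT grid.
#' @param standard standard-scan SPECT volume.
#' @param mask lesion-mask volume.
#' @param plane slicing plane; only `"axial"` is supported.
#' @return list of `paired_sample` objects with fields `fast_slice`,
#'   `ct_slice`, `target_slice`, `mask_slice`, `norm_fast`, `norm_ct`,
#'   `norm_target`.
#' @export
make_samples <- function(fast, ct, standard, mask, plane = "axial") {
  if (!identical(plane, "axial")) stop("only the axial inference plane is supported")
  stopifnot_volume(fast); stopifnot_volume(ct)
  stopifnot_volume(standard); stopifnot_volume(mask, "mask")
  for (v in list(ct, standard, mask))
    if (!same_grid(fast, v)) stop("all four volumes must share the SPECT grid")
  nf <- normalize_by_mean(fast)
  nc <- normalize_by_mean(ct_shift(ct))
  nt <- normalize_by_mean(standard)
  n_slices <- dim(fast$data)[1]
  lapply(seq_len(n_slices), function(s) {
    structure(list(fast_slice = nf$volume$data[s, , ],
                   ct_slice = nc$volume$data[s, , ],
                   target_slice = nt$volume$data[s, , ],
                   mask_slice = mask$data[s, , ],
                   norm_fast = nf$divisor, norm_ct = nc$divisor,
                   norm_target = nt$divisor),
              class = "paired_sample")
  })
}

# CT volumes are in HU-like units that include large negative air values; the
# mean normalization needs a positive-valued field, so CT is shifted to
# air = 0 before dividing by its mean.
ct_shift <- function(ct) {
  if (ct$modality != "ct") return(ct)
  out <- ct
  out$data <- ct$data - min(ct$data)
  out$modality <- "activity"
  out
}

#' Stack a paired sample into a network input
#'
#' Channel 0 (R index 1) is always the fast SPECT slice; channel 1 (R index
#' 2) is the CT slice when `use_ct` is `TRUE` (the ablation arm drops it).
#'
#' @param sample a `paired_sample`.
#' @param use_ct include the CT channel?
#' @return `(H, W, C)` array with C = 2 (`use_ct`) or 1.
#' @export
concat_channels <- function(sample, use_ct = TRUE) {
  stopifnot(inherits(sample, "paired_sample"))
  if (use_ct) {
    if (!identical(dim(sample$fast_slice), dim(sample$ct_slice)))
      stop("fast and CT slices have different shapes")
    array(c(sample$fast_slice, sample$ct_slice), c(dim(sample$fast_slice), 2L))
  } else {
    array(sample$fast_slice, c(dim(sample$fast_slice), 1L))
  }
}

# Assemble a batch (H, W, C, N) + targets + masks from a list of samples.
assemble_batch <- function(samples, use_ct = TRUE) {
  xs <- lapply(samples, concat_channels, use_ct = use_ct)
  d <- dim(xs[[1]])
  x <- array(unlist(xs, use.names = FALSE), c(d, length(xs)))
  t <- array(unlist(lapply(samples, `[[`, "target_slice"), use.names = FALSE),
             c(d[1], d[2], 1L, length(samples)))
  m <- array(unlist(lapply(samples, `[[`, "mask_slice"), use.names = FALSE),
             c(d[1], d[2], 1L, length(samples)))
  list(x = x, target = t, mask = m)
}
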