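#' 3-D image volume
#'
#' The basic container used throughout spectboost: a 3-D scalar field indexed
#' `(slice, row, col)` with per-axis voxel spacing in millimetres and a
#' modality tag. SPECT count volumes are integer-valued; mask volumes contain
#' only 0/1.
#'
#' @param data numeric 3-D array indexed `(slice, row, col)`.
#' @param voxel_size_mm numeric length-3 (or length-1, recycled) voxel spacing
#'   in mm along `(slice, row, col)`.
#' @param modality one of `"spect_counts"`, `"ct"`, `"mask"`, `"activity"`,
#'   `"suv"`.
#' @param origin_mm optional length-3 world position (mm) of the centre of
#'   voxel `(1, 1, 1)`. Defaults to `c(0, 0, 0)`.
#' @return an object of class `spect_volume`.
#' @export
volume <- function(data, voxel_size_mm, modality = c("activity", "spect_counts",
                                                     "ct", "mask", "suv"),
                   origin_mm = c(0, 0, 0)) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array indexed (slice, row, col)")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel spacing must be strictly positive")
  if (modality == "mask" && !all(data %in% c(0, 1)))
    stop("mask volumes must contain only 0 and 1")
  if (modality %in% c("spect_counts", "activity") && any(data < 0))
    stop("negative values are not allowed in ", modality, " volumes")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 modality = modality, origin_mm = as.numeric(origin_mm)),
            class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spect_volume> %s  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.spect_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "spect_volume")

stopifnot_volume <- function(x, modality = NULL, arg = deparse(substitute(x))) {
  if (!is_volume(x)) stop("`", arg, "` must be a spect_volume")
  if (!is.null(modality) && !x$modality %in% modality)
    stop("`", arg, "` must have modality ", paste(modality, collapse = "/"),
         ", got ", x$modality)
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) < tol)
}

#' Signed difference map between a reference and a comparison volume
#'
#' Computes `gt - pred` voxelwise (the convention used for the difference
#' panels of the evaluation report: reference minus comparison). Suggested
#' symmetric display bounds are attached as attribute `display_bounds`.
#'
#' @param pred comparison volume.
#' @param gt reference (ground-truth) volume.
#' @return a `spect_volume` of the same grid holding `gt - pred`.
#' @export
difference_map <- function(pred, gt) {
  stopifnot_volume(pred); stopifnot_volume(gt)
  if (!same_grid(pred, gt)) stop("volumes are not on the same grid")
  d <- gt$data - pred$data
  out <- structure(list(data = d, voxel_size_mm = gt$voxel_size_mm,
                        modality = "activity", origin_mm = gt$origin_mm),
                   class = "spect_volume")
  b <- max(abs(range(d)))
  attr(out, "display_bounds") <- c(-b, b)
  out
}
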