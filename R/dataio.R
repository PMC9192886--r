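#' Target grid specification
#'
#' @param shape integer length-3 `(slices, rows, cols)`.
#' @param voxel_size_mm numeric length-3 (or scalar) spacing in mm.
#' @param origin_mm world position (mm) of the centre of the first voxel;
#'   `NULL` means "align field-of-view centres with the source volume" when
#'   resampling.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(shape, voxel_size_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 entries >= 1")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("spacing must be > 0")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm), class = "grid_spec")
}

#' Read a volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file; spacing is taken from the header pixdim.
#' Data are stored internally as `(slice, row, col)`, mapping the NIfTI array
#' `(x, y, z)` so that the third NIfTI axis is the slice axis. Orientation is
#' assumed identity (simulator-native data); the affine is used only for
#' spacing. Negative values in SPECT count volumes are clamped to zero with a
#' warning.
#'
#' @param path file path.
#' @param modality modality tag for the resulting volume.
#' @return a `spect_volume`.
#' @export
read_volume <- function(path, modality = "activity") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume in ", path)
  pd <- RNifti::pixdim(img)[1:3]
  # file stores (x=col, y=row, z=slice); internal order is (slice, row, col)
  dat <- aperm(arr, c(3, 2, 1))
  spacing <- c(pd[3], pd[2], pd[1])
  if (modality == "spect_counts" && any(dat < 0)) {
    warning("negative SPECT counts in ", path, " clamped to zero")
    dat[dat < 0] <- 0
  }
  if (modality == "mask") dat <- (dat > 0.5) + 0
  volume(dat, spacing, modality)
}

#' Write a volume as NIfTI
#'
#' Masks are written as unsigned 8-bit; everything else as float32 (or int16
#' for counts below 32767). Spacing goes into the header pixdim.
#'
#' @param vol a volume.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  arr <- aperm(vol$data, c(3, 2, 1)) # back to (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol$voxel_size_mm[3], vol$voxel_size_mm[2],
                           vol$voxel_size_mm[1])
  dt <- if (vol$modality == "mask") "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

# World origin (centre of voxel 1,1,1) that aligns a volume's FOV centre with
# a target grid's FOV centre.
centered_origin <- function(shape, spacing, fov_center) {
  fov_center - (shape - 1) * spacing / 2
}

#' Resample a volume onto a target grid
#'
#' World-coordinate resampling (voxel value at voxel centre, clamp-to-edge
#' boundary), not an array stretch: the physical field of view is preserved.
#' Unless both origins are given, the source and target fields of view are
#' aligned on their centres — the natural mapping for a CT and a SPECT of the
#' same subject acquired on one scanner. Trilinear interpolation for images;
#' nearest neighbour is mandatory for masks.
#'
#' @param vol source volume.
#' @param target a [grid_spec()].
#' @param method `"trilinear"` or `"nearest"`.
#' @return volume on the target grid.
#' @export
resample_to_grid <- function(vol, target, method = c("trilinear", "nearest")) {
  stopifnot_volume(vol)
  stopifnot(inherits(target, "grid_spec"))
  method <- match.arg(method)
  if (vol$modality == "mask" && method != "nearest")
    stop("masks must be resampled with method = \"nearest\"")
  src_shape <- dim(vol$data)
  if (is.null(target$origin_mm)) {
    fov_center <- c(0, 0, 0)
    src_origin <- centered_origin(src_shape, vol$voxel_size_mm, fov_center)
    dst_origin <- centered_origin(target$shape, target$voxel_size_mm, fov_center)
  } else {
    src_origin <- vol$origin_mm
    dst_origin <- target$origin_mm
  }
  dat <- cpp_resample3d(vol$data, vol$voxel_size_mm, src_origin,
                        target$shape, target$voxel_size_mm, dst_origin,
                        method == "nearest")
  if (vol$modality == "mask") dat <- (dat > 0.5) + 0
  volume(dat, target$voxel_size_mm, vol$modality,
         origin_mm = dst_origin)
}
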