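#' NEMA IEC body-phantom specification
#'
#' Geometry of the standard image-quality phantom: a water-filled plexiglass
#' cylinder with six fillable spheres of graded diameter whose centres lie on
#' a ring around the cylinder axis, in a single axial plane. Defaults follow
#' the NEMA IEC body-phantom set: 9700 ml fill volume, spheres of 10, 13, 17,
#' 22, 28 and 37 mm diameter on a 50 mm ring, 70 mm below the top face, filled
#' at a 12:1 sphere:background activity-concentration ratio. The interior
#' cylinder length is fixed at 180 mm and the radius solved from the fill
#' volume.
#'
#' @param grid_shape integer length-3 `(slices, rows, cols)` voxel counts.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param cylinder_volume_ml interior (fill) volume of the cylinder.
#' @param sphere_diameters_mm strictly increasing sphere diameters in mm.
#' @param ring_radius_mm radius of the ring of sphere centres.
#' @param sphere_plane_depth_mm axial distance of the sphere-centre plane from
#'   the cylinder top face.
#' @param activity_ratio sphere:background activity-concentration ratio.
#' @param cylinder_length_mm interior cylinder length (mm).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(200L, 256L, 256L),
                         voxel_size_mm = 1.95,
                         cylinder_volume_ml = 9700,
                         sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                         ring_radius_mm = 50,
                         sphere_plane_depth_mm = 70,
                         activity_ratio = 12,
                         cylinder_length_mm = 180) {
  if (any(sphere_diameters_mm <= 0) || is.unsorted(sphere_diameters_mm, strictly = TRUE))
    stop("sphere diameters must be positive and strictly increasing")
  if (ring_radius_mm < max(sphere_diameters_mm) / 2)
    stop("ring radius must be at least the largest sphere radius")
  if (voxel_size_mm <= 0 || cylinder_volume_ml <= 0 || activity_ratio <= 0)
    stop("voxel size, cylinder volume and activity ratio must be positive")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 cylinder_volume_ml = cylinder_volume_ml,
                 sphere_diameters_mm = sphere_diameters_mm,
                 ring_radius_mm = ring_radius_mm,
                 sphere_plane_depth_mm = sphere_plane_depth_mm,
                 activity_ratio = activity_ratio,
                 cylinder_length_mm = cylinder_length_mm),
            class = "phantom_spec")
}

# Derived cylinder geometry (radius from fill volume, world coordinates of the
# axis and top face). World frame: voxel (i,j,k) centre sits at
# ((i-0.5)dz, (j-0.5)dy, (k-0.5)dx); slice 1 is the top face side.
phantom_geometry <- function(spec) {
  v <- spec$voxel_size_mm
  ext <- spec$grid_shape * v
  r_cyl <- sqrt(spec$cylinder_volume_ml * 1000 / (pi * spec$cylinder_length_mm))
  z_top <- (ext[1] - spec$cylinder_length_mm) / 2
  if (spec$cylinder_length_mm > ext[1])
    stop("grid too small along the slice axis: cylinder length ",
         spec$cylinder_length_mm, " mm exceeds grid extent ", ext[1], " mm")
  if (2 * r_cyl > ext[2])
    stop("grid too small along the row axis: cylinder diameter ",
         round(2 * r_cyl, 1), " mm exceeds grid extent ", ext[2], " mm")
  if (2 * r_cyl > ext[3])
    stop("grid too small along the col axis: cylinder diameter ",
         round(2 * r_cyl, 1), " mm exceeds grid extent ", ext[3], " mm")
  d <- sort(spec$sphere_diameters_mm, decreasing = TRUE)
  ang <- (seq_along(d) - 1) * 2 * pi / length(d) # sphere 1 (largest) at angle 0
  centers <- cbind(z = z_top + spec$sphere_plane_depth_mm,
                   y = ext[2] / 2 + spec$ring_radius_mm * cos(ang),
                   x = ext[3] / 2 + spec$ring_radius_mm * sin(ang))
  list(r_cyl = r_cyl, z_top = z_top, z_bottom = z_top + spec$cylinder_length_mm,
       center_y = ext[2] / 2, center_x = ext[3] / 2,
       sphere_diameters = d, sphere_centers = centers)
}

#' Voxelize the NEMA IEC phantom
#'
#' Builds the activity map (background 1, spheres at the configured ratio,
#' zero outside the cylinder), the lesion mask (sphere voxels), and a
#' pseudo-CT with three attenuation classes encoded as constant values:
#' air (-1000), water-equivalent fill (0) and plexiglass shell (+120).
#' A voxel belongs to a region when its centre does; every sphere is
#' guaranteed at least its centre voxel so no sphere vanishes on coarse grids.
#'
#' @param spec a [phantom_spec()].
#' @return list with `activity`, `lesion_mask` and `pseudo_ct` volumes.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  v <- spec$voxel_size_mm
  dims <- spec$grid_shape
  zc <- (seq_len(dims[1]) - 0.5) * v
  yc <- (seq_len(dims[2]) - 0.5) * v
  xc <- (seq_len(dims[3]) - 0.5) * v
  # in-plane masks (rows x cols)
  r2 <- outer((yc - g$center_y)^2, (xc - g$center_x)^2, `+`)
  inside2d <- r2 <= g$r_cyl^2
  shell_t <- 3 # mm wall thickness for the pseudo-CT shell
  shell2d <- r2 <= (g$r_cyl + shell_t)^2 & !inside2d
  act <- array(0, dims)
  ct <- array(-1000, dims)
  in_z <- zc >= g$z_top & zc <= g$z_bottom
  cap_z <- (zc >= g$z_top - shell_t & zc <= g$z_bottom + shell_t) & !in_z
  for (i in which(in_z)) {
    sl <- act[i, , ]; sl[inside2d] <- 1; act[i, , ] <- sl
    slc <- ct[i, , ]; slc[inside2d] <- 0; slc[shell2d] <- 120; ct[i, , ] <- slc
  }
  for (i in which(cap_z)) {
    slc <- ct[i, , ]; slc[inside2d | shell2d] <- 120; ct[i, , ] <- slc
  }
  mask <- array(0, dims)
  for (idx in sphere_voxels(spec)) mask[idx] <- 1
  act[mask == 1] <- spec$activity_ratio
  list(activity = volume(act, v, "activity"),
       lesion_mask = volume(mask, v, "mask"),
       pseudo_ct = volume(ct, v, "ct"))
}

# Linear voxel indices of each sphere's interior (a voxel belongs when its
# centre does; the centre voxel is always claimed so no sphere vanishes on
# coarse grids). Returned largest sphere first — the ROI definition shared by
# the phantom builder and the SUV report.
sphere_voxels <- function(spec) {
  g <- phantom_geometry(spec)
  v <- spec$voxel_size_mm
  dims <- spec$grid_shape
  zc <- (seq_len(dims[1]) - 0.5) * v
  yc <- (seq_len(dims[2]) - 0.5) * v
  xc <- (seq_len(dims[3]) - 0.5) * v
  lapply(seq_along(g$sphere_diameters), function(s) {
    rad <- g$sphere_diameters[s] / 2
    ctr <- g$sphere_centers[s, ]
    ii <- which(abs(zc - ctr["z"]) <= rad + v)
    jj <- which(abs(yc - ctr["y"]) <= rad + v)
    kk <- which(abs(xc - ctr["x"]) <= rad + v)
    if (!length(ii) || !length(jj) || !length(kk))
      stop("sphere ", s, " falls outside the grid")
    d2 <- outer(outer((zc[ii] - ctr["z"])^2, (yc[jj] - ctr["y"])^2, `+`),
                (xc[kk] - ctr["x"])^2, `+`)
    sel <- which(d2 <= rad^2, arr.ind = TRUE)
    lin <- ii[sel[, 1]] + dims[1] * (jj[sel[, 2]] - 1) +
      dims[1] * dims[2] * (kk[sel[, 3]] - 1)
    ci <- pmin(pmax(round(ctr / v + 0.5), 1), dims)
    unique(c(lin, ci[1] + dims[1] * (ci[2] - 1) + dims[1] * dims[2] * (ci[3] - 1)))
  })
}

#' Acquisition (scan-physics) specification
#'
#' Parameters of the image-domain forward model used in place of a scanner:
#' the activity map is blurred with an isotropic Gaussian point-spread
#' function and converted to expected counts per voxel as
#' `activity x sensitivity x seconds_per_projection x n_projections`, plus a
#' flat background rate; counts are then drawn independently Poisson.
#'
#' The default sensitivity is chosen so that unit background activity at the
#' standard protocol (20 s/projection, 60 projections) yields about 50
#' expected counts per voxel.
#'
#' @param seconds_per_projection dwell time per projection (s); 20 for the
#'   standard scan, 3 for the fast scan.
#' @param n_projections number of projections per scan.
#' @param psf_fwhm_mm full width at half maximum of the Gaussian system
#'   resolution blur (mm); 0 disables blurring.
#' @param sensitivity_counts_per_kBq_s expected counts per voxel per unit
#'   activity concentration per second of total acquisition.
#' @param background_counts_rate flat scatter/background floor, counts per
#'   voxel per second of total acquisition.
#' @param rng_seed seed for the Poisson draw; `NULL` leaves the RNG state
#'   alone.
#' @return an `acquisition_spec` list.
#' @export
acquisition_spec <- function(seconds_per_projection = 20,
                             n_projections = 60,
                             psf_fwhm_mm = 8,
                             sensitivity_counts_per_kBq_s = 1 / 24,
                             background_counts_rate = 0,
                             rng_seed = NULL) {
  if (seconds_per_projection <= 0) stop("seconds_per_projection must be > 0")
  if (n_projections < 1) stop("n_projections must be >= 1")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  if (sensitivity_counts_per_kBq_s <= 0) stop("sensitivity must be > 0")
  if (background_counts_rate < 0) stop("background rate must be >= 0")
  structure(list(seconds_per_projection = seconds_per_projection,
                 n_projections = n_projections,
                 psf_fwhm_mm = psf_fwhm_mm,
                 sensitivity_counts_per_kBq_s = sensitivity_counts_per_kBq_s,
                 background_counts_rate = background_counts_rate,
                 rng_seed = rng_seed),
            class = "acquisition_spec")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Gaussian point-spread blur of a volume
#'
#' Separable Gaussian blur with a normalized kernel (zero boundary), FWHM
#' given in mm and converted per-axis to voxels.
#'
#' @param vol a volume.
#' @param fwhm_mm isotropic FWHM in mm.
#' @return blurred volume of the same grid and modality.
#' @export
psf_blur <- function(vol, fwhm_mm) {
  stopifnot_volume(vol)
  if (fwhm_mm <= 0) return(vol)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vol$voxel_size_mm
  out <- vol
  out$data <- cpp_gauss_blur3d(vol$data, sigma_vox)
  out
}

# Expected counts per voxel under an acquisition spec (after PSF blur).
expected_counts <- function(activity, acq) {
  t_total <- acq$seconds_per_projection * acq$n_projections
  blurred <- psf_blur(activity, acq$psf_fwhm_mm)
  blurred$data * acq$sensitivity_counts_per_kBq_s * t_total +
    acq$background_counts_rate * t_total
}

#' Simulate a SPECT acquisition from an activity map
#'
#' Image-domain surrogate for the scanner + reconstruction chain: the activity
#' volume is blurred with the system PSF, scaled to expected counts
#' (`activity x sensitivity x dwell x projections` plus the background term),
#' and each voxel is drawn independently from a Poisson distribution. The
#' scan-time dependence is exactly linear, so a 3 s and a 20 s acquisition of
#' the same activity differ in expectation by the factor 3/20.
#'
#' @param activity an activity volume.
#' @param acq an [acquisition_spec()].
#' @return a `spect_counts` volume (integer-valued).
#' @export
simulate_acquisition <- function(activity, acq) {
  stopifnot_volume(activity, "activity")
  stopifnot(inherits(acq, "acquisition_spec"))
  if (any(activity$data < 0)) stop("activity values must be non-negative")
  lam <- expected_counts(activity, acq)
  lam[lam < 0] <- 0 # tiny negative ringing from the blur boundary
  counts <- with_seed(acq$rng_seed, stats::rpois(length(lam), lam))
  volume(array(as.numeric(counts), dim(activity$data)),
         activity$voxel_size_mm, "spect_counts")
}

#' Generate a synthetic subject
#'
#' A stand-in for a clinical bone-scan subject: an ellipsoidal soft-tissue
#' body with unit tracer uptake, skeletal structures (an axial spine rod, a
#' pelvic plate and oblique rib-like rods) at elevated uptake, and `n_lesions`
#' hot focal ellipsoids. The pseudo-CT shares the geometry at CT-like
#' contrast (air -1000, soft tissue 40, bone 700). Deterministic given the
#' seed.
#'
#' @param rng_seed integer seed.
#' @param n_lesions number of focal lesions (>= 0).
#' @param grid_shape `(slices, rows, cols)` voxel counts.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param bone_uptake activity in skeletal structures relative to body (1 =
#'   invisible on SPECT, useful for CT-ablation experiments).
#' @param lesion_uptake activity in lesions relative to body.
#' @return list with `activity`, `lesion_mask`, `pseudo_ct` volumes.
#' @export
generate_synthetic_subject <- function(rng_seed, n_lesions = 3,
                                       grid_shape = c(200L, 256L, 256L),
                                       voxel_size_mm = 1.95,
                                       bone_uptake = 3.5,
                                       lesion_uptake = 10) {
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  dims <- as.integer(grid_shape)
  v <- voxel_size_mm
  ext <- dims * v
  zc <- (seq_len(dims[1]) - 0.5) * v
  yc <- (seq_len(dims[2]) - 0.5) * v
  xc <- (seq_len(dims[3]) - 0.5) * v
  ctr <- ext / 2
  with_seed(rng_seed, {
    semi <- c(0.46, 0.34, 0.30) * ext * stats::runif(3, 0.95, 1.05)
    nz <- outer(outer(((zc - ctr[1]) / semi[1])^2, ((yc - ctr[2]) / semi[2])^2, `+`),
                ((xc - ctr[3]) / semi[3])^2, `+`)
    body <- nz <= 1
    act <- array(0, dims); act[body] <- 1
    ct <- array(-1000, dims); ct[body] <- 40
    bone <- array(FALSE, dims)
    # spine: rod along the slice axis, posterior offset
    sy <- ctr[2] + 0.45 * semi[2]
    r_spine <- max(0.06 * min(ext[2], ext[3]), 1.1 * v)
    rod2d <- outer((yc - sy)^2, (xc - ctr[3])^2, `+`) <= r_spine^2
    for (i in seq_len(dims[1])) if (any(body[i, , ])) {
      sl <- bone[i, , ]; sl[rod2d & body[i, , ]] <- TRUE; bone[i, , ] <- sl
    }
    # pelvic plate: flattened ellipsoid in the lower third
    pz <- ctr[1] + 0.55 * semi[1]
    plate <- outer(outer(((zc - pz) / (0.12 * ext[1]))^2,
                         ((yc - ctr[2]) / (0.55 * semi[2]))^2, `+`),
                   ((xc - ctr[3]) / (0.55 * semi[3]))^2, `+`) <= 1
    bone <- bone | (plate & nz <= 1)
    # oblique rib-like rods
    n_rods <- sample(2:4, 1)
    for (r in seq_len(n_rods)) {
      p0 <- ctr + stats::runif(3, -0.5, 0.5) * semi
      dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      len <- stats::runif(1, 0.3, 0.7) * min(ext)
      rr <- max(stats::runif(1, 0.02, 0.04) * min(ext), 1.1 * v)
      ts <- seq(-len / 2, len / 2, by = v / 2)
      for (t in ts) {
        p <- p0 + t * dirv
        ci <- round(p / v + 0.5)
        if (any(ci < 1) || any(ci > dims)) next
        rad <- ceiling(rr / v)
        ii <- max(1, ci[1] - rad):min(dims[1], ci[1] + rad)
        jj <- max(1, ci[2] - rad):min(dims[2], ci[2] + rad)
        kk <- max(1, ci[3] - rad):min(dims[3], ci[3] + rad)
        d2 <- outer(outer((zc[ii] - p[1])^2, (yc[jj] - p[2])^2, `+`),
                    (xc[kk] - p[3])^2, `+`)
        sub <- bone[ii, jj, kk, drop = FALSE]
        sub[d2 <= rr^2] <- TRUE
        bone[ii, jj, kk] <- sub
      }
    }
    bone <- bone & body
    act[bone] <- bone_uptake
    ct[bone] <- 700
    # focal lesions: non-overlapping hot ellipsoids inside the body
    mask <- array(0, dims)
    placed <- 0L; tries <- 0L
    centers <- matrix(0, 0, 3); radii <- numeric(0)
    while (placed < n_lesions) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_lesions))
        stop("could not place ", n_lesions,
             " non-overlapping lesions after bounded retries")
      p <- ctr + stats::runif(3, -0.75, 0.75) * semi
      if (sum(((p - ctr) / semi)^2) > 0.7) next
      sa <- stats::runif(3, 1.3, 2.6) * v
      ok <- TRUE
      if (placed > 0) {
        for (q in seq_len(placed)) {
          if (sqrt(sum((p - centers[q, ])^2)) < (max(sa) + radii[q] + 2 * v)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      rad <- ceiling(max(sa) / v) + 1
      ci <- round(p / v + 0.5)
      ii <- max(1, ci[1] - rad):min(dims[1], ci[1] + rad)
      jj <- max(1, ci[2] - rad):min(dims[2], ci[2] + rad)
      kk <- max(1, ci[3] - rad):min(dims[3], ci[3] + rad)
      d2 <- outer(outer(((zc[ii] - p[1]) / sa[1])^2, ((yc[jj] - p[2]) / sa[2])^2, `+`),
                  ((xc[kk] - p[3]) / sa[3])^2, `+`)
      sub <- mask[ii, jj, kk, drop = FALSE]
      sub[d2 <= 1] <- 1
      mask[ii, jj, kk] <- sub
      mask[min(max(ci[1], 1), dims[1]), min(max(ci[2], 1), dims[2]),
           min(max(ci[3], 1), dims[3])] <- 1
      placed <- placed + 1L
      centers <- rbind(centers, p); radii <- c(radii, max(sa))
    }
    act[mask == 1] <- lesion_uptake
    list(activity = volume(act, v, "activity"),
         lesion_mask = volume(mask, v, "mask"),
         pseudo_ct = volume(ct, v, "ct"))
  })
}

#' Count 6-connected components of a binary mask volume
#'
#' @param mask a mask volume or 0/1 3-D array.
#' @return number of connected components (face connectivity).
#' @export
count_components <- function(mask) {
  m <- if (is_volume(mask)) mask$data else mask
  dims <- dim(m)
  pos <- which(m > 0)
  if (!length(pos)) return(0L)
  id <- seq_along(pos)                  # union-find over positive voxels
  lookup <- integer(prod(dims)); lookup[pos] <- id
  find <- function(a) { while (id[a] != a) { id[a] <<- id[id[a]]; a <- id[a] }; a }
  ai <- arrayInd(pos, dims)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ai, 2, offs[o, ], `+`)
    ok <- nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    nbl <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) + dims[1] * dims[2] * (nb[ok, 3] - 1)
    src <- which(ok); tgt <- lookup[nbl]
    hit <- tgt > 0
    for (t in which(hit)) {
      ra <- find(src[t]); rb <- find(tgt[t])
      if (ra != rb) id[rb] <- ra
    }
  }
  length(unique(vapply(seq_along(pos), find, integer(1))))
}

#' Build a paired fast/standard training dataset
#'
#' Simulates, for the phantom and/or a set of synthetic subjects, one fast and
#' one standard acquisition of the same blurred activity (independent Poisson
#' realizations) plus the co-registered pseudo-CT and lesion mask, all on the
#' SPECT grid.
#'
#' @param fast_acq,std_acq [acquisition_spec()]s that differ only in
#'   `seconds_per_projection` (and seed).
#' @param n_subjects number of synthetic subjects to generate.
#' @param seed master seed; per-subject and per-scan seeds are derived from
#'   it.
#' @param phantom optional [phantom_spec()]; when given the phantom is
#'   included as the first entry.
#' @param grid_shape,voxel_size_mm grid for the synthetic subjects.
#' @param n_lesions lesions per synthetic subject.
#' @param ... passed to [generate_synthetic_subject()].
#' @return list of quadruplet lists with elements `fast`, `ct`, `standard`,
#'   `mask` (and `activity` for reference), one per subject.
#' @export
make_paired_dataset <- function(fast_acq, std_acq, n_subjects = 3, seed = 1,
                                phantom = NULL,
                                grid_shape = c(200L, 256L, 256L),
                                voxel_size_mm = 1.95, n_lesions = 3, ...) {
  same <- c("n_projections", "psf_fwhm_mm", "sensitivity_counts_per_kBq_s",
            "background_counts_rate")
  for (f in same)
    if (!isTRUE(all.equal(fast_acq[[f]], std_acq[[f]])))
      stop("fast and standard acquisition specs may differ only in dwell time; ",
           f, " differs")
  subjects <- list()
  if (!is.null(phantom)) subjects[[1]] <- build_phantom(phantom)
  for (s in seq_len(n_subjects))
    subjects[[length(subjects) + 1L]] <-
      generate_synthetic_subject(rng_seed = seed + 104729L * s,
                                 n_lesions = n_lesions,
                                 grid_shape = grid_shape,
                                 voxel_size_mm = voxel_size_mm, ...)
  out <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    fa <- fast_acq; fa$rng_seed <- seed + 7919L * s
    sa <- std_acq;  sa$rng_seed <- seed + 7919L * s + 1L
    fast <- simulate_acquisition(sub$activity, fa)
    std <- simulate_acquisition(sub$activity, sa)
    if (!same_grid(fast, sub$pseudo_ct))
      stop("CT and SPECT grids are misaligned for subject ", s)
    out[[s]] <- list(fast = fast, ct = sub$pseudo_ct, standard = std,
                     mask = sub$lesion_mask, activity = sub$activity)
  }
  out
}
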