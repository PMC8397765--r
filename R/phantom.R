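#' Parameterize the synthetic tendon phantom
#'
#' Full specification of the synthetic volumes used to exercise the
#' pipeline: tightly packed bright cylinders (collagen-scale fibers,
#' parallel to z, on a hexagonal lattice) in a darker non-collagenous
#' matrix, and bright spheres with sharp borders emulating fat cells.
#' Degradation (detector-PSF blur, additive Gaussian noise, ring bias) is
#' parameterized here and applied by [degrade()].
#'
#' Defaults emulate the coarser instrument profile (1.63 um voxels):
#' fibers of 8 um radius separated by a 4 um matrix rim, fiber/matrix gray
#' levels 1.0/0.6, one-voxel PSF blur and noise sd 0.2 so that the
#' analytic fiber-to-matrix contrast-to-noise ratio is
#' (1.0 - 0.6)/0.2 = 2. Fiber geometry is an assumption (micrometer-scale
#' fibers spanning several voxels), not a measured value.
#'
#' @param shape integer vector `(ny, nx, nz)` in voxels; each >= 16.
#' @param voxel_size isotropic voxel size, um.
#' @param fiber_radius fiber cylinder radius, um.
#' @param fiber_gap matrix rim between adjacent fibers, um (center spacing
#'   is `2 * fiber_radius + fiber_gap`).
#' @param fiber_level,matrix_level gray values of fiber and matrix phases;
#'   fibers must image brighter than matrix.
#' @param crimp_amplitude sinusoidal centerline displacement in x, um
#'   (0 = straight fibers).
#' @param crimp_period crimp wavelength along z, um.
#' @param sphere_radius_range min/max fat-cell sphere radius, um.
#' @param sphere_count number of non-overlapping spheres to place.
#' @param psf_sigma Gaussian detector-PSF sd, um.
#' @param noise_sigma additive Gaussian noise sd, gray units.
#' @param ring_amplitude ring-artifact bias amplitude, gray units.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   volumes.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L),
                         voxel_size = 1.63,
                         fiber_radius = 8,
                         fiber_gap = 4,
                         fiber_level = 1.0,
                         matrix_level = 0.6,
                         crimp_amplitude = 0,
                         crimp_period = 150,
                         sphere_radius_range = c(12, 25),
                         sphere_count = 6L,
                         psf_sigma = 1.63,
                         noise_sigma = 0.2,
                         ring_amplitude = 0,
                         seed = 1L) {
  spec <- structure(
    list(shape = as.integer(shape), voxel_size = voxel_size,
         fiber_radius = fiber_radius, fiber_gap = fiber_gap,
         fiber_level = fiber_level, matrix_level = matrix_level,
         crimp_amplitude = crimp_amplitude, crimp_period = crimp_period,
         sphere_radius_range = as.numeric(sphere_radius_range),
         sphere_count = as.integer(sphere_count),
         psf_sigma = psf_sigma, noise_sigma = noise_sigma,
         ring_amplitude = ring_amplitude, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec$shape
  if (length(s) != 3L || any(!is.finite(s)) || any(s < 16L)) {
    stop_validation("shape must be three integers, each >= 16")
  }
  check_scalar_number(spec$voxel_size, "voxel_size", 0, strict = TRUE)
  check_scalar_number(spec$fiber_radius, "fiber_radius", 0, strict = TRUE)
  check_scalar_number(spec$fiber_gap, "fiber_gap", 0, strict = TRUE)
  check_scalar_number(spec$crimp_amplitude, "crimp_amplitude", 0)
  check_scalar_number(spec$crimp_period, "crimp_period", 0, strict = TRUE)
  if (!(spec$fiber_level > spec$matrix_level)) {
    stop_validation("fiber_level must exceed matrix_level (fibers image brighter)")
  }
  r <- spec$sphere_radius_range
  if (length(r) != 2L || any(r <= 0) || r[2] < r[1]) {
    stop_validation("sphere_radius_range must be a positive increasing pair")
  }
  check_scalar_number(spec$psf_sigma, "psf_sigma", 0)
  check_scalar_number(spec$noise_sigma, "noise_sigma", 0)
  check_scalar_number(spec$ring_amplitude, "ring_amplitude", 0)
  check_scalar_number(spec$seed, "seed")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s voxels @ %.3g um | fibers r=%g gap=%g um (%g/%g gray)\n",
    paste(x$shape, collapse = "x"), x$voxel_size, x$fiber_radius,
    x$fiber_gap, x$fiber_level, x$matrix_level))
  cat(sprintf("  crimp %g um / %g um, %d spheres r in [%g, %g] um\n",
              x$crimp_amplitude, x$crimp_period, x$sphere_count,
              x$sphere_radius_range[1], x$sphere_radius_range[2]))
  cat(sprintf("  degrade: psf %g um, noise %g, ring %g, seed %d\n",
              x$psf_sigma, x$noise_sigma, x$ring_amplitude, x$seed))
  invisible(x)
}

# Hexagonal-lattice fiber cross-section membership for a 2D grid.
# qx, qy: query coordinates in voxel units (may be shifted for crimp);
# a: center spacing, r: fiber radius, both in voxels. The lattice is
# anchored so one fiber center sits at (cx, cy). Returns logical matrix.
hex_fiber_mask <- function(qx, qy, cx, cy, a, r) {
  h <- a * sqrt(3) / 2
  jr <- (qy - cy) / h
  inside <- matrix(FALSE, nrow = nrow(qx), ncol = ncol(qx))
  r2 <- r^2
  for (dj in -1:1) {
    j <- floor(jr) + dj
    ycen <- cy + j * h
    xoff <- cx + (j %% 2) * a / 2
    ir <- (qx - xoff) / a
    for (di in -1:1) {
      i <- floor(ir) + di
      xcen <- xoff + i * a
      inside <- inside | ((qx - xcen)^2 + (qy - ycen)^2 <= r2)
    }
  }
  inside
}

#' Generate the parallel-fiber phantom
#'
#' Bright cylinders of radius `fiber_radius` on a hexagonal (densest
#' packing) lattice with center spacing `2 * fiber_radius + fiber_gap`,
#' axes parallel to z, in a darker matrix. With `crimp_amplitude > 0` all
#' centerlines are displaced sinusoidally in x with wavelength
#' `crimp_period` along z (in-phase crimp). No degradation is applied;
#' voxels are exactly `fiber_level` inside and `matrix_level` outside, so
#' the phantom carries its own analytic ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume_stack()]; `meta` records the lattice type, spacing
#'   and analytic packing fraction.
#' @export
make_fiber_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$shape
  vx <- spec$voxel_size
  spacing_um <- 2 * spec$fiber_radius + spec$fiber_gap
  fov_x <- d[2] * vx
  fov_y <- d[1] * vx
  if (spacing_um > fov_x) {
    stop_validation("fiber spacing ", spacing_um, " um exceeds the x field of view (",
                    fov_x, " um): no fiber fits")
  }
  if (spacing_um > fov_y) {
    stop_validation("fiber spacing ", spacing_um, " um exceeds the y field of view (",
                    fov_y, " um): no fiber fits")
  }
  a <- spacing_um / vx
  r <- spec$fiber_radius / vx
  cy <- (d[1] + 1) / 2
  cx <- (d[2] + 1) / 2
  qy <- matrix(seq_len(d[1]), d[1], d[2])
  qx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  vol <- array(spec$matrix_level, d)
  amp_vox <- spec$crimp_amplitude / vx
  if (amp_vox == 0) {
    m <- hex_fiber_mask(qx, qy, cx, cy, a, r)
    slice <- matrix(spec$matrix_level, d[1], d[2])
    slice[m] <- spec$fiber_level
    for (k in seq_len(d[3])) vol[, , k] <- slice
  } else {
    for (k in seq_len(d[3])) {
      dx <- amp_vox * sin(2 * pi * (k - 1) * vx / spec$crimp_period)
      m <- hex_fiber_mask(qx - dx, qy, cx, cy, a, r)
      slice <- matrix(spec$matrix_level, d[1], d[2])
      slice[m] <- spec$fiber_level
      vol[, , k] <- slice
    }
  }
  packing <- 2 * pi * r^2 / (sqrt(3) * a^2)
  volume_stack(vol, vx, meta = list(
    content = "fibers", lattice = "hexagonal",
    spacing_um = spacing_um, packing_fraction = packing,
    fiber_level = spec$fiber_level, matrix_level = spec$matrix_level))
}

#' Generate the fat-cell sphere phantom
#'
#' Non-overlapping bright spheres (sharp borders, gray `fiber_level`) on a
#' `matrix_level` background. Radii are drawn uniformly from
#' `sphere_radius_range` and centers by rejection sampling (spheres fully
#' inside the volume, pairwise disjoint), all under `spec$seed`, so the
#' output is a pure function of the spec.
#'
#' @param spec a [phantom_spec()] with `sphere_count >= 1`.
#' @return a [volume_stack()]; `meta` records centers and radii (voxels).
#' @export
make_fat_cell_phantom <- function(spec) {
  validate_phantom_spec(spec)
  if (spec$sphere_count < 1L) stop_validation("sphere_count must be >= 1")
  d <- spec$shape
  vx <- spec$voxel_size
  rmin <- spec$sphere_radius_range[1] / vx
  rmax <- spec$sphere_radius_range[2] / vx
  if (2 * rmin + 2 > min(d)) {
    stop_validation("smallest sphere (diameter ", 2 * rmin,
                    " voxels) does not fit in shape ", paste(d, collapse = "x"))
  }
  placed <- with_seed(spec$seed, {
    centers <- matrix(NA_real_, 0, 3)   # (y, x, z) voxels
    radii <- numeric(0)
    attempts <- 0L
    while (length(radii) < spec$sphere_count && attempts < 10000L) {
      attempts <- attempts + 1L
      r <- stats::runif(1, rmin, rmax)
      if (2 * r + 2 > min(d)) next
      cen <- vapply(d, function(n) stats::runif(1, r + 1, n - r), 0)
      if (nrow(centers) > 0) {
        sep <- sqrt(rowSums(sweep(centers, 2, cen)^2))
        if (any(sep < radii + r)) next
      }
      centers <- rbind(centers, cen)
      radii <- c(radii, r)
    }
    list(centers = centers, radii = radii)
  })
  if (length(placed$radii) < spec$sphere_count) {
    stop_computation("could only place ", length(placed$radii), " of ",
                     spec$sphere_count, " non-overlapping spheres in 10000 attempts")
  }
  vol <- array(spec$matrix_level, d)
  for (s in seq_along(placed$radii)) {
    cen <- placed$centers[s, ]
    r <- placed$radii[s]
    yr <- max(1L, floor(cen[1] - r)):min(d[1], ceiling(cen[1] + r))
    xr <- max(1L, floor(cen[2] - r)):min(d[2], ceiling(cen[2] + r))
    zr <- max(1L, floor(cen[3] - r)):min(d[3], ceiling(cen[3] + r))
    dy2 <- (yr - cen[1])^2
    dx2 <- (xr - cen[2])^2
    dz2 <- (zr - cen[3])^2
    box <- outer(outer(dy2, dx2, "+"), dz2, "+") <= r^2
    sub <- vol[yr, xr, zr, drop = FALSE]
    sub[box] <- spec$fiber_level
    vol[yr, xr, zr] <- sub
  }
  volume_stack(vol, vx, meta = list(
    content = "fat_cells",
    centers_vox = unname(placed$centers), radii_vox = placed$radii,
    fiber_level = spec$fiber_level, matrix_level = spec$matrix_level))
}

#' Generate a solid-cylinder phantom
#'
#' A single bright cylinder along z on a dark background — a minimal
#' tendon-outline stand-in for exercising reorientation and
#' cross-sectional-area measurement.
#'
#' @param shape integer `(ny, nx, nz)` voxels.
#' @param voxel_size voxel size, um.
#' @param radius cylinder radius, um.
#' @param level,background gray values inside / outside.
#' @param tilt_deg optional tilt of the cylinder axis in the xz-plane,
#'   degrees.
#' @return a [volume_stack()].
#' @export
make_cylinder_phantom <- function(shape, voxel_size, radius,
                                  level = 1, background = 0, tilt_deg = 0) {
  d <- as.integer(shape)
  if (length(d) != 3L || any(d < 4L)) stop_validation("shape must be three integers >= 4")
  check_scalar_number(voxel_size, "voxel_size", 0, strict = TRUE)
  check_scalar_number(radius, "radius", 0, strict = TRUE)
  r <- radius / voxel_size
  cy <- (d[1] + 1) / 2
  cx <- (d[2] + 1) / 2
  cz <- (d[3] + 1) / 2
  dy2 <- (seq_len(d[1]) - cy)^2
  vol <- array(background, d)
  t <- tan(tilt_deg * pi / 180)
  for (k in seq_len(d[3])) {
    xc <- cx + t * (k - cz)
    dx2 <- (seq_len(d[2]) - xc)^2
    m <- outer(dy2, dx2, "+") <= r^2
    slice <- matrix(background, d[1], d[2])
    slice[m] <- level
    vol[, , k] <- slice
  }
  volume_stack(vol, voxel_size, meta = list(content = "cylinder",
                                            radius_um = radius,
                                            tilt_deg = tilt_deg))
}

#' Degrade a volume with blur, noise and ring bias
#'
#' Applies, in this fixed order: (1) Gaussian blur of sd `psf_sigma`
#' (micrometers, converted to voxels) with symmetric (reflective) boundary
#' handling, so that the mean gray value is conserved exactly; (2)
#' additive zero-mean Gaussian noise of sd `noise_sigma` (gray units);
#' (3) a per-slice concentric-ring bias field
#' `ring_amplitude * sin(r_vox)` where `r_vox` is the in-plane distance
#' (voxels) from the volume's central axis — the simplest structured
#' artifact that defeats naive global thresholding, standing in for
#' detector ring artifacts.
#'
#' @param volume a [volume_stack()].
#' @param psf_sigma Gaussian blur sd, um (>= 0).
#' @param noise_sigma additive noise sd, gray units (>= 0).
#' @param ring_amplitude ring bias amplitude, gray units (>= 0).
#' @param seed integer seed for the noise draw.
#' @return a degraded [volume_stack()] with the applied parameters
#'   appended to `meta`.
#' @export
degrade <- function(volume, psf_sigma = 0, noise_sigma = 0,
                    ring_amplitude = 0, seed = 1L) {
  stopifnot(inherits(volume, "volume_stack"))
  check_scalar_number(psf_sigma, "psf_sigma", 0)
  check_scalar_number(noise_sigma, "noise_sigma", 0)
  check_scalar_number(ring_amplitude, "ring_amplitude", 0)
  d <- dim(volume$data)
  a <- volume$data
  if (psf_sigma > 0) a <- gauss_blur(a, psf_sigma / volume$voxel_size)
  if (noise_sigma > 0) {
    a <- a + with_seed(seed, array(stats::rnorm(prod(d), 0, noise_sigma), d))
  }
  if (ring_amplitude > 0) {
    cy <- (d[1] + 1) / 2
    cx <- (d[2] + 1) / 2
    rad <- sqrt(outer((seq_len(d[1]) - cy)^2, (seq_len(d[2]) - cx)^2, "+"))
    bias <- ring_amplitude * sin(rad)
    a <- a + array(bias, d)   # same rings on every slice
  }
  meta <- volume$meta
  meta$degrade <- list(psf_sigma_um = psf_sigma, noise_sigma = noise_sigma,
                       ring_amplitude = ring_amplitude, seed = as.integer(seed))
  volume_stack(a, volume$voxel_size, meta = meta)
}

#' Projected-thickness map of a phantom
#'
#' Line integral of the binary phantom structure (fibers or fat cells)
#' along the beam axis (the volume's y axis), times the voxel size:
#' thickness in micrometers per detector pixel. Rows of the returned map
#' index z (vertical on the detector), columns index x. This is the
#' forward-model input for the Fresnel propagation / Paganin retrieval
#' round trip.
#'
#' With `psf_sigma > 0` the projected map is additionally smoothed by a
#' detector-referred Gaussian of that sd (micrometers) — the same PSF
#' model [degrade()] applies to volumes. The default (0) returns the raw
#' line integral of the binary structure.
#'
#' @param spec a [phantom_spec()].
#' @param content which structure to project, `"fibers"` or `"fat_cells"`.
#' @param psf_sigma detector PSF sd applied to the projected map, um.
#' @return numeric matrix `(nz, nx)` of thickness in um, with attribute
#'   `pixel_size_um`.
#' @export
make_phase_object <- function(spec, content = c("fibers", "fat_cells"),
                              psf_sigma = 0) {
  content <- match.arg(content)
  check_scalar_number(psf_sigma, "psf_sigma", 0)
  vol <- switch(content,
                fibers = make_fiber_phantom(spec),
                fat_cells = make_fat_cell_phantom(spec))
  mask <- vol$data > (spec$matrix_level + spec$fiber_level) / 2
  # sum over y (dim 1) -> (nx, nz), transpose to (nz, nx)
  thick <- t(apply(mask, c(2, 3), sum)) * spec$voxel_size
  if (psf_sigma > 0) thick <- gauss_blur(thick, psf_sigma / spec$voxel_size)
  attr(thick, "pixel_size_um") <- spec$voxel_size
  thick
}
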