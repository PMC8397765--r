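# Wave-optics stage: fringe-distance rule, flat/dark correction, Fresnel
# forward propagation (forward model for testing), Paganin single-distance
# retrieval, line-profile diagnostic, dose arithmetic.

# physical constants (SI)
.hc_Jm <- 6.62607015e-34 * 2.99792458e8     # Planck * c
.keV_J <- 1.602176634e-16

#' X-ray wavelength from photon energy
#'
#' `lambda = hc / E`. At 15 keV this gives ~0.827 Angstrom.
#'
#' @param energy_kev photon energy in keV (> 0).
#' @return wavelength in meters.
#' @export
xray_wavelength <- function(energy_kev) {
  check_scalar_number(energy_kev, "energy_kev", 0, strict = TRUE)
  .hc_Jm / (energy_kev * .keV_J)
}

#' First-interference-fringe propagation distance
#'
#' The single-distance phase-contrast regime is bounded by the distance at
#' which the first interference fringe matches the detector sampling:
#' `z = (2 p)^2 / lambda` for effective pixel size `p`. For the two
#' instrument profiles at 15 keV this gives ~130 mm (1.63 um pixels) and
#' ~5 mm (0.33 um pixels).
#'
#' @param pixel_size effective detector pixel size, um (> 0).
#' @param energy_kev photon energy, keV (> 0).
#' @return distance in mm.
#' @examples
#' first_fringe_distance(1.63, 15)  # ~129 mm
#' first_fringe_distance(0.33, 15)  # ~5.3 mm
#' @export
first_fringe_distance <- function(pixel_size, energy_kev) {
  check_scalar_number(pixel_size, "pixel_size", 0, strict = TRUE)
  lambda <- xray_wavelength(energy_kev)
  (2 * pixel_size * 1e-6)^2 / lambda * 1e3
}

#' Skin dose from dose rate and exposure
#'
#' Upper-bound entrance dose for one projection: dose rate times exposure
#' time (e.g. 200 Gy/s for 100 ms gives 20 Gy).
#'
#' @param dose_rate dose rate, Gy/s (>= 0).
#' @param exposure exposure time, s (>= 0).
#' @return dose in Gy.
#' @export
skin_dose <- function(dose_rate, exposure) {
  check_scalar_number(dose_rate, "dose_rate", 0)
  check_scalar_number(exposure, "exposure", 0)
  dose_rate * exposure
}

#' Configure the imaging optics
#'
#' Houses the wave-optics parameters: photon energy, detector-referred
#' pixel size, sample-to-detector propagation distance, and the complex
#' refractive index `n = 1 - delta + i beta` of the (assumed homogeneous)
#' sample. When `delta` is not given it is derived from the retrieval
#' ratio as `delta = delta_beta_ratio * beta`, mirroring the practice of
#' tuning the phase-retrieval strength through the delta/beta ratio while
#' beta is fixed from tabulated soft-tissue attenuation (default
#' 9.3e-9 at 15 keV).
#'
#' @param energy photon energy, keV.
#' @param pixel_size pixel size, um.
#' @param distance sample-to-detector distance `z_D`, mm (>= 0).
#' @param beta absorption index (> 0).
#' @param delta_beta_ratio retrieval ratio delta/beta (> 0); default 50.
#' @param delta refractive index decrement; default derived from the ratio.
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(energy = 15, pixel_size = 1.63, distance = 150,
                          beta = 9.3e-9, delta_beta_ratio = 50,
                          delta = NULL) {
  check_scalar_number(energy, "energy", 0, strict = TRUE)
  check_scalar_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_scalar_number(distance, "distance", 0)
  check_scalar_number(beta, "beta", 0, strict = TRUE)
  check_scalar_number(delta_beta_ratio, "delta_beta_ratio", 0, strict = TRUE)
  if (is.null(delta)) delta <- delta_beta_ratio * beta
  check_scalar_number(delta, "delta", 0, strict = TRUE)
  structure(
    list(energy = energy, pixel_size = pixel_size, distance = distance,
         beta = beta, delta_beta_ratio = delta_beta_ratio, delta = delta,
         wavelength = xray_wavelength(energy)),
    class = "optics_config"
  )
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "<optics_config> %g keV (lambda %.4g A), pixel %g um, z_D %g mm\n",
    x$energy, x$wavelength * 1e10, x$pixel_size, x$distance))
  cat(sprintf("  beta %.3g, delta %.3g (delta/beta = %g)\n",
              x$beta, x$delta, x$delta / x$beta))
  invisible(x)
}

# linear attenuation coefficient mu = 4 pi beta / lambda, 1/m
mu_linear <- function(optics) 4 * pi * optics$beta / optics$wavelength

as_image_stack <- function(x, name) {
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[3]), function(k) x[, , k]))
  }
  if (is.list(x) && all(vapply(x, is.matrix, TRUE))) return(x)
  stop_validation(name, " must be a matrix, 3D array, or list of matrices")
}

#' Bundle projections with flats, darks and optics
#'
#' @param projections matrix, 3D array `(ny, nx, n_proj)`, or list of
#'   matrices.
#' @param flats,darks flat-field / dark-current frames, same shape as the
#'   projections; at least one of each.
#' @param optics an [optics_config()].
#' @param angles optional rotation angles (degrees), one per projection.
#' @return an object of class `projection_set`.
#' @export
projection_set <- function(projections, flats, darks, optics, angles = NULL) {
  stopifnot(inherits(optics, "optics_config"))
  proj <- as_image_stack(projections, "projections")
  flats <- as_image_stack(flats, "flats")
  darks <- as_image_stack(darks, "darks")
  shapes <- unique(vapply(c(proj, flats, darks),
                          function(m) paste(dim(m), collapse = "x"), ""))
  if (length(shapes) != 1L) stop_validation("all frames must share one shape")
  if (length(flats) < 1L || length(darks) < 1L) {
    stop_validation("at least one flat and one dark frame are required")
  }
  if (!is.null(angles) && length(angles) != length(proj)) {
    stop_validation("angles must match the number of projections")
  }
  structure(list(projections = proj, flats = flats, darks = darks,
                 optics = optics, angles = angles),
            class = "projection_set")
}

#' Flat/dark correction of a projection set
#'
#' Per projection returns `(I - Dbar) / (Fbar - Dbar)` with `Dbar`, `Fbar`
#' the pixelwise mean dark and flat frames. The transmission is clipped
#' below at `1e-6` of the mean flat level so downstream logarithms stay
#' finite.
#'
#' @param proj a [projection_set()].
#' @return list of corrected transmission matrices.
#' @export
flat_dark_correct <- function(proj) {
  stopifnot(inherits(proj, "projection_set"))
  Fbar <- Reduce(`+`, proj$flats) / length(proj$flats)
  Dbar <- Reduce(`+`, proj$darks) / length(proj$darks)
  denom <- Fbar - Dbar
  nbad <- sum(denom <= 0)
  if (nbad > 0) {
    stop_computation(nbad, " pixel(s) have mean flat <= mean dark; ",
                     "flat/dark frames are unusable")
  }
  floorv <- 1e-6 * mean(Fbar)
  lapply(proj$projections, function(I) pmax((I - Dbar) / denom, floorv))
}

pad_even <- function(m) {
  d <- dim(m)
  if (d[1] %% 2L == 1L) m <- rbind(m, m[d[1], , drop = FALSE])
  if (d[2] %% 2L == 1L) m <- cbind(m, m[, dim(m)[2], drop = FALSE])
  m
}

#' Fresnel forward propagation of a thickness map
#'
#' Forward model used to test the retrieval chain. Builds the complex
#' transmission `exp(-(mu/2) t - i k delta t)` from projected thickness
#' `t` (`mu = 4 pi beta / lambda`, `k = 2 pi / lambda`), applies the
#' paraxial Fresnel transfer function
#' `H(f) = exp(-i pi lambda z |f|^2)` for distance `z_D` at the configured
#' pixel pitch, and returns the squared modulus (intensity, unit incident
#' flux). At `z_D = 0` this reduces to the pure-absorption image
#' `exp(-mu t)`.
#'
#' @param thickness_map numeric matrix of projected thickness, um.
#' @param optics an [optics_config()].
#' @return intensity matrix, same shape as the input.
#' @export
fresnel_propagate <- function(thickness_map, optics) {
  stopifnot(inherits(optics, "optics_config"))
  if (!is.matrix(thickness_map) || !is.numeric(thickness_map)) {
    stop_validation("thickness_map must be a numeric matrix")
  }
  d0 <- dim(thickness_map)
  m <- pad_even(thickness_map)
  d <- dim(m)
  lambda <- optics$wavelength
  p <- optics$pixel_size * 1e-6
  z <- optics$distance * 1e-3
  if (z > 0) {
    zmax <- min(d) * p^2 / lambda
    if (z > zmax) {
      stop_validation(sprintf(
        "Fresnel transfer function undersampled: z_D = %g mm exceeds the maximum safe distance %.4g mm for %d px at %g um pitch",
        optics$distance, zmax * 1e3, min(d), optics$pixel_size))
    }
  }
  t_m <- m * 1e-6
  mu <- mu_linear(optics)
  k <- 2 * pi / lambda
  Tc <- exp(-(mu / 2 + 1i * k * optics$delta) * t_m)
  if (z == 0) {
    out <- Mod(Tc)^2
  } else {
    fy <- fft_freq(d[1], p)
    fx <- fft_freq(d[2], p)
    f2 <- outer(fy^2, fx^2, "+")
    H <- exp(-1i * pi * lambda * z * f2)
    U <- stats::fft(stats::fft(Tc) * H, inverse = TRUE) / prod(d)
    out <- Mod(U)^2
  }
  out[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]
}

# next FFT-friendly size >= n (factors 2,3,5), via stats::nextn
fast_size <- function(n) stats::nextn(n, factors = c(2L, 3L, 5L))

# symmetric (mirror) pad a matrix to target dims
pad_symmetric <- function(m, dy, dx) {
  d <- dim(m)
  iy <- reflect_index(seq_len(dy), d[1])
  ix <- reflect_index(seq_len(dx), d[2])
  m[iy, ix, drop = FALSE]
}

#' Paganin single-distance phase retrieval
#'
#' Recovers projected thickness from a single propagation distance under
#' the homogeneous-object assumption: per projection,
#' `t = -(1/mu) ln( IFFT[ FFT[I/I0] / (1 + (z_D delta / mu) |q|^2) ] )`
#' with `|q| = 2 pi |f|` the angular spatial frequency in physical units.
#' The low-pass filter strength grows with the delta/beta ratio. Images
#' are mirror-padded to the next FFT-friendly size before filtering and
#' cropped on return.
#'
#' @param transmission flat/dark-corrected transmission: matrix, 3D array
#'   or list of matrices, values in `(0, ~1.5]`.
#' @param optics an [optics_config()]; `delta` defaults to
#'   `delta_beta_ratio * beta`.
#' @return retrieved thickness in um — a matrix if a single image was
#'   given, otherwise a list of matrices.
#' @export
paganin_retrieve <- function(transmission, optics) {
  stopifnot(inherits(optics, "optics_config"))
  single <- is.matrix(transmission)
  stack <- as_image_stack(transmission, "transmission")
  mu <- mu_linear(optics)
  z <- optics$distance * 1e-3
  p <- optics$pixel_size * 1e-6
  coef <- z * optics$delta / mu
  out <- lapply(stack, function(I) {
    d0 <- dim(I)
    dy <- fast_size(d0[1])
    dx <- fast_size(d0[2])
    m <- pad_symmetric(I, dy, dx)
    q2 <- (2 * pi)^2 * outer(fft_freq(dy, p)^2, fft_freq(dx, p)^2, "+")
    filt <- Re(stats::fft(stats::fft(m) / (1 + coef * q2), inverse = TRUE)) / (dy * dx)
    filt <- filt[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]
    nbad <- sum(filt <= 0)
    if (nbad > 0) {
      stop_computation(nbad, " non-positive value(s) entering the retrieval ",
                       "logarithm; check flat/dark correction")
    }
    -log(filt) / mu * 1e6
  })
  if (single) out[[1L]] else out
}

#' Intensity profile along a line segment
#'
#' Ordered gray values along an axis-aligned segment of `length` pixels —
#' the diagnostic used to compare reconstructions at different delta/beta
#' ratios at the same location.
#'
#' @param slice 2D numeric matrix (one reconstructed slice).
#' @param start integer `(row, col)` of the first sample.
#' @param direction `"x"` (along columns) or `"y"` (along rows).
#' @param length number of samples; default 200.
#' @return numeric vector of `length` gray values.
#' @export
ratio_line_profile <- function(slice, start, direction = c("x", "y"),
                               length = 200L) {
  direction <- match.arg(direction)
  if (!is.matrix(slice)) stop_validation("slice must be a matrix")
  if (length(start) != 2L) stop_validation("start must be (row, col)")
  length <- as.integer(length)
  check_scalar_number(length, "length", 1)
  d <- dim(slice)
  r0 <- as.integer(start[1]); c0 <- as.integer(start[2])
  if (r0 < 1L || c0 < 1L || r0 > d[1] || c0 > d[2]) {
    stop_validation("start (", r0, ",", c0, ") outside image ",
                    d[1], "x", d[2])
  }
  if (direction == "x") {
    end <- c0 + length - 1L
    if (end > d[2]) {
      stop_validation("segment exceeds image: columns ", c0, "..", end,
                      " but image has ", d[2], " (clipped extent ", d[2] - c0 + 1L,
                      " px)")
    }
    slice[r0, c0:end]
  } else {
    end <- r0 + length - 1L
    if (end > d[1]) {
      stop_validation("segment exceeds image: rows ", r0, "..", end,
                      " but image has ", d[1], " (clipped extent ", d[1] - r0 + 1L,
                      " px)")
    }
    slice[r0:end, c0]
  }
}
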