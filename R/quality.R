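# The four image-quality metrics computed on sub-volumes, plus the
# reproducibility summary (mean, SD, CV).

#' Construct a sub-volume for quality analysis
#'
#' A cube (or box) cut from a reconstructed volume, labeled by content:
#' metric legality follows the label — spatial resolution, FMCR and UTS
#' are defined on fiber sub-volumes, GSE on fat-cell sub-volumes (sharp
#' sphere borders).
#'
#' @param data 3D numeric array `(ny, nx, nz)`.
#' @param voxel_size isotropic voxel size, um.
#' @param content `"fibers"` or `"fat_cells"`.
#' @param origin integer `(y, x, z)` offset of this sub-volume in its
#'   parent volume (1-based voxel of the first corner).
#' @return an object of class `subvolume`.
#' @export
subvolume <- function(data, voxel_size, content = c("fibers", "fat_cells"),
                      origin = c(1L, 1L, 1L)) {
  content <- match.arg(content)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_validation("data must be a 3D array")
  }
  check_scalar_number(voxel_size, "voxel_size", 0, strict = TRUE)
  structure(list(data = data, voxel_size = voxel_size, content = content,
                 origin = as.integer(origin)),
            class = "subvolume")
}

#' @export
print.subvolume <- function(x, ...) {
  cat(sprintf("<subvolume> %s, %s voxels @ %.3g um, origin (%s)\n",
              x$content, paste(dim(x$data), collapse = "x"), x$voxel_size,
              paste(x$origin, collapse = ",")))
  invisible(x)
}

#' @export
as.subvolume <- function(x, ...) UseMethod("as.subvolume")

#' @export
as.subvolume.volume_stack <- function(x, content = c("fibers", "fat_cells"), ...) {
  content <- match.arg(content)
  subvolume(x$data, x$voxel_size, content = content)
}

moving_average <- function(x, width = 5L) {
  # centered moving average with shrinking windows at the ends
  n <- length(x)
  h <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# averaged one-sided PSD over the rows (direction = "x") or columns
# ("y") of a slice; DC excluded
slice_psd <- function(slice, direction) {
  if (direction == "y") slice <- t(slice)
  n <- ncol(slice)
  prof <- slice - rowMeans(slice)
  P <- Mod(stats::mvfft(t(prof)))^2 / n
  nf <- n %/% 2L
  rowMeans(P[2:(nf + 1L), , drop = FALSE])
}

#' Spatial resolution from power-spectral-density analysis
#'
#' Estimates spatial resolution from the frequency at which the image
#' power spectrum converges to the noise floor. For `n_slices` z-slices
#' (first, middle, last) the 1D PSDs of all row (x) and column (y)
#' profiles are averaged; the noise floor `L` is the median PSD over the
#' top 10% of frequencies; the resolution is the full period `1/f*` of
#' the lowest frequency at which the smoothed PSD first falls to `2 L`.
#' The per-slice, per-direction estimates are averaged. A flat spectrum
#' (no signal above the floor at any scale, e.g. pure noise) saturates
#' the estimate at the Nyquist period `2 * voxel_size`; a spectrum that
#' never converges to the floor raises an error (the sub-volume is too
#' small for the criterion).
#'
#' @param sub a fibers [subvolume()], each dimension >= 64 voxels.
#' @param n_slices number of z-slices to analyze (default 3).
#' @param smooth_bins width (bins) of the moving average applied to the
#'   PSD before the threshold crossing is located.
#' @return resolution in um.
#' @export
estimate_resolution <- function(sub, n_slices = 3L, smooth_bins = 5L) {
  stopifnot(inherits(sub, "subvolume"))
  if (sub$content != "fibers") {
    stop_validation("resolution is defined on fiber sub-volumes")
  }
  d <- dim(sub$data)
  if (any(d < 64L)) {
    stop_validation("each sub-volume dimension must be >= 64 voxels (got ",
                    paste(d, collapse = "x"), ")")
  }
  ks <- unique(round(seq(1L, d[3], length.out = max(2L, n_slices))))
  vx <- sub$voxel_size
  est <- c()
  for (k in ks) {
    slice <- sub$data[, , k]
    for (dir in c("x", "y")) {
      psd <- slice_psd(slice, dir)
      nf <- length(psd)
      freq <- seq_len(nf) / ((if (dir == "x") d[2] else d[1]) * vx)
      top <- psd[freq >= stats::quantile(freq, 0.9)]
      L <- stats::median(top)
      sm <- moving_average(psd, smooth_bins)
      below <- which(sm <= 2 * L)
      if (length(below) == 0L) {
        stop_computation("PSD never converges to twice the noise floor; ",
                         "use a larger sub-volume")
      }
      fstar <- freq[below[1L]]
      r <- if (below[1L] == 1L) 2 * vx else max(1 / fstar, 2 * vx)
      est <- c(est, r)
    }
  }
  mean(est)
}

#' Fiber-to-matrix contrast ratio (contrast-to-noise ratio)
#'
#' With fibers as the structure of interest and the inter-fiber matrix as
#' background:
#' `FMCR = (Im_F - Im_M) / sqrt((sigma_F^2 + sigma_M^2) / 2)`
#' where `Im` and `sigma` are the mean and standard deviation of the
#' voxels under each mask. The sign is preserved: inverted contrast gives
#' a negative value.
#'
#' @param sub a fibers [subvolume()].
#' @param fiber_mask,matrix_mask logical arrays matching `sub$data`,
#'   disjoint, each covering at least 1000 voxels (statistical floor).
#' @return dimensionless contrast-to-noise ratio.
#' @export
fmcr <- function(sub, fiber_mask, matrix_mask) {
  stopifnot(inherits(sub, "subvolume"))
  if (!identical(dim(fiber_mask), dim(sub$data)) ||
      !identical(dim(matrix_mask), dim(sub$data))) {
    stop_validation("masks must match the sub-volume dimensions")
  }
  fiber_mask <- as.logical(fiber_mask)
  matrix_mask <- as.logical(matrix_mask)
  if (any(fiber_mask & matrix_mask)) {
    stop_validation("fiber and matrix masks overlap")
  }
  nf <- sum(fiber_mask)
  nm <- sum(matrix_mask)
  if (nf < 1000L || nm < 1000L) {
    stop_validation("each mask needs >= 1000 voxels (got ", nf, " fiber, ",
                    nm, " matrix)")
  }
  f <- sub$data[fiber_mask]
  m <- sub$data[matrix_mask]
  (mean(f) - mean(m)) / sqrt((stats::var(f) + stats::var(m)) / 2)
}

#' Uncertainty of threshold-based segmentation
#'
#' Fraction of voxels whose gray value cannot be uniquely assigned to the
#' fiber or the matrix phase. A three-class Otsu decomposition of the
#' 256-bin gray histogram yields thresholds `t_low < t_high`: `t_high`
#' selects the fibers as precisely as possible, `t_low` the matrix; the
#' voxels in between are ambiguous:
#' `UTS = 100 * #{t_low < v <= t_high} / #voxels`.
#' An optional Gaussian prefilter (in voxels) is applied first — intended
#' for the coarser instrument profile, where unfiltered noise inflates
#' the ambiguous band; the finer profile needs none.
#'
#' @param sub a fibers [subvolume()].
#' @param prefilter_sigma Gaussian prefilter sd in voxels, or `NULL` for
#'   none.
#' @param bins histogram bins (default 256).
#' @return list with `uts_pct`, the thresholds `t_low`, `t_high` (gray
#'   units), and the `prefilter_sigma` used.
#' @export
uts <- function(sub, prefilter_sigma = NULL, bins = 256L) {
  stopifnot(inherits(sub, "subvolume"))
  if (sub$content != "fibers") {
    stop_validation("UTS is defined on fiber sub-volumes")
  }
  a <- sub$data
  if (!is.null(prefilter_sigma)) {
    check_scalar_number(prefilter_sigma, "prefilter_sigma", 0)
    if (prefilter_sigma > 0) a <- gauss_blur(a, prefilter_sigma)
  }
  h <- hist_fixed(as.numeric(a), bins = bins)
  if (sum(h$counts > 0) == 2L) {
    # perfectly bimodal (two delta peaks): no ambiguous band exists, the
    # matrix- and fiber-precise thresholds coincide at the 2-class split
    t1 <- otsu_from_hist(h$counts, h$mids, k = 2L)
    idx <- c(t1, t1)
  } else {
    idx <- otsu_from_hist(h$counts, h$mids, k = 3L)
  }
  t_low <- h$upper[idx[1L]]
  t_high <- h$upper[idx[2L]]
  amb <- if (idx[2L] > idx[1L]) sum(h$counts[(idx[1L] + 1L):idx[2L]]) else 0L
  list(uts_pct = 100 * amb / length(a),
       t_low = t_low, t_high = t_high,
       prefilter_sigma = prefilter_sigma %||% 0)
}

# per-slice central-difference gradient magnitude on interior pixels
slice_gradient_magnitude <- function(slice) {
  d <- dim(slice)
  iy <- 2:(d[1] - 1L)
  ix <- 2:(d[2] - 1L)
  gy <- (slice[iy + 1L, ix] - slice[iy - 1L, ix]) / 2
  gx <- (slice[iy, ix + 1L] - slice[iy, ix - 1L]) / 2
  sqrt(gy^2 + gx^2)
}

#' Gradient sharpness at edges
#'
#' Quantifies edge sharpness (inversely, blurriness): the per-slice 2D
#' gradient magnitude is computed by central differences, edge voxels are
#' classified by Otsu's threshold on the pooled gradient-magnitude
#' histogram, and the mean gradient magnitude over the edge voxels is
#' returned — gray units per voxel. Computed on fat-cell sub-volumes,
#' whose sphere borders are sharp and unambiguous. A 3D gradient
#' (including the z component) is available behind `mode = "3d"`.
#'
#' @param sub a fat-cells [subvolume()] containing at least one edge.
#' @param mode `"slice"` (default, per-slice 2D gradient) or `"3d"`.
#' @param bins histogram bins for the edge threshold (default 256).
#' @return mean edge gradient magnitude, gray units per voxel.
#' @export
gse <- function(sub, mode = c("slice", "3d"), bins = 256L) {
  stopifnot(inherits(sub, "subvolume"))
  mode <- match.arg(mode)
  if (sub$content != "fat_cells") {
    stop_validation("GSE is defined on fat-cell sub-volumes")
  }
  d <- dim(sub$data)
  if (mode == "slice") {
    g <- unlist(lapply(seq_len(d[3]), function(k) {
      slice_gradient_magnitude(sub$data[, , k])
    }), use.names = FALSE)
  } else {
    iy <- 2:(d[1] - 1L); ix <- 2:(d[2] - 1L); iz <- 2:(d[3] - 1L)
    a <- sub$data
    gy <- (a[iy + 1L, ix, iz] - a[iy - 1L, ix, iz]) / 2
    gx <- (a[iy, ix + 1L, iz] - a[iy, ix - 1L, iz]) / 2
    gz <- (a[iy, ix, iz + 1L] - a[iy, ix, iz - 1L]) / 2
    g <- as.numeric(sqrt(gy^2 + gx^2 + gz^2))
  }
  if (max(g) <= 0) stop_computation("no edges detected: gradient is zero everywhere")
  thr <- tryCatch(otsu_thresholds(g, k = 2L, bins = bins),
                  tomoqc_computation_error = function(e) {
                    stop_computation("no edges detected: ", conditionMessage(e))
                  })
  edge <- g > thr
  if (!any(edge)) stop_computation("no edges detected: no voxel exceeds the edge threshold")
  mean(g[edge])
}

#' Reproducibility summary of repeated metric values
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variability `CV = sd / mean` over repeated measurements of one metric
#' in different sub-volumes.
#'
#' @param values numeric vector, length >= 2.
#' @return list with `mean`, `sd`, `cv`, `n`.
#' @export
summarize_metric <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop_validation("need >= 2 finite values to summarize")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0) stop_computation("CV undefined: mean is zero")
  list(mean = m, sd = s, cv = s / m, n = length(values))
}

#' All applicable quality metrics for one sub-volume
#'
#' Dispatches on the content label: fiber sub-volumes get resolution,
#' FMCR (with Otsu-derived masks when none are supplied) and UTS;
#' fat-cell sub-volumes get GSE.
#'
#' For FMCR the fiber/matrix masks default to the voxels above `t_high` /
#' below `t_low` of the same three-class Otsu decomposition UTS uses, so
#' the masks exclude the ambiguous band. Mask granularity affects FMCR;
#' the thresholds used are recorded in the result.
#'
#' @param sub a [subvolume()].
#' @param prefilter_sigma Gaussian prefilter (voxels) for the UTS /
#'   mask thresholds; default 1 for typical coarse-profile volumes,
#'   use `NULL` or 0 for fine-profile volumes.
#' @param fiber_mask,matrix_mask optional explicit masks for FMCR.
#' @return a one-row data.frame (class `quality_result`) with columns
#'   `content`, `origin_y/x/z`, `resolution_um`, `fmcr`, `uts_pct`,
#'   `gse`, `t_low`, `t_high`, `prefilter_sigma`; inapplicable metrics
#'   are `NA`.
#' @export
quality_metrics <- function(sub, prefilter_sigma = 1,
                            fiber_mask = NULL, matrix_mask = NULL) {
  stopifnot(inherits(sub, "subvolume"))
  row <- data.frame(content = sub$content,
                    origin_y = sub$origin[1], origin_x = sub$origin[2],
                    origin_z = sub$origin[3],
                    resolution_um = NA_real_, fmcr = NA_real_,
                    uts_pct = NA_real_, gse = NA_real_,
                    t_low = NA_real_, t_high = NA_real_,
                    prefilter_sigma = NA_real_,
                    stringsAsFactors = FALSE)
  if (sub$content == "fibers") {
    row$resolution_um <- estimate_resolution(sub)
    u <- uts(sub, prefilter_sigma = prefilter_sigma)
    row$uts_pct <- u$uts_pct
    row$t_low <- u$t_low
    row$t_high <- u$t_high
    row$prefilter_sigma <- u$prefilter_sigma
    if (is.null(fiber_mask)) fiber_mask <- sub$data > u$t_high
    if (is.null(matrix_mask)) matrix_mask <- sub$data <= u$t_low
    row$fmcr <- fmcr(sub, fiber_mask, matrix_mask)
  } else {
    row$gse <- gse(sub)
  }
  class(row) <- c("quality_result", class(row))
  row
}
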