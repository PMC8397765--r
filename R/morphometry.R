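# Volume reorientation, sub-volume extraction along the tendon axis, and
# the MIP-based cross-sectional-area measurement.

# foreground mask via global 2-class Otsu (256 bins)
foreground_mask <- function(volume) {
  thr <- otsu_thresholds(volume$data, k = 2L)
  volume$data > thr
}

# principal axes of a voxel cloud: list(center, vectors, values)
principal_axes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)   # columns y, x, z
  if (nrow(idx) < 10L) stop_computation("foreground too small for axis estimation")
  ctr <- colMeans(idx)
  cen <- sweep(idx, 2, ctr)
  C <- crossprod(cen) / nrow(idx)
  e <- eigen(C, symmetric = TRUE)
  list(center = ctr, vectors = e$vectors, values = e$values)
}

# Rodrigues rotation taking unit vector v onto unit vector w
rotation_between <- function(v, w) {
  v <- v / sqrt(sum(v^2))
  w <- w / sqrt(sum(w^2))
  c_ <- sum(v * w)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to v
    u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * v) * v
    u <- u / sqrt(sum(u^2))
    return(2 * tcrossprod(u) - diag(3))
  }
  a <- c(v[2] * w[3] - v[3] * w[2],
         v[3] * w[1] - v[1] * w[3],
         v[1] * w[2] - v[2] * w[1])
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# trilinear interpolation of a 3D array at fractional (y, x, z) coords;
# queries outside the domain return `fill`
trilinear <- function(a, y, x, z, fill) {
  d <- dim(a)
  out <- rep(fill, length(y))
  ok <- y >= 1 & y <= d[1] & x >= 1 & x <= d[2] & z >= 1 & z <= d[3]
  if (!any(ok)) return(out)
  y <- y[ok]; x <- x[ok]; z <- z[ok]
  y0 <- pmin(floor(y), d[1] - 1L); x0 <- pmin(floor(x), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fy <- y - y0; fx <- x - x0; fz <- z - z0
  at <- function(dy, dx, dz) a[cbind(y0 + dy, x0 + dx, z0 + dz)]
  v <- at(0, 0, 0) * (1 - fy) * (1 - fx) * (1 - fz) +
       at(1, 0, 0) * fy       * (1 - fx) * (1 - fz) +
       at(0, 1, 0) * (1 - fy) * fx       * (1 - fz) +
       at(1, 1, 0) * fy       * fx       * (1 - fz) +
       at(0, 0, 1) * (1 - fy) * (1 - fx) * fz +
       at(1, 0, 1) * fy       * (1 - fx) * fz +
       at(0, 1, 1) * (1 - fy) * fx       * fz +
       at(1, 1, 1) * fy       * fx       * fz
  out[ok] <- v
  out
}

#' Reorient a volume so the tendon axis is along z
#'
#' Thresholds the volume (global Otsu) to a foreground voxel cloud,
#' computes its principal axes, and rotates the volume (trilinear
#' resampling about the volume center) so the dominant axis aligns with
#' +z. Requires a clearly elongated foreground: the ratio of the largest
#' to second eigenvalue of the voxel-cloud covariance must be at least
#' 1.5, otherwise the axis is undefined. Voxels resampled from outside
#' the original domain are filled with the volume minimum. The applied
#' rotation matrix is recorded in `meta$rotation`.
#'
#' @param volume a [volume_stack()].
#' @param min_anisotropy eigenvalue ratio below which the axis is
#'   declared undefined (default 1.5).
#' @return the reoriented [volume_stack()].
#' @export
reorient <- function(volume, min_anisotropy = 1.5) {
  stopifnot(inherits(volume, "volume_stack"))
  pa <- principal_axes(foreground_mask(volume))
  if (pa$values[1] / pa$values[2] < min_anisotropy) {
    stop_computation("axis undefined: foreground is not elongated ",
                     sprintf("(eigenvalue ratio %.2f < %.2f)",
                             pa$values[1] / pa$values[2], min_anisotropy))
  }
  v <- pa$vectors[, 1]
  if (v[3] < 0) v <- -v
  R <- rotation_between(v, c(0, 0, 1))
  if (max(abs(R - diag(3))) < 1e-12) {
    out <- volume
    out$meta$rotation <- diag(3)
    return(out)
  }
  d <- dim(volume$data)
  ctr <- (d + 1) / 2
  g <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]), z = seq_len(d[3]))
  # output voxel p maps back to input R^T (p - c) + c
  P <- cbind(g$y - ctr[1], g$x - ctr[2], g$z - ctr[3]) %*% R   # = R^T p when rows
  src <- sweep(P, 2, ctr, "+")
  vals <- trilinear(volume$data, src[, 1], src[, 2], src[, 3],
                    fill = min(volume$data))
  meta <- volume$meta
  meta$rotation <- R
  volume_stack(array(vals, d), volume$voxel_size, meta = meta)
}

#' Extract sub-volumes along the tendon axis
#'
#' Cuts `count` axis-aligned cubic sub-volumes of side `size` voxels at
#' regular z offsets (`stride` voxels apart, the run centered in z),
#' centered in x and y on the foreground centroid — the repeated
#' "moving along the tendon main axis" sampling used for reproducibility
#' estimates.
#'
#' @param volume a [volume_stack()].
#' @param count number of sub-volumes (>= 1).
#' @param size sub-volume side, voxels.
#' @param stride z offset between consecutive sub-volumes, voxels;
#'   default `size` (disjoint).
#' @param content label attached to each sub-volume.
#' @return list of [subvolume()] objects.
#' @export
extract_subvolumes <- function(volume, count, size, stride = size,
                               content = c("fibers", "fat_cells")) {
  stopifnot(inherits(volume, "volume_stack"))
  content <- match.arg(content)
  count <- as.integer(count); size <- as.integer(size)
  stride <- as.integer(stride)
  check_scalar_number(count, "count", 1)
  check_scalar_number(size, "size", 1)
  check_scalar_number(stride, "stride", 1)
  d <- dim(volume$data)
  span <- (count - 1L) * stride + size
  if (span > d[3]) {
    feasible <- if (size > d[3]) 0L else (d[3] - size) %/% stride + 1L
    stop_validation("requested ", count, " sub-volumes spanning ", span,
                    " slices but volume has ", d[3],
                    "; maximum feasible count is ", feasible)
  }
  if (size > d[1] || size > d[2]) {
    stop_validation("sub-volume side ", size, " exceeds the in-plane extent ",
                    d[1], "x", d[2])
  }
  ctr <- colMeans(which(foreground_mask(volume), arr.ind = TRUE))[1:2]
  y0 <- min(max(round(ctr[1] - (size - 1) / 2), 1L), d[1] - size + 1L)
  x0 <- min(max(round(ctr[2] - (size - 1) / 2), 1L), d[2] - size + 1L)
  z_first <- (d[3] - span) %/% 2L + 1L
  lapply(seq_len(count), function(i) {
    z0 <- z_first + (i - 1L) * stride
    subvolume(volume$data[y0:(y0 + size - 1L), x0:(x0 + size - 1L),
                          z0:(z0 + size - 1L), drop = FALSE],
              volume$voxel_size, content = content,
              origin = c(y0, x0, z0))
  })
}

#' Cross-sectional area from block-wise maximum-intensity projections
#'
#' Measures the tendon cross-sectional area over the central z-window of
#' physical extent `central_extent` (micrometers): the window is split
#' into non-overlapping blocks of `block` slices (remainder dropped);
#' each block is collapsed by a per-pixel maximum-intensity projection
#' along z to enhance the tissue outline; the projection is binarized by
#' Otsu's threshold, holes are filled, the largest connected component is
#' kept, and its pixel count is converted to mm^2. Block areas plus their
#' mean and sample SD are returned.
#'
#' @param volume a [volume_stack()].
#' @param block slices per MIP block (default 100).
#' @param central_extent physical z-extent of the analysis window, um
#'   (default 500); must cover at least one block.
#' @return an `area_profile`: data.frame of `block`, `z_start`, `z_end`,
#'   `area_mm2` with attributes `mean_mm2`, `sd_mm2`.
#' @export
cross_section_area <- function(volume, block = 100L, central_extent = 500) {
  stopifnot(inherits(volume, "volume_stack"))
  block <- as.integer(block)
  check_scalar_number(block, "block", 1)
  check_scalar_number(central_extent, "central_extent", 0, strict = TRUE)
  d <- dim(volume$data)
  nwin <- min(round(central_extent / volume$voxel_size), d[3])
  if (nwin < block) {
    stop_validation("central window of ", nwin, " slices (",
                    central_extent, " um at ", volume$voxel_size,
                    " um/voxel) is smaller than one block of ", block)
  }
  z0 <- (d[3] - nwin) %/% 2L + 1L
  nblocks <- nwin %/% block
  px_mm2 <- (volume$voxel_size * 1e-3)^2
  rows <- lapply(seq_len(nblocks), function(b) {
    zs <- z0 + (b - 1L) * block
    ze <- zs + block - 1L
    mip <- apply(volume$data[, , zs:ze, drop = FALSE], c(1, 2), max)
    thr <- tryCatch(otsu_thresholds(mip, k = 2L),
                    tomoqc_computation_error = function(e) {
                      stop_computation("empty foreground: ", conditionMessage(e))
                    })
    bin <- mip > thr
    if (!any(bin)) stop_computation("empty foreground after binarization")
    bin <- EBImage::fillHull(bin)
    lab <- EBImage::bwlabel(bin)
    tab <- tabulate(lab[lab > 0])
    keep <- which.max(tab)
    data.frame(block = b, z_start = zs, z_end = ze,
               area_mm2 = sum(lab == keep) * px_mm2)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_mm2") <- mean(out$area_mm2)
  attr(out, "sd_mm2") <- if (nrow(out) > 1) stats::sd(out$area_mm2) else 0
  attr(out, "block") <- block
  attr(out, "central_extent_um") <- central_extent
  class(out) <- c("area_profile", class(out))
  out
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("<area_profile> %d block(s) of %d slices: %.4g +/- %.3g mm^2\n",
              nrow(x), attr(x, "block"), attr(x, "mean_mm2"), attr(x, "sd_mm2")))
  print.data.frame(x, ...)
  invisible(x)
}
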