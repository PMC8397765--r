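#' Construct a volume stack
#'
#' The universal unit of analysis: a 3D gray-value array with an isotropic
#' voxel size. The array uses `[y, x, z]` axis order with the tendon
#' (fiber) axis along z, so `v$data[, , k]` is the k-th cross-sectional
#' slice. Gray values are abstract floats; any 16-bit export window is
#' applied only at I/O time.
#'
#' @param data 3D numeric array, dimensions `(ny, nx, nz)`.
#' @param voxel_size isotropic voxel size in micrometers (> 0).
#' @param meta optional named list of provenance metadata.
#' @return an object of class `volume_stack`.
#' @export
volume_stack <- function(data, voxel_size, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_validation("data must be a 3D array (ny, nx, nz)")
  }
  check_scalar_number(voxel_size, "voxel_size", min = 0, strict = TRUE)
  structure(
    list(data = data, voxel_size = voxel_size, meta = meta),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %d x %d x %d voxels @ %.3g um (%.3g x %.3g x %.3g um)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[2] * x$voxel_size, d[1] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  gray range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a volume as a multi-page TIFF with JSON sidecar
#'
#' One TIFF page per z-slice, 32-bit samples. Gray values are mapped into
#' `[0, 1]` through an affine export window `[window[1], window[2]]`
#' (default: the volume's min-max range) before writing; the window, the
#' voxel size and any metadata are stored in a JSON sidecar next to the
#' TIFF so that [read_volume()] restores physical gray values. The 32-bit
#' sample depth bounds the round-trip quantization error by
#' `diff(window) / 2^32`.
#'
#' @param volume a [volume_stack()].
#' @param path output TIFF path (`.tif`/`.tiff`); the sidecar replaces the
#'   extension with `.json`.
#' @param window length-2 numeric export window (gray units); values
#'   outside are clipped. Default: volume range (or `[0, 1]` for a
#'   constant volume).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, window = NULL) {
  stopifnot(inherits(volume, "volume_stack"))
  if (is.null(window)) {
    window <- range(volume$data)
    if (window[1] == window[2]) window <- window[1] + c(0, 1)
  }
  if (length(window) != 2L || !all(is.finite(window)) || window[2] <= window[1]) {
    stop_validation("window must be two finite increasing gray values")
  }
  d <- dim(volume$data)
  scaled <- pmin(pmax((volume$data - window[1]) / (window[2] - window[1]), 0), 1)
  pages <- lapply(seq_len(d[3L]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  side <- list(
    voxel_size_um = volume$voxel_size,
    window = as.numeric(window),
    shape = as.integer(d),
    meta = volume$meta
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF volume with its JSON sidecar
#'
#' Reads the stack written by [write_volume()] (or any multi-page TIFF with
#' uniform page shape), maps samples back through the sidecar's export
#' window to physical gray values, and attaches the voxel size. If no
#' sidecar exists, `voxel_size` must be supplied and samples are returned
#' as stored (window `[0, 1]`).
#'
#' @param path TIFF file path.
#' @param voxel_size voxel size in micrometers; required when no sidecar
#'   is present, otherwise taken from the sidecar.
#' @return a [volume_stack()].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop_validation(
                      "cannot read '", path, "' as TIFF: ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  shp <- lapply(pages, dim)
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L) {
    stop_validation("mixed page shapes in ", path)
  }
  if (length(shp[[1L]]) != 2L) stop_validation("pages must be single-channel 2D images")
  side_file <- sidecar_path(path)
  window <- c(0, 1)
  meta <- list()
  if (file.exists(side_file)) {
    side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
    voxel_size <- voxel_size %||% side$voxel_size_um
    if (!is.null(side$window)) window <- as.numeric(side$window)
    meta <- as.list(side$meta %||% list())
  }
  if (is.null(voxel_size)) {
    stop_validation("voxel size missing: no sidecar found for ", path,
                    " and voxel_size not supplied")
  }
  d <- c(shp[[1L]], length(pages))
  a <- array(0, d)
  for (k in seq_along(pages)) a[, , k] <- pages[[k]]
  a <- window[1] + a * (window[2] - window[1])
  volume_stack(a, voxel_size, meta = meta)
}
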