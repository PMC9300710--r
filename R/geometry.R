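#' Voxel geometry of an image stack
#'
#' Physical calibration shared by all raster types: lateral pixel pitch,
#' axial slice spacing and the acquisition bit depth. All physical
#' quantities downstream (patch sizes, neck lengths, FWHM profiles) are
#' derived from this object, never from pixel counts alone.
#'
#' @param dx Pixel size along image columns (micrometres/pixel).
#' @param dy Pixel size along image rows (micrometres/pixel); defaults to `dx`.
#' @param dz Slice spacing (micrometres/slice) or `NULL` for 2D data.
#' @param bit_depth Acquisition bit depth, one of 8, 12 or 16. 12-bit data
#'   is expected to live in 16-bit containers; the configured depth wins.
#' @return An object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(dx, dy = dx, dz = NULL, bit_depth = 16L) {
  stopifnot(is.numeric(dx), length(dx) == 1L, dx > 0,
            is.numeric(dy), length(dy) == 1L, dy > 0)
  if (!is.null(dz)) stopifnot(is.numeric(dz), length(dz) == 1L, dz > 0)
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("bit_depth must be one of 8, 12, 16")
  structure(list(dx = dx, dy = dy, dz = dz, bit_depth = as.integer(bit_depth)),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> dx = %g um, dy = %g um, dz = %s, %d-bit\n",
              x$dx, x$dy,
              if (is.null(x$dz)) "none (2D)" else sprintf("%g um", x$dz),
              x$bit_depth))
  invisible(x)
}

#' Z-stack of fluorescence intensities
#'
#' A single-time-point image volume (rows x cols x slices) with its
#' physical calibration. Intensities are non-negative and bounded by the
#' configured bit depth.
#'
#' @param data Numeric 3D array (M x N x Z) or a matrix (treated as Z = 1).
#' @param geometry A [voxel_geometry()].
#' @return An object of class `zstack` with fields `data` and `geometry`.
#' @export
zstack <- function(data, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[3] >= 1L)
  if (any(data < 0)) stop("zstack intensities must be non-negative")
  if (max(data) > 2^geometry$bit_depth - 1)
    stop(sprintf("intensity %g exceeds %d-bit range", max(data),
                 geometry$bit_depth))
  structure(list(data = data, geometry = geometry), class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<zstack> %d x %d x %d, range [%g, %g]\n", d[1], d[2], d[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Single-plane image
#'
#' @param data Numeric matrix of non-negative intensities.
#' @param geometry A [voxel_geometry()] (the `dz` component is unused).
#' @return An object of class `image2d`.
#' @export
image2d <- function(data, geometry) {
  stopifnot(is.matrix(data), inherits(geometry, "voxel_geometry"))
  if (any(data < 0)) stop("image intensities must be non-negative")
  structure(list(data = data, geometry = geometry), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d, range [%g, %g]\n", nrow(x$data),
              ncol(x$data), min(x$data), max(x$data)))
  invisible(x)
}

#' Time series of z-stacks
#'
#' Ordered acquisition of the same field of view over T time points. All
#' stacks must share lateral dimensions and geometry.
#'
#' @param stacks List of [zstack()] objects in acquisition order.
#' @param timestamps Optional numeric vector (acquisition index or minutes);
#'   defaults to `seq_along(stacks)`.
#' @return An object of class `spine_timeseries`.
#' @export
timeseries <- function(stacks, timestamps = seq_along(stacks)) {
  stopifnot(is.list(stacks), length(stacks) >= 1L,
            all(vapply(stacks, inherits, logical(1), "zstack")),
            length(timestamps) == length(stacks))
  dims <- vapply(stacks, function(s) dim(s$data)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all stacks must share M and N")
  structure(list(stacks = stacks, timestamps = as.numeric(timestamps)),
            class = "spine_timeseries")
}

#' @export
print.spine_timeseries <- function(x, ...) {
  d <- dim(x$stacks[[1]]$data)
  cat(sprintf("<spine_timeseries> T = %d, %d x %d x %d\n",
              length(x$stacks), d[1], d[2], d[3]))
  invisible(x)
}

#' @export
length.spine_timeseries <- function(x) length(x$stacks)
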