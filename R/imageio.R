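#' Load a time series of multi-page TIFF z-stacks
#'
#' Each time point is one multi-page grayscale TIFF. A directory is read in
#' lexicographic order; a character vector of files is read in the given
#' order (so a manifest can override lexicographic sorting).
#'
#' @param path_spec Directory containing one TIFF per time point, or a
#'   character vector of TIFF paths in acquisition order.
#' @param geometry A [voxel_geometry()]; its `bit_depth` overrides the
#'   container depth (12-bit data typically ships in 16-bit TIFFs).
#' @return A [timeseries()].
#' @export
load_timeseries <- function(path_spec, geometry) {
  files <- path_spec
  if (length(path_spec) == 1L && dir.exists(path_spec)) {
    files <- sort(list.files(path_spec, pattern = "\\.tiff?$",
                             ignore.case = TRUE, full.names = TRUE))
  }
  if (length(files) == 0L) stop("no TIFF files found in ", path_spec[1])
  stacks <- lapply(files, function(f) {
    if (!file.exists(f)) stop("missing input file: ", f)
    pages <- tryCatch(tiff::readTIFF(f, all = TRUE, as.is = TRUE),
                      error = function(e) stop("cannot read TIFF ", f, ": ",
                                               conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (z in seq_along(pages)) {
      pg <- pages[[z]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # first channel
      arr[, , z] <- pg
    }
    zstack(arr, geometry)
  })
  dims <- vapply(stacks, function(s) dim(s$data)[1:2], integer(2))
  if (any(dims != dims[, 1]))
    stop("inconsistent stack dimensions across time points")
  timeseries(stacks)
}

#' Write a z-stack as a multi-page 16-bit TIFF
#'
#' Integer intensities are stored losslessly; the read-back via
#' [load_timeseries()] is bit-exact for 8/12/16-bit data.
#'
#' @param stack A [zstack()] or a numeric matrix/array.
#' @param file Output path.
#' @export
save_zstack <- function(stack, file) {
  arr <- if (inherits(stack, "zstack")) stack$data else stack
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(z) round(arr[, , z]) / 65535)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  invisible(file)
}

#' Maximum intensity projection
#'
#' Collapses a z-stack to 2D by taking the per-pixel maximum across slices.
#'
#' @param stack A [zstack()].
#' @return An [image2d()].
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$data)
  if (any(d == 0L)) stop("empty stack")
  mip <- apply(stack$data, c(1, 2), max)
  image2d(mip, stack$geometry)
}

#' 2D median filter with edge replication
#'
#' Each pixel is replaced by the exact median of its `window` x `window`
#' neighbourhood; the image border is replicated so that edge statistics do
#' not acquire a dark halo (which would bias Otsu thresholds downstream).
#'
#' @param image An [image2d()] or numeric matrix.
#' @param window Odd window side in pixels; `window = 1` is the identity.
#' @return Same type as the input.
#' @export
median_filter2d <- function(image, window = 3L) {
  img <- if (inherits(image, "image2d")) image$data else image
  stopifnot(is.matrix(img))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1")
  if (window == 1L) return(image)
  r <- (window - 1L) %/% 2L
  padded <- replicate_pad(img, r)
  n <- nrow(img) * ncol(img)
  k <- window * window
  cols <- matrix(0, n, k)
  idx <- 1L
  for (dj in 0:(window - 1L)) {
    for (di in 0:(window - 1L)) {
      cols[, idx] <- padded[di + seq_len(nrow(img)), dj + seq_len(ncol(img))]
      idx <- idx + 1L
    }
  }
  med <- row_median_smallk(cols)
  out <- matrix(med, nrow(img), ncol(img))
  if (inherits(image, "image2d")) image2d(out, image$geometry) else out
}

#' Default median-filter window for a given sampling
#'
#' Coarser than 0.03 um/px gets a 3 px window; finer sampling (where the
#' PSF spans many pixels) gets 5 px. Overridable per run.
#'
#' @param geometry A [voxel_geometry()].
#' @return Odd integer window side.
#' @export
default_median_window <- function(geometry) {
  if (min(geometry$dx, geometry$dy) >= 0.03) 3L else 5L
}

# pad a matrix by r pixels on each side, replicating the edge values
replicate_pad <- function(img, r) {
  ri <- c(rep(1L, r), seq_len(nrow(img)), rep(nrow(img), r))
  ci <- c(rep(1L, r), seq_len(ncol(img)), rep(ncol(img), r))
  img[ri, ci]
}

# exact row-wise median for a small fixed number of columns via odd-even
# transposition sort (vectorised compare-swaps; no per-row sort calls)
row_median_smallk <- function(cols) {
  k <- ncol(cols)
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    j <- start
    while (j + 1L <= k) {
      lo <- pmin(cols[, j], cols[, j + 1L])
      hi <- pmax(cols[, j], cols[, j + 1L])
      cols[, j] <- lo
      cols[, j + 1L] <- hi
      j <- j + 2L
    }
  }
  cols[, (k + 1L) %/% 2L]
}
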