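#' Otsu threshold of an image
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' spanning the observed intensity range. Because the histogram is built on
#' the data range, the threshold is covariant with affine intensity changes
#' (up to one bin width) -- the property that makes downstream segmentation
#' insensitive to imaging laser power.
#'
#' @param image An [image2d()] or numeric matrix.
#' @return Threshold on the intensity scale of the input.
#' @export
otsu_threshold <- function(image) {
  img <- if (inherits(image, "image2d")) image$data else image
  lo <- min(img)
  hi <- max(img)
  if (hi <= lo) stop("degenerate input: constant image has no Otsu threshold")
  x <- EBImage::Image((img - lo) / (hi - lo))
  th <- EBImage::otsu(x, range = c(0, 1), levels = 256L)
  lo + th * (hi - lo)
}

# strip the EBImage S4 wrapper back to a plain matrix/array
ebi_mat <- function(x) EBImage::imageData(x)

# largest 8-connected foreground component of a logical matrix
largest_component <- function(mask, report_ties = FALSE) {
  lab <- ebi_mat(EBImage::bwlabel(mask))
  if (max(lab) == 0L) stop("no foreground component")
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes == max(sizes))
  if (report_ties && length(big) > 1L)
    stop(sprintf("ambiguous: %d equally large components (sizes %d)",
                 length(big), max(sizes)))
  lab == big[1]
}

# Euclidean distance transform (distance to background, pixels)
distance_transform <- function(mask) {
  ebi_mat(EBImage::distmap(EBImage::Image(mask * 1)))
}

# Dice coefficient of two logical masks
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# bilinear interpolation of matrix img at fractional (row, col) positions
interp_bilinear <- function(img, r, c) {
  nr <- nrow(img)
  nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

# trilinear interpolation of 3D array vol at fractional (r, c, z)
interp_trilinear <- function(vol, r, c, z) {
  d <- dim(vol)
  if (any(r < 0.5 | r > d[1] + 0.5 | c < 0.5 | c > d[2] + 0.5 |
          z < 0.5 | z > d[3] + 0.5))
    stop("sample point outside volume")
  r <- pmin(pmax(r, 1), d[1])
  c <- pmin(pmax(c, 1), d[2])
  z <- pmin(pmax(z, 1), d[3])
  r0 <- pmin(floor(r), max(d[1] - 1L, 1L))
  c0 <- pmin(floor(c), max(d[2] - 1L, 1L))
  z0 <- pmin(floor(z), max(d[3] - 1L, 1L))
  fr <- r - r0
  fc <- c - c0
  fz <- z - z0
  r1 <- pmin(r0 + 1, d[1])
  c1 <- pmin(c0 + 1, d[2])
  z1 <- pmin(z0 + 1, d[3])
  v <- vol[cbind(r0, c0, z0)] * (1 - fr) * (1 - fc) * (1 - fz) +
    vol[cbind(r1, c0, z0)] * fr * (1 - fc) * (1 - fz) +
    vol[cbind(r0, c1, z0)] * (1 - fr) * fc * (1 - fz) +
    vol[cbind(r1, c1, z0)] * fr * fc * (1 - fz) +
    vol[cbind(r0, c0, z1)] * (1 - fr) * (1 - fc) * fz +
    vol[cbind(r1, c0, z1)] * fr * (1 - fc) * fz +
    vol[cbind(r0, c1, z1)] * (1 - fr) * fc * fz +
    vol[cbind(r1, c1, z1)] * fr * fc * fz
  v
}

# separable Gaussian blur of a 3D array; sigma per axis in voxels,
# edge-replicated borders
gaussian_blur3d <- function(vol, sigma) {
  d <- dim(vol)
  blur_axis <- function(v, axis, s) {
    if (s <= 0) return(v)
    half <- max(1L, ceiling(3 * s))
    kern <- dnorm(seq(-half, half), sd = s)
    kern <- kern / sum(kern)
    n <- dim(v)[axis]
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- array(0, dim(v))
    for (o in seq(-half, half)) {
      w <- kern[o + half + 1L]
      sel <- idx(seq_len(n) + o)
      out <- out + w * switch(axis,
                              v[sel, , , drop = FALSE],
                              v[, sel, , drop = FALSE],
                              v[, , sel, drop = FALSE])
    }
    out
  }
  v <- blur_axis(vol, 1L, sigma[1])
  v <- blur_axis(v, 2L, sigma[2])
  if (length(d) == 3L && d[3] > 1L && length(sigma) >= 3L)
    v <- blur_axis(v, 3L, sigma[3])
  v
}

# h-maxima transform: grayscale reconstruction of (img - h) under img,
# returning the reconstructed image (domes of height > h survive)
hmaxima_reconstruct <- function(img, h) {
  marker <- img - h
  kern <- EBImage::makeBrush(3L, "box")
  repeat {
    grown <- pmin(ebi_mat(EBImage::dilate(EBImage::Image(marker), kern)),
                  img)
    if (max(abs(grown - marker)) < 1e-12) break
    marker <- grown
  }
  marker
}

# labelled regional-maxima regions of the h-maxima transform: connected
# plateaus strictly above every outside neighbour
hmaxima_regions <- function(img, h) {
  recon <- hmaxima_reconstruct(img, h)
  kern <- EBImage::makeBrush(3L, "box")
  locmax <- ebi_mat(EBImage::dilate(EBImage::Image(recon), kern)) <=
    recon + 1e-12
  lab <- ebi_mat(EBImage::bwlabel(locmax))
  out <- matrix(0L, nrow(img), ncol(img))
  newl <- 0L
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    if (all(comp)) next  # whole image flat: no maximum
    v <- max(recon[comp])
    ring <- ebi_mat(EBImage::dilate(EBImage::Image(comp * 1), kern)) >
      0.5 & !comp
    if (any(ring) && max(recon[ring]) >= v - 1e-9) next  # not a summit
    newl <- newl + 1L
    out[comp] <- newl
  }
  out
}

#' Multi-stencil fast-marching arrival times
#'
#' Solves the eikonal equation |grad T| = 1/speed on a 2D or 3D grid with
#' second-order upwind differences over axis and diagonal stencils. The
#' neighbourhood of the source is initialised analytically where the
#' medium is locally homogeneous.
#'
#' @param speed Non-negative 2D matrix or 3D array of propagation speeds.
#' @param source Integer voxel `(row, col)` or `(row, col, slice)`, 1-based.
#' @param spacing Physical spacing per axis (same length as `dim(speed)`).
#' @param second_order Use second-order differences (default) or first.
#' @return Array of arrival times, same shape as `speed`.
#' @export
msfm_distance <- function(speed, source, spacing = rep(1, length(dim(speed))),
                          second_order = TRUE) {
  d <- dim(speed)
  stopifnot(length(d) %in% c(2L, 3L), length(spacing) == length(d))
  src <- matrix(as.integer(source) - 1L, nrow = 1)
  if (any(src < 0L) || any(src >= d)) stop("source outside volume")
  T <- .msfm_cpp(as.numeric(speed), as.integer(d), as.numeric(spacing), src,
                 second_order)
  array(T, d)
}
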