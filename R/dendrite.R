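#' Segment the dendritic shaft and extract its medial axis
#'
#' Median filter, Otsu binarization and largest-component selection give a
#' rough branch mask including spines. The medial axis is the fast-marching
#' geodesic between the two farthest foreground points, traced along the
#' ridge of the distance transform. A locally adaptive disk (radius = the
#' distance-transform value at each axis point, clamped to the median
#' radius +/- `clamp_frac`) is swept along the axis; the union of disks is
#' the shaft mask, which excludes the attached spines. The median shaft
#' intensity recorded here is the IFI normalizer.
#'
#' @param mip An [image2d()] (maximum intensity projection).
#' @param median_window Median filter window (odd px); default from
#'   [default_median_window()].
#' @param clamp_frac Radius clamp as a fraction of the median radius.
#' @param min_span_frac Minimum fraction of the image diagonal the branch
#'   must span.
#' @return An object of class `dendrite_mask` with fields `mask`,
#'   `medial_axis` (data.frame s, row, col, radius_px), `local_radius`,
#'   `median_intensity`, `otsu_threshold`.
#' @export
segment_dendrite <- function(mip, median_window = NULL, clamp_frac = 0.25,
                             min_span_frac = 0.25) {
  stopifnot(inherits(mip, "image2d"))
  if (is.null(median_window))
    median_window <- default_median_window(mip$geometry)
  filt <- median_filter2d(mip, median_window)$data
  th <- otsu_threshold(filt)
  fg <- filt > th
  if (!any(fg)) stop("no foreground after Otsu thresholding")
  lab <- ebi_mat(EBImage::bwlabel(fg))
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    # prefer the component containing (or nearest) the image center
    ctr <- round(dim(filt) / 2)
    pick <- NA_integer_
    for (b in big) {
      px <- which(lab == b, arr.ind = TRUE)
      if (any(px[, 1] == ctr[1] & px[, 2] == ctr[2])) pick <- b
    }
    if (is.na(pick))
      stop(sprintf("ambiguous: %d equally large components (labels %s)",
                   length(big), paste(big, collapse = ", ")))
    big <- pick
  }
  mask <- lab == big[1]
  bb <- which(mask, arr.ind = TRUE)
  span <- sqrt(diff(range(bb[, 1]))^2 + diff(range(bb[, 2]))^2)
  diag_len <- sqrt(sum(dim(filt)^2))
  if (span < min_span_frac * diag_len)
    stop("largest component does not span enough of the field of view ",
         "to be a dendrite")
  axis_df <- medial_axis_path(mask)
  dt <- distance_transform(mask)
  radii <- interp_bilinear(dt, axis_df$row, axis_df$col)
  med_r <- stats::median(radii)
  radii_cl <- pmin(pmax(radii, med_r * (1 - clamp_frac)),
                   med_r * (1 + clamp_frac))
  shaft <- matrix(FALSE, nrow(filt), ncol(filt))
  for (i in seq_len(nrow(axis_df))) {
    shaft <- shaft | disc_mask(nrow(filt), ncol(filt), axis_df$row[i],
                               axis_df$col[i], radii_cl[i])
  }
  shaft <- shaft & fg
  axis_df$radius_px <- radii_cl
  structure(list(mask = shaft, medial_axis = axis_df,
                 local_radius = radii_cl,
                 median_intensity = stats::median(mip$data[shaft]),
                 otsu_threshold = th),
            class = "dendrite_mask")
}

#' @export
print.dendrite_mask <- function(x, ...) {
  cat(sprintf(
    "<dendrite_mask> %d px shaft, axis %d pts, median intensity %.1f\n",
    sum(x$mask), nrow(x$medial_axis), x$median_intensity))
  invisible(x)
}

# geodesic medial axis of a binary mask: farthest-pair endpoints by two
# marching passes, then a ridge-following geodesic on a centredness speed
medial_axis_path <- function(mask) {
  eps <- 1e-3
  speed_flat <- mask * 1 + eps
  start <- which(mask, arr.ind = TRUE)[1, ]
  T1 <- msfm_distance(speed_flat, start)
  p1 <- which(mask & is.finite(T1), arr.ind = TRUE)
  p1 <- p1[which.max(T1[p1]), ]
  T2 <- msfm_distance(speed_flat, p1)
  p2 <- which(mask & is.finite(T2), arr.ind = TRUE)
  p2 <- p2[which.max(T2[p2]), ]
  # ridge speed: marching is fastest along the center of the tube
  dt <- distance_transform(mask)
  speed <- (dt / max(dt))^2
  speed[speed < eps] <- eps
  Tc <- msfm_distance(speed, p1)
  path <- trace_descent(Tc, p2, source = p1, step = 0.5)
  path <- resample_path(path, 1.0)
  data.frame(s = seq_len(nrow(path)), row = path[, 1], col = path[, 2])
}

# Runge-Kutta (4th order) descent on an arrival-time map from `start`
# toward the source; works on 2D matrices and 3D arrays
trace_descent <- function(tmap, start, source, step = 0.25,
                          max_steps = 20000L) {
  d2 <- is.matrix(tmap)
  if (d2) {
    dim(tmap) <- c(dim(tmap), 1L)
    start <- c(start, 1)
    source <- c(source, 1)
  }
  dims <- dim(tmap)
  big <- max(tmap[is.finite(tmap)])
  tmap[!is.finite(tmap)] <- big * 2
  grad_at <- function(p) {
    g <- numeric(3)
    for (ax in 1:3) {
      if (dims[ax] == 1L) next
      e <- c(0, 0, 0)
      e[ax] <- 1
      hi <- pmin(pmax(p + e, 1), dims)
      lo <- pmin(pmax(p - e, 1), dims)
      g[ax] <- (interp_trilinear(tmap, hi[1], hi[2], hi[3]) -
                  interp_trilinear(tmap, lo[1], lo[2], lo[3])) /
        max(hi[ax] - lo[ax], 1e-9)
    }
    g
  }
  unit <- function(g) {
    n <- sqrt(sum(g^2))
    if (n < 1e-12) return(NULL)
    g / n
  }
  # discrete steepest-descent step used when the interpolated gradient
  # stalls (narrow channels, staircase minima)
  voxel_descent <- function(p) {
    pi0 <- round(pmin(pmax(p, 1), dims))
    best <- NULL
    bestv <- tmap[pi0[1], pi0[2], pi0[3]]
    for (dk in (if (dims[3] > 1) -1:1 else 0)) for (dj in -1:1)
      for (di in -1:1) {
        q <- pi0 + c(di, dj, dk)
        if (any(q < 1) || any(q > dims)) next
        if (tmap[q[1], q[2], q[3]] < bestv) {
          bestv <- tmap[q[1], q[2], q[3]]
          best <- q
        }
      }
    best
  }
  p <- as.numeric(start)
  path <- list(p)
  ok <- TRUE
  for (it in seq_len(max_steps)) {
    if (sqrt(sum((p - source)^2)) <= 1) break
    k1 <- unit(grad_at(p))
    moved <- FALSE
    if (!is.null(k1)) {
      k2 <- unit(grad_at(pmin(pmax(p - step / 2 * k1, 1), dims)))
      k3 <- if (!is.null(k2))
        unit(grad_at(pmin(pmax(p - step / 2 * k2, 1), dims))) else NULL
      k4 <- if (!is.null(k3))
        unit(grad_at(pmin(pmax(p - step * k3, 1), dims))) else NULL
      dir <- if (!is.null(k4)) (k1 + 2 * k2 + 2 * k3 + k4) / 6 else k1
      dir <- unit(dir)
      if (!is.null(dir)) {
        pn <- pmin(pmax(p - step * dir, 1), dims)
        tn <- interp_trilinear(tmap, pn[1], pn[2], pn[3])
        tp <- interp_trilinear(tmap, p[1], p[2], p[3])
        if (tn < tp - 1e-12) {
          p <- pn
          moved <- TRUE
        }
      }
    }
    if (!moved) {
      q <- voxel_descent(p)
      if (is.null(q)) { ok <- FALSE; break }
      p <- as.numeric(q)
    }
    path[[length(path) + 1L]] <- p
    if (it == max_steps) ok <- FALSE
  }
  reached <- sqrt(sum((p - source)^2)) <= 1.5
  pathm <- do.call(rbind, path)
  pathm <- rbind(pathm, source)
  if (d2) pathm <- pathm[, 1:2, drop = FALSE]
  attr(pathm, "reached") <- reached && ok || reached
  pathm
}

# resample a polyline (rows = points) at uniform arclength steps (in the
# same coordinate units as the points)
resample_path <- function(points, step = 0.5) {
  if (nrow(points) < 2L) return(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-12)  # drop duplicated vertices
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) return(points)
  seg <- seg[seg > 1e-12]
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(points[1, , drop = FALSE])
  ss <- unique(c(seq(0, total, by = step), total))
  out <- matrix(0, length(ss), ncol(points))
  for (j in seq_len(ncol(points)))
    out[, j] <- stats::approx(s, points[, j], xout = ss)$y
  out
}

#' Grow or shrink a segmentation boundary
#'
#' Intensity-guided curve evolution: each iteration moves the boundary one
#' pixel outward (positive `iterations`) or inward (negative), preferring
#' pixels on the right side of a fixed intensity gate (the Otsu threshold
#' of the guiding image) so the contour locks onto the intensity edge;
#' where the gate stalls, the full morphological ring moves, so repeated
#' growth and shrinkage stay near-inverse on smooth shapes.
#'
#' @param mask Logical matrix (non-empty).
#' @param iterations Signed integer: > 0 grows, < 0 shrinks, 0 is identity.
#' @param image [image2d()] or matrix guiding the evolution.
#' @return Logical matrix, a single connected component.
#' @export
adjust_boundary <- function(mask, iterations, image) {
  img <- if (inherits(image, "image2d")) image$data else image
  stopifnot(is.matrix(img), any(mask))
  it <- as.integer(iterations)
  if (it == 0L) return(mask)
  thr <- tryCatch(otsu_threshold(img), error = function(e) stats::median(img))
  kern <- EBImage::makeBrush(3L, "disc")
  for (i in seq_len(abs(it))) {
    if (it > 0L) {
      ring <- ebi_mat(EBImage::dilate(EBImage::Image(mask * 1), kern)) >
        0.5 & !mask
      add <- ring & img >= thr
      if (!any(add)) add <- ring  # past the edge: balloon outward
      mask <- mask | add
    } else {
      er <- ebi_mat(EBImage::erode(EBImage::Image(mask * 1), kern)) > 0.5
      ring <- mask & !er
      if (!any(ring)) ring <- mask  # single-pixel-thin mask
      drop <- ring & img < thr
      if (!any(drop)) drop <- ring  # inside the edge: deflate inward
      cand <- mask & !drop
      if (!any(cand)) stop("contract violation: mask shrank to empty")
      mask <- cand
    }
    lab <- ebi_mat(EBImage::bwlabel(mask))
    if (max(lab) > 1L) {
      sizes <- tabulate(lab[lab > 0])
      mask <- lab == which.max(sizes)
    }
  }
  if (!any(mask)) stop("contract violation: mask shrank to empty")
  mask
}
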