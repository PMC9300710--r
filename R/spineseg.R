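#' Seed regions for spine-head watershed
#'
#' Regional maxima of the h-maxima transform of the ROI (domes of
#' prominence greater than `h`), united with a one-pixel seed at the
#' detected spine center so every detection yields at least one seed.
#'
#' @param roi Numeric matrix or [image2d()] (ROI around the spine).
#' @param detected_center `(row, col)` within the ROI.
#' @param h Prominence threshold; default 10% of the ROI dynamic range.
#' @return Integer label matrix of seed regions (>= 1 region).
#' @export
find_seeds <- function(roi, detected_center, h = NULL) {
  img <- if (inherits(roi, "image2d")) roi$data else roi
  rng <- max(img) - min(img)
  if (is.null(h)) h <- 0.1 * rng
  labels <- if (rng > 0) hmaxima_regions(img, h) else
    matrix(0L, nrow(img), ncol(img))
  ctr <- pmin(pmax(round(detected_center), 1L), dim(img))
  if (labels[ctr[1], ctr[2]] == 0L) {
    labels[ctr[1], ctr[2]] <- max(labels) + 1L
  }
  labels
}

#' Seeded watershed segmentation of a spine ROI
#'
#' Region growing from the seed regions on the intensity relief, restricted
#' to a boundary mask. The boundary is the Otsu foreground of the ROI; when
#' the spine is entirely below the Otsu threshold (dim spine), a circular
#' mock boundary around the detected center replaces it.
#'
#' @param roi Numeric matrix or [image2d()].
#' @param seeds Label matrix from [find_seeds()].
#' @param detected_center `(row, col)` used for the mock fallback.
#' @param boundary Optional logical matrix; default Otsu foreground.
#' @param mock_radius_um Radius of the mock boundary (micrometres).
#' @param geometry [voxel_geometry()] used to convert the mock radius;
#'   required if `roi` is a bare matrix and the fallback triggers.
#' @return List: `labels` (watershed regions), `boundary`, `provenance`
#'   (`"otsu"` or `"mock-boundary"`).
#' @export
watershed_segment <- function(roi, seeds, detected_center, boundary = NULL,
                              mock_radius_um = 0.6, geometry = NULL) {
  img <- if (inherits(roi, "image2d")) roi$data else roi
  if (inherits(roi, "image2d")) geometry <- roi$geometry
  provenance <- "otsu"
  ctr <- pmin(pmax(round(detected_center), 1L), dim(img))
  if (is.null(boundary)) {
    th <- tryCatch(otsu_threshold(img), error = function(e) Inf)
    boundary <- img > th
    seed_px <- seeds > 0L
    if (!any(boundary & seed_px) || !boundary[ctr[1], ctr[2]]) {
      if (is.null(geometry))
        stop("geometry needed for the mock-boundary fallback")
      rad_px <- mock_radius_um / geometry$dx
      boundary <- disc_mask(nrow(img), ncol(img), ctr[1], ctr[2], rad_px)
      provenance <- "mock-boundary"
    }
  }
  if (!boundary[ctr[1], ctr[2]])
    stop("contract violation: seed outside boundary after mock fallback")
  labels <- ebi_mat(EBImage::propagate(EBImage::Image(img / max(img, 1)),
                                         seeds, mask = boundary))
  storage.mode(labels) <- "integer"
  list(labels = labels, boundary = boundary, provenance = provenance)
}

#' Refine a watershed region into the final spine-head mask
#'
#' Pixels of the region are clustered on standardized (intensity, geodesic
#' distance to seed) features: connectivity-aware over-clustering is merged
#' hierarchically to at most ten quasi-concentric clusters, ranked by mean
#' geodesic distance from the seed. Clusters are accumulated inward-out
#' until the mean intensity first drops below fraction `f` of the seed
#' cluster's mean; the mask is the connected component of that union
#' containing the seed (never empty: the innermost cluster is the
#' fallback).
#'
#' @param roi Numeric matrix or [image2d()].
#' @param region Logical matrix from the watershed stage.
#' @param seed `(row, col)` inside the region.
#' @param f Intensity-drop fraction.
#' @param n_clusters Maximum merged cluster count.
#' @param timepoint Stamped on the result.
#' @return An object of class `spine_head_mask`: `mask`, `seed`, `area_px`,
#'   `timepoint`, `provenance`.
#' @export
refine_segmentation <- function(roi, region, seed, f = 0.5,
                                n_clusters = 10L, timepoint = 1L) {
  img <- if (inherits(roi, "image2d")) roi$data else roi
  seed <- pmin(pmax(round(seed), 1L), dim(img))
  stopifnot(any(region))
  if (!region[seed[1], seed[2]])
    stop("seed must lie inside the region")
  px <- which(region, arr.ind = TRUE)
  n <- nrow(px)
  if (n <= 4L) {
    return(new_spine_head_mask(region, seed, timepoint, "watershed+refined"))
  }
  # geodesic distance from seed inside the region
  speed <- region * 1 + 1e-6
  gd <- msfm_distance(speed, seed)
  gdv <- gd[px]
  gdv[!is.finite(gdv)] <- max(gdv[is.finite(gdv)]) + 1
  iv <- img[px]
  feat <- cbind(scale_unit(iv), scale_unit(gdv))
  k0 <- min(30L, n - 1L, length(unique(round(feat[, 1] * 1e6))))
  k0 <- max(k0, 2L)
  cl <- stats::cutree(stats::hclust(stats::dist(feat), method = "ward.D2"),
                      k = min(k0, n))
  # merge to <= n_clusters on cluster centroids
  cent <- stats::aggregate(feat, by = list(cl = cl), FUN = mean)
  kf <- min(n_clusters, nrow(cent))
  merge_cl <- stats::cutree(stats::hclust(stats::dist(cent[, -1]),
                                          method = "ward.D2"), k = kf)
  cl <- merge_cl[match(cl, cent$cl)]
  # rank clusters by mean geodesic distance from the seed
  mean_d <- tapply(gdv, cl, mean)
  mean_i <- tapply(iv, cl, mean)
  ord <- order(mean_d)
  seed_mean <- mean_i[ord[1]]
  keep <- ord[1]
  for (j in seq_along(ord)[-1]) {
    if (mean_i[ord[j]] < f * seed_mean) break
    keep <- c(keep, ord[j])
  }
  mask <- matrix(FALSE, nrow(img), ncol(img))
  mask[px[cl %in% as.integer(names(mean_d))[keep], , drop = FALSE]] <- TRUE
  mask[seed[1], seed[2]] <- TRUE
  # connected component containing the seed
  lab <- ebi_mat(EBImage::bwlabel(mask))
  mask <- lab == lab[seed[1], seed[2]]
  if (!any(mask)) {  # fallback: innermost cluster
    mask <- matrix(FALSE, nrow(img), ncol(img))
    mask[px[cl == as.integer(names(mean_d))[ord[1]], , drop = FALSE]] <- TRUE
    mask[seed[1], seed[2]] <- TRUE
  }
  new_spine_head_mask(mask & region | seed_only(mask, seed), seed, timepoint,
                      "watershed+refined")
}

seed_only <- function(mask, seed) {
  m <- matrix(FALSE, nrow(mask), ncol(mask))
  m[seed[1], seed[2]] <- TRUE
  m
}

scale_unit <- function(x) {
  s <- stats::sd(x)
  if (s > 0) (x - mean(x)) / s else x * 0
}

new_spine_head_mask <- function(mask, seed, timepoint, provenance) {
  structure(list(mask = mask, seed = as.integer(seed),
                 area_px = sum(mask), timepoint = as.integer(timepoint),
                 provenance = provenance),
            class = "spine_head_mask")
}

#' @export
print.spine_head_mask <- function(x, ...) {
  cat(sprintf("<spine_head_mask> t=%d, %d px, %s\n", x$timepoint, x$area_px,
              x$provenance))
  invisible(x)
}

#' Segment one spine head in a single frame
#'
#' Seeds, seeded watershed with Otsu/mock boundary, and cluster refinement,
#' returned as a full-frame mask cropped computation inside an ROI window.
#'
#' @param frame [image2d()] full frame.
#' @param center `(row, col)` spine center in frame coordinates.
#' @param half_size ROI half side (pixels).
#' @param h,f,mock_radius_um Stage parameters (see the stage functions).
#' @param timepoint Stamped on the result.
#' @return A `spine_head_mask` whose `mask` is full-frame; `roi_origin`
#'   records the ROI offset, `provenance` the boundary source.
#' @export
segment_spine_frame <- function(frame, center, half_size = 30L, h = NULL,
                                f = 0.5, mock_radius_um = 0.6,
                                timepoint = 1L) {
  win <- roi_window(center, half_size, timepoint)
  roi <- crop_roi(frame, win)
  r0 <- clamp_center(win$center[1], half_size, nrow(frame$data)) - half_size
  c0 <- clamp_center(win$center[2], half_size, ncol(frame$data)) - half_size
  ctr_roi <- c(center[1] - r0 + 1L, center[2] - c0 + 1L)
  ctr_roi <- pmin(pmax(round(ctr_roi), 1L), dim(roi))
  seeds <- find_seeds(roi, ctr_roi, h)
  ws <- watershed_segment(roi, seeds, ctr_roi, geometry = frame$geometry,
                          mock_radius_um = mock_radius_um)
  lab_at_ctr <- ws$labels[ctr_roi[1], ctr_roi[2]]
  if (lab_at_ctr == 0L) {
    # center fell outside the boundary: take the region of the nearest seed
    cand <- which(ws$labels > 0L, arr.ind = TRUE)
    d2 <- (cand[, 1] - ctr_roi[1])^2 + (cand[, 2] - ctr_roi[2])^2
    lab_at_ctr <- ws$labels[cand[which.min(d2), , drop = FALSE]]
  }
  region <- ws$labels == lab_at_ctr
  seed_px <- which(region, arr.ind = TRUE)
  seed_in <- if (region[ctr_roi[1], ctr_roi[2]]) ctr_roi else
    seed_px[which.max(roi[seed_px]), ]
  ref <- refine_segmentation(roi, region, seed_in, f = f,
                             timepoint = timepoint)
  full <- matrix(FALSE, nrow(frame$data), ncol(frame$data))
  full[r0 + seq_len(nrow(roi)) - 1L, c0 + seq_len(ncol(roi)) - 1L] <- ref$mask
  out <- new_spine_head_mask(full, c(seed_in[1] + r0 - 1L,
                                     seed_in[2] + c0 - 1L),
                             timepoint, ws$provenance)
  out$roi_origin <- c(r0, c0)
  wfull <- matrix(FALSE, nrow(frame$data), ncol(frame$data))
  wfull[r0 + seq_len(nrow(roi)) - 1L, c0 + seq_len(ncol(roi)) - 1L] <- region
  out$watershed_mask <- wfull
  out
}

#' Segment one spine across a registered time series
#'
#' The ROI is re-centered at every time point by NMI local registration
#' against the previous time point's ROI, then segmented. When the best NMI
#' falls below `nmi_floor` the spine is flagged missing for that time point
#' and the previous center is kept.
#'
#' @param series A registered [timeseries()].
#' @param spine_center `(row, col)` at the first time point.
#' @param half_size ROI half side (pixels).
#' @param search_radius Local-registration search radius (pixels).
#' @param nmi_floor Minimum acceptable NMI.
#' @param ... Passed to [segment_spine_frame()].
#' @return List of `spine_head_mask` (one per time point; missing ones
#'   carry a `"missing"` provenance and empty mask).
#' @export
segment_spine_timeseries <- function(series, spine_center, half_size = 30L,
                                     search_radius = 10L, nmi_floor = 1.02,
                                     ...) {
  stopifnot(inherits(series, "spine_timeseries"))
  mips <- lapply(series$stacks, max_intensity_projection)
  out <- vector("list", length(series))
  center <- round(spine_center)
  prev_roi <- NULL
  for (t in seq_along(series$stacks)) {
    frame <- mips[[t]]
    if (t > 1L) {
      win <- roi_window(center, half_size, t)
      win2 <- local_register_roi(prev_roi, frame, win, search_radius)
      if (attr(win2, "nmi") < nmi_floor) {
        out[[t]] <- new_spine_head_mask(
          matrix(FALSE, nrow(frame$data), ncol(frame$data)), center, t,
          "missing")
        prev_roi <- crop_roi(frame, win)
        next
      }
      center <- win2$center
    }
    out[[t]] <- segment_spine_frame(frame, center, half_size,
                                    timepoint = t, ...)
    prev_roi <- crop_roi(frame, roi_window(center, half_size, t))
  }
  out
}
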