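#' Scale-space interest points (determinant of Hessian)
#'
#' Candidate spine locations: local maxima of the scale-normalized
#' determinant-of-Hessian response over a small scale pyramid, restricted
#' to bright blobs (negative Laplacian). The image is normalized to its
#' own range first, so the response threshold is invariant to intensity
#' scale.
#'
#' @param mip An [image2d()] or matrix.
#' @param threshold Minimum normalized response.
#' @param sigmas Scale sigmas in pixels; default spans typical spine-head
#'   radii (0.15-0.6 um) for the image geometry when available.
#' @return data.frame `(row, col, scale, response)` sorted by descending
#'   response (empty for a constant image).
#' @export
detect_interest_points <- function(mip, threshold = 5e-4, sigmas = NULL) {
  img <- if (inherits(mip, "image2d")) mip$data else mip
  rng <- max(img) - min(img)
  if (rng <= 0)
    return(data.frame(row = integer(0), col = integer(0),
                      scale = numeric(0), response = numeric(0)))
  if (is.null(sigmas)) {
    dx <- if (inherits(mip, "image2d")) mip$geometry$dx else 0.072
    radii <- c(0.15, 0.25, 0.4, 0.6)
    sigmas <- pmax(radii / sqrt(2) / dx, 1)
  }
  x <- (img - min(img)) / rng
  n1 <- nrow(x)
  n2 <- ncol(x)
  resp <- array(-Inf, c(n1, n2, length(sigmas)))
  for (s in seq_along(sigmas)) {
    sg <- sigmas[s]
    G <- ebi_mat(EBImage::gblur(EBImage::Image(x), sigma = sg))
    Lxx <- G * 0
    Lyy <- G * 0
    Lxy <- G * 0
    Lyy[2:(n1 - 1), ] <- G[3:n1, ] - 2 * G[2:(n1 - 1), ] + G[1:(n1 - 2), ]
    Lxx[, 2:(n2 - 1)] <- G[, 3:n2] - 2 * G[, 2:(n2 - 1)] + G[, 1:(n2 - 2)]
    Lxy[2:(n1 - 1), 2:(n2 - 1)] <-
      (G[3:n1, 3:n2] - G[3:n1, 1:(n2 - 2)] -
         G[1:(n1 - 2), 3:n2] + G[1:(n1 - 2), 1:(n2 - 2)]) / 4
    doh <- sg^4 * (Lxx * Lyy - Lxy^2)
    doh[Lxx + Lyy >= 0] <- -Inf  # bright blobs only
    resp[, , s] <- doh
  }
  pts <- NULL
  kern <- EBImage::makeBrush(3L, "box")
  for (s in seq_along(sigmas)) {
    # per-scale 3x3 spatial maxima; a blob responding at several scales
    # yields near-duplicate points, which downstream NMS merges
    r <- resp[, , s]
    rmax <- r
    rmax[!is.finite(rmax)] <- -1e30
    dil <- ebi_mat(EBImage::dilate(EBImage::Image(rmax), kern))
    is_max <- rmax >= dil - 1e-15 & r >= threshold
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 0L)
      pts <- rbind(pts, data.frame(row = idx[, 1], col = idx[, 2],
                                   scale = sigmas[s],
                                   response = r[idx]))
  }
  if (is.null(pts))
    return(data.frame(row = integer(0), col = integer(0),
                      scale = numeric(0), response = numeric(0)))
  pts[order(-pts$response, pts$row, pts$col), , drop = FALSE]
}

#' Extract a square patch of fixed physical size
#'
#' The side is `round(patch_um / dx)` forced odd; out-of-bounds area is
#' zero-padded so extraction is total.
#'
#' @param image An [image2d()].
#' @param center `(row, col)` patch center.
#' @param patch_um Physical side in micrometres.
#' @return List with `pixels` (side x side matrix), `center`, `side_px`,
#'   `label` (NA), `confidence` (NA).
#' @export
extract_patch <- function(image, center, patch_um = 3.4) {
  stopifnot(inherits(image, "image2d"), patch_um > 0)
  side <- as.integer(round(patch_um / image$geometry$dx))
  if (side %% 2L == 0L) side <- side + 1L
  h <- (side - 1L) %/% 2L
  img <- image$data
  out <- matrix(0, side, side)
  ctr <- round(center)
  rr <- (ctr[1] - h):(ctr[1] + h)
  cc <- (ctr[2] - h):(ctr[2] + h)
  rok <- rr >= 1L & rr <= nrow(img)
  cok <- cc >= 1L & cc <= ncol(img)
  out[which(rok), which(cok)] <- img[rr[rok], cc[cok]]
  list(pixels = out, center = ctr, side_px = side, label = NA_integer_,
       confidence = NA_real_)
}

#' Detect spine centers in a frame
#'
#' Interest points are classified by the patch classifier; detections of
#' the spine class above the confidence threshold are merged by
#' non-maximum suppression (highest confidence wins within
#' `nms_radius_um`; ties by lower row, then lower column).
#'
#' @param mip An [image2d()].
#' @param classifier A trained [train_classifier()] result.
#' @param nms_radius_um Suppression radius (micrometres).
#' @param patch_um Patch side fed to the classifier.
#' @param confidence Minimum spine-class probability.
#' @param ip_threshold Interest-point response threshold.
#' @param max_candidates Cap on the number of interest points classified.
#' @return data.frame `(row, col, confidence)`.
#' @export
detect_spines <- function(mip, classifier, nms_radius_um = 0.5,
                          patch_um = 3.4, confidence = 0.5,
                          ip_threshold = 5e-4, max_candidates = 400L) {
  stopifnot(inherits(classifier, "spine_classifier"))
  ips <- detect_interest_points(mip, ip_threshold)
  empty <- data.frame(row = integer(0), col = integer(0),
                      confidence = numeric(0))
  if (nrow(ips) == 0L) return(empty)
  if (nrow(ips) > max_candidates) ips <- ips[seq_len(max_candidates), ]
  patches <- lapply(seq_len(nrow(ips)), function(i)
    extract_patch(mip, c(ips$row[i], ips$col[i]), patch_um))
  probs <- classify_patches(classifier, patches)
  conf <- probs[, 1]
  keep <- conf >= confidence
  if (!any(keep)) return(empty)
  det <- data.frame(row = ips$row[keep], col = ips$col[keep],
                    confidence = conf[keep])
  nms_points(det, nms_radius_um / mip$geometry$dx)
}

# greedy non-maximum suppression: keep highest confidence, drop anything
# closer than radius_px; ties broken by lower row then lower column
nms_points <- function(det, radius_px) {
  det <- det[order(-det$confidence, det$row, det$col), ]
  taken <- logical(nrow(det))
  out <- list()
  for (i in seq_len(nrow(det))) {
    if (taken[i]) next
    out[[length(out) + 1L]] <- det[i, ]
    d2 <- (det$row - det$row[i])^2 + (det$col - det$col[i])^2
    taken[d2 < radius_px^2] <- TRUE
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spine counts across a time series
#'
#' Runs [detect_spines()] on the median-filtered MIP of every time point.
#'
#' @param series A registered [timeseries()].
#' @param classifier A trained classifier.
#' @param median_window Median filter window (odd px).
#' @param ... Passed to [detect_spines()].
#' @return Integer vector of per-timepoint counts.
#' @export
count_spines_timeseries <- function(series, classifier, median_window = 3L,
                                    ...) {
  stopifnot(inherits(series, "spine_timeseries"))
  vapply(series$stacks, function(st) {
    mip <- median_filter2d(max_intensity_projection(st), median_window)
    nrow(detect_spines(mip, classifier, ...))
  }, integer(1))
}

#' Build a labelled training set from a simulation
#'
#' Samples patch centers from the simulator's ground-truth geometry and
#' maps them to the nine dendritic-feature classes (spine center,
#' overlapping spines, head-dendrite junction, dendrite edge, dendrite
#' interior, neck midpoint, head edge, bouton/axon, background noise).
#' Classes with no available sites are omitted with a warning. In
#' two-class mode all non-spine sites collapse to label 2.
#'
#' @param sim A [simulate_timeseries()] result.
#' @param n_per_class Target patches per class (balanced up to
#'   availability).
#' @param patch_um Patch side (micrometres).
#' @param n_classes 9 or 2.
#' @param seed Integer seed.
#' @return List of labelled patches (fields `pixels`, `center`, `label`).
#' @export
patch_training_set <- function(sim, n_per_class = 200L, patch_um = 3.4,
                               n_classes = 9L, seed = 1L) {
  stopifnot(inherits(sim, "simulated_dendrite"))
  set.seed(seed)
  sites <- lapply(1:9, function(i) NULL)  # per-class (frame, row, col)
  px_um <- sim$curve$px_um
  for (f in seq_along(sim$frames)) {
    tr <- sim$frames[[f]]$truth
    ctr <- tr$centers
    vis <- which(stats::complete.cases(ctr))  # heads inside the frame
    if (nrow(ctr) > 0L) {
      on_attrs <- tr$attrs
      # class 1: spine centers; class 2: midpoints of overlapping pairs
      sites[[1]] <- rbind(sites[[1]], cbind(f, ctr[vis, , drop = FALSE]))
      if (length(vis) > 1L) {
        cv <- ctr[vis, , drop = FALSE]
        d <- as.matrix(stats::dist(cv)) * px_um
        diag(d) <- Inf
        pair <- which(d < 0.8, arr.ind = TRUE)
        pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
        if (nrow(pair) > 0L)
          sites[[2]] <- rbind(sites[[2]], cbind(
            f, (cv[pair[, 1], , drop = FALSE] +
                  cv[pair[, 2], , drop = FALSE]) / 2))
      }
      # classes 3 and 6: junctions and neck midpoints from geometry
      for (i in seq_len(nrow(ctr))) {
        j <- findInterval(sim$positions_um[sim$states[, f] == 1L][i],
                          sim$curve$arclen_um, all.inside = TRUE)
        ax <- c(sim$curve$rows[j], sim$curve$cols[j])
        nrm <- c(sim$curve$normal_r[j], sim$curve$normal_c[j]) *
          on_attrs$side[i]
        hw <- sim$render$dendrite_width_um / 2 / px_um
        sites[[3]] <- rbind(sites[[3]], cbind(f, t(ax + nrm * hw)))
        mid <- ax + nrm * (hw + on_attrs$neck_um[i] / 2 / px_um)
        sites[[6]] <- rbind(sites[[6]], cbind(f, t(mid)))
        # class 7: head edge (visible heads only)
        if (i %in% vis) {
          edge <- ctr[i, ] + c(on_attrs$radius_um[i] / px_um, 0)
          sites[[7]] <- rbind(sites[[7]], cbind(f, t(edge)))
        }
      }
    }
    dm <- tr$dendrite_mask
    per <- which(mask_perimeter(dm), arr.ind = TRUE)
    if (nrow(per) > 0L)
      sites[[4]] <- rbind(sites[[4]],
                          cbind(f, per[sample.int(nrow(per),
                                                  min(50L, nrow(per))), ,
                                       drop = FALSE]))
    core <- which(dm & !mask_perimeter(dm), arr.ind = TRUE)
    if (nrow(core) > 0L)
      sites[[5]] <- rbind(sites[[5]],
                          cbind(f, core[sample.int(nrow(core),
                                                   min(50L, nrow(core))), ,
                                        drop = FALSE]))
    if (!is.null(tr$bouton_centers) && nrow(tr$bouton_centers) > 0L)
      sites[[8]] <- rbind(sites[[8]], cbind(f, tr$bouton_centers))
    # class 9: background far from any painted structure (incl. boutons)
    far <- !(dm | tr$head_labels > 0L | tr$neck_mask)
    far <- ebi_mat(EBImage::erode(EBImage::Image(far * 1),
                                  EBImage::makeBrush(25L, "box"))) > 0.5
    bg <- which(far, arr.ind = TRUE)
    if (!is.null(tr$bouton_centers) && nrow(tr$bouton_centers) > 0L &&
        nrow(bg) > 0L) {
      bc <- tr$bouton_centers
      mind <- apply(bg, 1, function(p)
        min((bc[, 1] - p[1])^2 + (bc[, 2] - p[2])^2))
      bg <- bg[mind > 20^2, , drop = FALSE]
    }
    if (nrow(bg) > 0L)
      sites[[9]] <- rbind(sites[[9]],
                          cbind(f, bg[sample.int(nrow(bg),
                                                 min(50L, nrow(bg))), ,
                                      drop = FALSE]))
  }
  patches <- list()
  for (cls in 1:9) {
    s <- sites[[cls]]
    if (is.null(s) || nrow(s) == 0L) {
      warning(sprintf("class %d (%s): no available sites, omitted", cls,
                      patch_class_names()[cls]))
      next
    }
    take <- s[sample.int(nrow(s), min(n_per_class, nrow(s))), ,
              drop = FALSE]
    for (i in seq_len(nrow(take))) {
      img <- sim$frames[[take[i, 1]]]$image
      p <- extract_patch(img, take[i, 2:3], patch_um)
      p$label <- if (n_classes == 2L && cls != 1L) 2L else cls
      p$frame <- take[i, 1]
      patches[[length(patches) + 1L]] <- p
    }
  }
  patches
}
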