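#' Build the fast-marching speed map for neck tracing
#'
#' Each z-slice is grayscale-eroded with a disk (suppressing thin spurious
#' bridges), then intensities are normalized to `[0, 1]`. The background
#' keeps a small positive floor so the march is total and the arrival time
#' finite everywhere.
#'
#' @param stack A [zstack()].
#' @param erosion_radius Disk radius in pixels (0 skips the erosion).
#' @param floor_frac Speed floor as a fraction of the maximum speed.
#' @return An object of class `speed_map` (fields `values`,
#'   `erosion_radius`).
#' @export
build_speed_map <- function(stack, erosion_radius = 1L, floor_frac = 1e-3) {
  stopifnot(inherits(stack, "zstack"))
  arr <- stack$data
  if (erosion_radius > 0L) {
    kern <- EBImage::makeBrush(2L * as.integer(erosion_radius) + 1L, "disc")
    for (z in seq_len(dim(arr)[3]))
      arr[, , z] <- ebi_mat(EBImage::erode(EBImage::Image(arr[, , z]),
                                             kern))
  }
  mx <- max(arr)
  if (mx <= 0)
    stop("erosion removed all foreground; use a smaller erosion_radius")
  v <- arr / mx
  v[v < floor_frac] <- floor_frac
  structure(list(values = v, erosion_radius = as.integer(erosion_radius)),
            class = "speed_map")
}

#' 3D arrival-time map from a source voxel
#'
#' Multi-stencil fast marching (see [msfm_distance()]) on a [build_speed_map()]
#' result, anisotropy-aware via the stack geometry.
#'
#' @param speed A `speed_map` or a bare non-negative array.
#' @param source Voxel `(row, col, slice)`, 1-based.
#' @param geometry Optional [voxel_geometry()]; when given, arrival times
#'   are in micrometre units.
#' @return Arrival-time array.
#' @export
distance_map_3d <- function(speed, source, geometry = NULL) {
  v <- if (inherits(speed, "speed_map")) speed$values else speed
  spacing <- if (is.null(geometry)) rep(1, length(dim(v))) else
    c(geometry$dy, geometry$dx,
      if (length(dim(v)) == 3L) geometry$dz %||% 1 else NULL)
  msfm_distance(v, source, spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trace a geodesic on an arrival-time map
#'
#' Fourth-order Runge-Kutta descent on the arrival-time gradient from
#' `start` back to the source, in steps of `step` voxels.
#'
#' @param distmap Arrival-time array from [distance_map_3d()].
#' @param start Voxel `(row, col[, slice])` with finite arrival time.
#' @param source The source voxel used to build the map.
#' @param step Step size as a fraction of a voxel.
#' @return Matrix of ordered path points (subvoxel, one row per point)
#'   from `start` to the source; attribute `reached` reports success.
#' @export
trace_path <- function(distmap, start, source, step = 0.25) {
  if (!is.finite(distmap[matrix(round(start), 1)]))
    stop("start has no finite arrival time")
  if (all(round(start) == round(source)))
    return(matrix(as.numeric(source), 1, length(source)))
  p <- trace_descent(distmap, as.numeric(start), as.numeric(source), step)
  if (!isTRUE(attr(p, "reached")))
    attr(p, "reached") <- FALSE
  p
}

#' Candidate neck base points on the dendrite perimeter
#'
#' The `n` perimeter voxels closest (anisotropy-aware Euclidean distance)
#' to the spine head center, ties broken by row, then col, then slice.
#'
#' @param head_center Voxel `(row, col[, slice])`.
#' @param dendrite_mask Logical 2D matrix or 3D array.
#' @param n Number of candidates.
#' @param geometry Optional [voxel_geometry()] for anisotropic distance.
#' @return Matrix with one candidate voxel per row.
#' @export
candidate_base_points <- function(head_center, dendrite_mask, n = 8L,
                                  geometry = NULL) {
  stopifnot(any(dendrite_mask), n >= 1L)
  per <- mask_perimeter(dendrite_mask)
  vox <- which(per, arr.ind = TRUE)
  if (nrow(vox) < n)
    warning(sprintf("perimeter has only %d points (< n = %d)", nrow(vox), n))
  w <- if (is.null(geometry)) rep(1, ncol(vox)) else
    c(geometry$dy, geometry$dx, geometry$dz %||% 1)[seq_len(ncol(vox))]
  hc <- head_center[seq_len(ncol(vox))]
  d2 <- rowSums(sweep(sweep(vox, 2, hc), 2, w, "*")^2)
  ord <- order(d2, vox[, 1], vox[, 2],
               if (ncol(vox) >= 3L) vox[, 3] else rep(0, nrow(vox)))
  vox[ord[seq_len(min(n, nrow(vox)))], , drop = FALSE]
}

# boundary voxels of a mask (6/4-connectivity erosion complement)
mask_perimeter <- function(mask) {
  d <- dim(mask)
  er <- mask
  shift_and <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), length(d))
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    if (length(d) == 2L) {
      if (ax == 1L) m[src, , drop = FALSE] else m[, src, drop = FALSE]
    } else {
      if (ax == 1L) m[src, , , drop = FALSE]
      else if (ax == 2L) m[, src, , drop = FALSE]
      else m[, , src, drop = FALSE]
    }
  }
  for (ax in seq_along(d)) {
    if (d[ax] == 1L) next
    er <- er & shift_and(mask, ax, 1L) & shift_and(mask, ax, -1L)
  }
  mask & !er
}

#' Length, complexity and smoothness of a neck-path candidate
#'
#' `L` is the physical arclength (micrometres, anisotropic). `C` is the sum
#' of L1 norms of the coordinate increments (voxel units) over the path
#' resampled at half-voxel steps. `S` is the total variation of the image
#' intensity sampled along the resampled path by trilinear interpolation.
#'
#' @param path Matrix of path points (rows), voxel coordinates.
#' @param stack A [zstack()] to sample intensities from.
#' @param geometry A [voxel_geometry()].
#' @return Named list `(L, C, S)`.
#' @export
path_terms <- function(path, stack, geometry = stack$geometry) {
  stopifnot(nrow(path) >= 2L)
  arr <- if (inherits(stack, "zstack")) stack$data else stack
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  if (ncol(path) == 2L) path <- cbind(path, 1)
  w <- c(geometry$dy, geometry$dx, geometry$dz %||% 1)
  dif <- path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE]
  L <- sum(sqrt(dif^2 %*% w^2))
  rp <- resample_path(path, 0.5)
  dif_r <- rp[-1, , drop = FALSE] - rp[-nrow(rp), , drop = FALSE]
  C <- sum(abs(dif_r))
  I <- interp_trilinear(arr, rp[, 1], rp[, 2], rp[, 3])
  S <- sum(abs(diff(I)))
  list(L = L, C = C, S = S)
}

#' Select the neck path among candidates
#'
#' Cost of candidate p is `L_p/max(L) + C_p/max(C) + S_p/max(S)`; the
#' smallest total wins (ties: first candidate). Degenerate terms (all
#' zero across candidates) contribute 0 to every candidate.
#'
#' @param candidates List of candidates, each a list with `path` (matrix)
#'   and `L`, `C`, `S`.
#' @return The winning candidate augmented with `cost` and `index`.
#' @export
select_neck_path <- function(candidates) {
  if (length(candidates) == 0L) stop("no valid neck-path candidates")
  term <- function(x) {
    mx <- max(x)
    if (mx <= 0) rep(0, length(x)) else x / mx
  }
  L <- vapply(candidates, `[[`, numeric(1), "L")
  C <- vapply(candidates, `[[`, numeric(1), "C")
  S <- vapply(candidates, `[[`, numeric(1), "S")
  cost <- term(L) + term(C) + term(S)
  i <- which.min(cost)
  out <- candidates[[i]]
  out$cost <- cost[i]
  out$index <- i
  out
}

#' Trim a neck path to the portion between head and dendrite
#'
#' Removes path points inside the segmented spine head and inside the
#' dendrite mask, keeping the longest contiguous run outside both; `L`,
#' `C`, `S` are recomputed on the trimmed path and the trimmed `L` is the
#' reported neck length.
#'
#' @param path Matrix of path points (voxel coordinates).
#' @param head_mask Logical 2D matrix (full-frame or ROI-aligned).
#' @param dendrite_mask Logical 2D matrix or 3D array.
#' @param stack A [zstack()] for recomputing terms.
#' @param geometry A [voxel_geometry()].
#' @return List with `points`, `L`, `C`, `S`, `trimmed`, `zero_length`.
#' @export
trim_path <- function(path, head_mask, dendrite_mask, stack,
                      geometry = stack$geometry) {
  in_mask <- function(m, pts) {
    r <- pmin(pmax(round(pts[, 1]), 1L), dim(m)[1])
    c <- pmin(pmax(round(pts[, 2]), 1L), dim(m)[2])
    if (length(dim(m)) == 3L) {
      z <- pmin(pmax(round(pts[, 3]), 1L), dim(m)[3])
      m[cbind(r, c, z)]
    } else m[cbind(r, c)]
  }
  inside_head <- in_mask(head_mask, path)
  inside_dend <- in_mask(dendrite_mask, path)
  if (!any(inside_head) || !any(inside_dend)) {
    warning("path does not intersect both masks; returned untrimmed")
    tm <- path_terms(path, stack, geometry)
    return(list(points = path, L = tm$L, C = tm$C, S = tm$S,
                trimmed = FALSE, zero_length = FALSE))
  }
  outside <- !(inside_head | inside_dend)
  runs <- rle(outside)
  if (!any(runs$values)) {
    return(list(points = path[0, , drop = FALSE], L = 0, C = 0, S = 0,
                trimmed = TRUE, zero_length = TRUE))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  keep <- starts[best]:ends[best]
  sub <- path[keep, , drop = FALSE]
  if (nrow(sub) < 2L)
    return(list(points = sub, L = 0, C = 0, S = 0, trimmed = TRUE,
                zero_length = TRUE))
  tm <- path_terms(sub, stack, geometry)
  list(points = sub, L = tm$L, C = tm$C, S = tm$S, trimmed = TRUE,
       zero_length = FALSE)
}

#' Extract the spine-neck path and its length
#'
#' Full neck workflow: speed map with per-slice erosion, fast-marching
#' arrival times from the head center, geodesics traced back from the `n`
#' Euclidean-nearest dendrite perimeter points, candidate selection by the
#' normalized length/complexity/smoothness cost, and trimming to the
#' head-to-dendrite portion.
#'
#' @param stack A [zstack()].
#' @param head_center Voxel `(row, col[, slice])` of the spine head center.
#' @param dendrite_mask Logical 2D/3D dendrite mask.
#' @param head_mask Optional logical head mask for trimming.
#' @param n Number of candidate base points.
#' @param erosion_radius Passed to [build_speed_map()].
#' @param step Runge-Kutta step (voxels).
#' @return An object of class `neck_path`: `points`, `base_point`,
#'   `length_um`, `L`, `C`, `S`, `cost`, `trimmed`, `flags`.
#' @export
extract_neck_path <- function(stack, head_center, dendrite_mask,
                              head_mask = NULL, n = 8L, erosion_radius = 1L,
                              step = 0.25) {
  sp <- build_speed_map(stack, erosion_radius)
  src <- round(head_center)
  if (length(src) == 2L) src <- c(src, 1L)
  tmap <- distance_map_3d(sp, src, stack$geometry)
  bases <- candidate_base_points(head_center, dendrite_mask, n,
                                 stack$geometry)
  cands <- list()
  for (i in seq_len(nrow(bases))) {
    b <- bases[i, ]
    if (length(b) == 2L) b <- c(b, 1L)
    p <- tryCatch(trace_path(tmap, b, src, step), error = function(e) NULL)
    if (is.null(p) || !isTRUE(attr(p, "reached"))) next
    # orient from head (source) to base
    p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    tm <- path_terms(p, stack)
    cands[[length(cands) + 1L]] <-
      list(path = p, base = b, L = tm$L, C = tm$C, S = tm$S)
  }
  if (length(cands) == 0L)
    stop("neck extraction failed: no candidate geodesic reached the head")
  sel <- select_neck_path(cands)
  res <- list(points = sel$path, base_point = sel$base, L = sel$L,
              C = sel$C, S = sel$S, cost = sel$cost, trimmed = FALSE,
              length_um = sel$L, flags = character(0))
  if (!is.null(head_mask)) {
    tr <- trim_path(sel$path, head_mask, dendrite_mask, stack)
    res$points <- tr$points
    res$L <- tr$L
    res$C <- tr$C
    res$S <- tr$S
    res$trimmed <- tr$trimmed
    res$length_um <- tr$L
    if (tr$zero_length) res$flags <- c(res$flags, "zero-neck")
  }
  class(res) <- "neck_path"
  res
}

#' @export
print.neck_path <- function(x, ...) {
  cat(sprintf("<neck_path> %d pts, length %.3f um, cost %.3f%s\n",
              nrow(x$points), x$length_um, x$cost,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}
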