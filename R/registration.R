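#' Subpixel global registration of two z-stacks
#'
#' Estimates the lateral drift of `mov` relative to `ref` by phase
#' cross-correlation of the two maximum-intensity projections, refined to
#' `1/upsample` pixel by a matrix-multiply DFT evaluated on a small
#' neighbourhood of the coarse peak. The moving stack is translated back by
#' the estimate with a Fourier shift (periodic boundary); an integer slice
#' offset is then chosen to maximize slice-wise correlation.
#'
#' @param ref Reference [zstack()].
#' @param mov Moving [zstack()] with the same M, N.
#' @param upsample Subpixel refinement factor (>= 1); 100 gives 0.01 px.
#' @param z_correct Estimate an integer slice offset as well.
#' @return List with `shift` (fields `dy`, `dx`, `dz`, `peak_error`) and
#'   `registered` (the translated moving stack).
#' @export
global_register <- function(ref, mov, upsample = 100L, z_correct = TRUE) {
  stopifnot(inherits(ref, "zstack"), inherits(mov, "zstack"))
  if (!all(dim(ref$data)[1:2] == dim(mov$data)[1:2]))
    stop("stacks must share M and N")
  a <- max_intensity_projection(ref)$data
  b <- max_intensity_projection(mov)$data
  est <- phase_correlate(a, b, upsample)
  reg <- fourier_shift_stack(mov$data, -est$dy, -est$dx)
  dz <- 0L
  nz <- dim(ref$data)[3]
  if (z_correct && nz > 1L) {
    best <- -Inf
    for (cand in seq(-(nz - 1L), nz - 1L)) {
      za <- seq_len(nz)
      zb <- za + cand
      keep <- zb >= 1L & zb <= nz
      if (sum(keep) < 1L) next
      v <- mean(vapply(which(keep), function(z) {
        suppressWarnings(cor(as.numeric(ref$data[, , z]),
                             as.numeric(reg[, , z + cand])))
      }, numeric(1)), na.rm = TRUE)
      if (is.finite(v) && v > best) {
        best <- v
        dz <- as.integer(cand)
      }
    }
    if (dz != 0L) reg <- shift_slices(reg, -dz)
  }
  reg[reg < 0] <- 0
  maxv <- 2^ref$geometry$bit_depth - 1
  reg[reg > maxv] <- maxv
  list(shift = list(dy = est$dy, dx = est$dx, dz = dz,
                    peak_error = est$peak_error),
       registered = zstack(reg, mov$geometry))
}

# cross-correlation peak with matrix-multiply DFT upsampling; the cross
# power is left unnormalized so signal-dominated frequencies carry the
# weight (robust under shot noise)
phase_correlate <- function(a, b, upsample = 1L) {
  if (max(a) <= min(a) || max(b) <= min(b))
    stop("degenerate input: constant image has no correlation peak")
  M <- nrow(a)
  N <- ncol(a)
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  R <- Conj(Fa) * Fb
  cc <- stats::fft(R, inverse = TRUE) / length(R)
  peak <- which.max(Mod(cc))
  pr <- (peak - 1) %% M
  pc <- (peak - 1) %/% M
  dy <- if (pr > M / 2) pr - M else pr
  dx <- if (pc > N / 2) pc - N else pc
  peak_mag <- Mod(cc[peak])
  if (upsample > 1L) {
    us <- as.integer(upsample)
    half <- ceiling(1.5 * us) / 2
    ys <- dy + seq(-half, half) / us
    xs <- dx + seq(-half, half) / us
    fu <- c(0:(ceiling(M / 2) - 1), -(floor(M / 2):1))
    fv <- c(0:(ceiling(N / 2) - 1), -(floor(N / 2):1))
    Ey <- exp(2i * pi * outer(ys, fu) / M)
    Ex <- exp(2i * pi * outer(fv, xs) / N)
    ccu <- Ey %*% R %*% Ex / length(R)
    pk <- which(Mod(ccu) == max(Mod(ccu)), arr.ind = TRUE)[1, ]
    dy <- ys[pk[1]]
    dx <- xs[pk[2]]
    peak_mag <- max(Mod(ccu))
  }
  # normalized residual: 0 when the images are exact translates
  denom <- sqrt(sum(Mod(Fa)^2) * sum(Mod(Fb)^2)) / length(R)
  list(dy = dy, dx = dx,
       peak_error = sqrt(max(0, 1 - (peak_mag / denom)^2)))
}

# translate a matrix by (dy, dx) with the Fourier shift theorem
fourier_shift2d <- function(img, dy, dx) {
  M <- nrow(img)
  N <- ncol(img)
  fu <- c(0:(ceiling(M / 2) - 1), -(floor(M / 2):1))
  fv <- c(0:(ceiling(N / 2) - 1), -(floor(N / 2):1))
  ramp <- exp(-2i * pi * (outer(fu * dy / M, rep(1, N)) +
                          outer(rep(1, M), fv * dx / N)))
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / (M * N)
}

fourier_shift_stack <- function(arr, dy, dx) {
  for (z in seq_len(dim(arr)[3])) arr[, , z] <- fourier_shift2d(arr[, , z], dy, dx)
  arr
}

# integer slice shift, zero-filled
shift_slices <- function(arr, dz) {
  if (dz == 0L) return(arr)
  nz <- dim(arr)[3]
  out <- array(0, dim(arr))
  for (z in seq_len(nz)) {
    zs <- z - dz
    if (zs >= 1L && zs <= nz) out[, , z] <- arr[, , zs]
  }
  out
}

#' Register a whole time series by chained global registration
#'
#' Each time point is registered to its predecessor; the accumulated drift
#' is applied once per stack so the data is resampled a single time.
#'
#' @param series A [timeseries()].
#' @param upsample Subpixel factor passed to [global_register()].
#' @param z_correct Estimate integer slice offsets as well.
#' @return List with `series` (registered) and `shifts` (data.frame with
#'   columns t, dy, dx, dz, peak_error; accumulated drift per time point).
#' @export
register_timeseries <- function(series, upsample = 100L, z_correct = TRUE) {
  stopifnot(inherits(series, "spine_timeseries"))
  T <- length(series)
  shifts <- data.frame(t = seq_len(T), dy = 0, dx = 0, dz = 0L,
                       peak_error = 0)
  out <- series$stacks
  acc <- c(0, 0, 0)
  for (t in seq_len(T)[-1]) {
    a <- max_intensity_projection(series$stacks[[t - 1]])$data
    b <- max_intensity_projection(series$stacks[[t]])$data
    est <- phase_correlate(a, b, upsample)
    acc[1] <- acc[1] + est$dy
    acc[2] <- acc[2] + est$dx
    reg <- fourier_shift_stack(series$stacks[[t]]$data, -acc[1], -acc[2])
    dz <- 0L
    nz <- dim(reg)[3]
    if (z_correct && nz > 1L) {
      refd <- out[[t - 1]]$data
      best <- -Inf
      for (cand in seq(-(nz - 1L), nz - 1L)) {
        zb <- seq_len(nz) + cand
        keep <- zb >= 1L & zb <= nz
        if (!any(keep)) next
        v <- mean(vapply(which(keep), function(z) {
          suppressWarnings(cor(as.numeric(refd[, , z]),
                               as.numeric(reg[, , z + cand])))
        }, numeric(1)), na.rm = TRUE)
        if (is.finite(v) && v > best) {
          best <- v
          dz <- as.integer(cand)
        }
      }
      if (dz != 0L) reg <- shift_slices(reg, -dz)
    }
    reg[reg < 0] <- 0
    maxv <- 2^series$stacks[[t]]$geometry$bit_depth - 1
    reg[reg > maxv] <- maxv
    out[[t]] <- zstack(reg, series$stacks[[t]]$geometry)
    shifts[t, c("dy", "dx")] <- acc[1:2]
    shifts$dz[t] <- dz
    shifts$peak_error[t] <- est$peak_error
  }
  list(series = timeseries(out, series$timestamps), shifts = shifts)
}

#' Normalized mutual information of two images
#'
#' NMI = (H(A) + H(B)) / H(A, B) from a joint histogram with `bins` levels
#' per axis, each image standardized to its own intensity range. Ranges in
#' value from 1 (independence) to 2 (perfect dependence); a constant image
#' pair is defined to have NMI 2.
#'
#' @param a,b Equal-shaped [image2d()] objects or matrices.
#' @param bins Histogram bins per axis (>= 2).
#' @return NMI in `[1, 2]`.
#' @export
normalized_mutual_information <- function(a, b, bins = 64L) {
  a <- if (inherits(a, "image2d")) a$data else a
  b <- if (inherits(b, "image2d")) b$data else b
  stopifnot(all(dim(a) == dim(b)), bins >= 2L)
  qa <- quantize_range(a, bins)
  qb <- quantize_range(b, bins)
  if (is.null(qa) && is.null(qb)) return(2)
  if (is.null(qa) || is.null(qb)) return(1)
  joint <- table(factor(qa, levels = seq_len(bins)),
                 factor(qb, levels = seq_len(bins)))
  p <- joint / sum(joint)
  pa <- rowSums(p)
  pb <- colSums(p)
  ha <- entropy_bits(pa)
  hb <- entropy_bits(pb)
  hab <- entropy_bits(p)
  if (hab <= 0) return(2)
  (ha + hb) / hab
}

quantize_range <- function(x, bins) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(NULL)
  pmin(as.integer((x - lo) / (hi - lo) * bins) + 1L, bins)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' ROI window around a spine
#'
#' @param center Integer `(row, col)` pixel position.
#' @param half_size Half side in pixels (> 0); the window spans
#'   `2 * half_size + 1` pixels.
#' @param timepoint Time index the window refers to.
#' @return An object of class `roi_window`.
#' @export
roi_window <- function(center, half_size, timepoint = 1L) {
  stopifnot(length(center) == 2L, half_size > 0)
  structure(list(center = as.numeric(round(center)),
                 half_size = as.integer(half_size),
                 timepoint = as.integer(timepoint)),
            class = "roi_window")
}

# crop a window out of an image; the window must fit after clamping
crop_roi <- function(image, window) {
  img <- if (inherits(image, "image2d")) image$data else image
  h <- window$half_size
  if (2L * h + 1L > min(dim(img))) stop("ROI window larger than image")
  r <- clamp_center(window$center[1], h, nrow(img))
  c <- clamp_center(window$center[2], h, ncol(img))
  img[(r - h):(r + h), (c - h):(c + h)]
}

clamp_center <- function(x, h, n) as.integer(min(max(x, h + 1L), n - h))

#' Re-center a spine ROI by maximizing NMI with the previous time point
#'
#' Scans all integer offsets within a Chebyshev radius, cropping the
#' current image at each offset and scoring it against the previous ROI by
#' normalized mutual information. Ties go to the smallest offset magnitude,
#' then row-major order.
#'
#' @param prev_roi_image Matrix or [image2d()]: the ROI at the previous
#'   time point.
#' @param current_image The full current frame.
#' @param window [roi_window()] giving the starting center.
#' @param search_radius Chebyshev search radius in pixels (>= 0).
#' @param bins NMI histogram bins.
#' @return Updated [roi_window()] with attributes `nmi` (best score).
#' @export
local_register_roi <- function(prev_roi_image, current_image, window,
                               search_radius = 10L, bins = 64L) {
  prev <- if (inherits(prev_roi_image, "image2d")) prev_roi_image$data else prev_roi_image
  img <- if (inherits(current_image, "image2d")) current_image$data else current_image
  h <- window$half_size
  if (2L * h + 1L > min(dim(img))) stop("ROI window larger than image")
  if (search_radius < 0L) stop("search_radius must be >= 0")
  if (search_radius == 0L) {
    w <- window
    attr(w, "nmi") <- normalized_mutual_information(
      prev, crop_roi(img, window), bins)
    return(w)
  }
  best <- NULL
  best_key <- c(-Inf, Inf, Inf, Inf)
  for (dy in seq(-search_radius, search_radius)) {
    for (dx in seq(-search_radius, search_radius)) {
      cand <- roi_window(window$center + c(dy, dx), h, window$timepoint)
      crop <- crop_roi(img, cand)
      v <- normalized_mutual_information(prev, crop, bins)
      key <- c(v, -(dy^2 + dx^2), -dy, -dx)
      if (key_greater(key, best_key)) {
        best_key <- key
        best <- cand
      }
    }
  }
  attr(best, "nmi") <- best_key[1]
  best
}

key_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + 1e-12) return(TRUE)
    if (a[i] < b[i] - 1e-12) return(FALSE)
  }
  FALSE
}
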