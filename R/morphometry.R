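#' Integrated fluorescence intensity (IFI) spine-head volume
#'
#' Sums intensities inside the head mask, subtracts the background (minimum
#' intensity in the spine field of view times the mask area) and normalizes
#' by the median intensity of the segmented dendrite. The normalized value
#' is a dimensionless volume proxy invariant to common intensity scaling of
#' the frame.
#'
#' @param roi Numeric matrix or [image2d()]: the spine field of view.
#' @param mask Logical matrix or `spine_head_mask` (same shape as `roi`).
#' @param fov_min Background level; default `min(roi)`.
#' @param dendrite_median Median shaft intensity (> 0).
#' @return An object of class `ifi_measurement`: `raw_sum`, `background`,
#'   `area_px`, `dendrite_median`, `normalized_volume`, `clamped`.
#' @export
ifi_volume <- function(roi, mask, fov_min = NULL, dendrite_median) {
  img <- if (inherits(roi, "image2d")) roi$data else roi
  m <- if (inherits(mask, "spine_head_mask")) mask$mask else mask
  stopifnot(all(dim(img) == dim(m)))
  if (!any(m)) stop("empty mask")
  if (dendrite_median <= 0) stop("dendrite_median must be > 0")
  if (is.null(fov_min)) fov_min <- min(img)
  raw <- sum(img[m])
  area <- sum(m)
  bg <- fov_min * area
  num <- raw - bg
  clamped <- FALSE
  if (num < 0) {
    num <- 0
    clamped <- TRUE
  }
  structure(list(raw_sum = raw, background = bg, area_px = area,
                 dendrite_median = dendrite_median,
                 normalized_volume = num / dendrite_median,
                 clamped = clamped),
            class = "ifi_measurement")
}

#' @export
print.ifi_measurement <- function(x, ...) {
  cat(sprintf("<ifi> raw %.4g, bg %.4g, area %d px, normalized %.4g%s\n",
              x$raw_sum, x$background, x$area_px, x$normalized_volume,
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' FWHM-based spine-head volume
#'
#' Samples an intensity profile along a line through the head center at the
#' given orientation (parallel to the postsynaptic density), fits a
#' Gaussian with constant offset, and treats the FWHM of the fit as the
#' diameter of a sphere: r = FWHM/2 and V = 4/3 pi r^3. Orientation is an
#' explicit parameter; there is no automatic PSD search.
#'
#' @param roi An [image2d()] (geometry supplies the micrometre scale).
#' @param center `(row, col)` of the spine head.
#' @param orientation_deg Line orientation in degrees (0 = along image
#'   columns, counterclockwise positive).
#' @param line_length_um Profile length in micrometres.
#' @return An object of class `fwhm_measurement`: `profile` (data.frame
#'   x_um, intensity), `fit` (amplitude, mean, sigma, offset), `fwhm_um`,
#'   `radius_um`, `volume_um3`, `orientation_deg`.
#' @export
fwhm_volume <- function(roi, center, orientation_deg, line_length_um = 2) {
  stopifnot(inherits(roi, "image2d"))
  img <- roi$data
  dx <- roi$geometry$dx
  step <- dx / 2
  xs <- seq(-line_length_um / 2, line_length_um / 2, by = step)
  th <- orientation_deg * pi / 180
  rr <- center[1] - xs * sin(th) / roi$geometry$dy
  cc <- center[2] + xs * cos(th) / dx
  if (any(rr < 1 | rr > nrow(img) | cc < 1 | cc > ncol(img)))
    stop("profile line does not fit inside the ROI")
  prof <- interp_bilinear(img, rr, cc)
  imax <- which.max(prof)
  if (imax == 1L || imax == length(prof))
    stop("profile has no interior maximum")
  off0 <- min(prof)
  amp0 <- max(prof) - off0
  mu0 <- xs[imax]
  w <- pmax(prof - off0, 0)
  sig0 <- sqrt(sum(w * (xs - mu0)^2) / sum(w))
  sig0 <- max(sig0, step)
  resid_fn <- function(p) p[1] * exp(-(xs - p[2])^2 / (2 * p[3]^2)) +
    p[4] - prof
  fit <- minpack.lm::nls.lm(
    par = c(A = amp0, mu = mu0, s = sig0, c0 = off0),
    fn = resid_fn,
    lower = c(0, min(xs), step / 10, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    stop("Gaussian fit did not converge: ", fit$message)
  cf <- fit$par
  sigma <- unname(cf["s"])
  if (sigma > line_length_um / 2)
    stop("fit quality: sigma exceeds half the profile length")
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  r <- fwhm / 2
  structure(list(profile = data.frame(x_um = xs, intensity = prof),
                 fit = as.list(cf), fwhm_um = fwhm, radius_um = r,
                 volume_um3 = 4 / 3 * pi * r^3,
                 orientation_deg = orientation_deg),
            class = "fwhm_measurement")
}

#' @export
print.fwhm_measurement <- function(x, ...) {
  cat(sprintf("<fwhm> %.3f um -> r %.3f um, V %.4f um^3 (at %g deg)\n",
              x$fwhm_um, x$radius_um, x$volume_um3, x$orientation_deg))
  invisible(x)
}

#' Normalize a volume series to its baseline
#'
#' @param series Numeric per-timepoint values.
#' @param baseline_idx Indices of the baseline time points.
#' @return `series / mean(series[baseline_idx])`.
#' @export
normalize_to_baseline <- function(series, baseline_idx) {
  m <- mean(series[baseline_idx])
  if (!is.finite(m) || m <= 0) stop("baseline mean must be > 0")
  series / m
}

#' Symmetric mean absolute percentage error of two series
#'
#' `100/t * sum(|a - b| / |a + b|)`; a term with `a + b = 0` is 0 when both
#' entries are 0 and an error otherwise. For non-negative series the result
#' lies in `[0, 100]`.
#'
#' @param series_a,series_b Equal-length numeric vectors.
#' @return sMAPE in percent.
#' @export
smape <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b), length(series_a) >= 1L)
  num <- abs(series_a - series_b)
  den <- abs(series_a + series_b)
  bad <- den == 0 & num != 0
  if (any(bad)) stop("undefined sMAPE term: a + b = 0 with a != b")
  terms <- ifelse(den == 0, 0, num / den)
  100 * mean(terms)
}

#' Similarity score of two series
#'
#' `SS = 100 - sMAPE` (percent scale), so identical series score 100.
#'
#' @inheritParams smape
#' @return Similarity score in percent.
#' @export
similarity_score <- function(series_a, series_b) {
  100 - smape(series_a, series_b)
}
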