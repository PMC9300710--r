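#' Turnover dynamics parameters
#'
#' Two-state Markov dynamics of potential synapses: a site that is off
#' turns on with probability `p_on` per step, an occupied site turns off
#' with probability `p_off` per step. Defaults are the in-vivo estimates
#' the simulated dataset is built on.
#'
#' @param p_on Off-to-on probability per time step.
#' @param p_off On-to-off probability per time step.
#' @param steps Number of simulation steps.
#' @param n_keyframes Number of rendered keyframes sampled from the chain.
#' @param seed Integer seed.
#' @return An object of class `turnover_params`.
#' @export
turnover_params <- function(p_on = 1e-3, p_off = 4.1e-3, steps = 2000L,
                            n_keyframes = 26L, seed = 1L) {
  stopifnot(p_on >= 0, p_on <= 1, p_off >= 0, p_off <= 1, steps >= 1)
  structure(list(p_on = p_on, p_off = p_off, steps = as.integer(steps),
                 n_keyframes = as.integer(n_keyframes),
                 seed = as.integer(seed)),
            class = "turnover_params")
}

#' Rendering parameters for simulated two-photon frames
#'
#' Single dendrite in the optical plane: dendrite pixels fluctuate around
#' 1000 +/- 100, spine pixels around 2000 +/- 300, values clipped to
#' `[0, intensity_max]`, blurred with a Gaussian PSF and Poisson-sampled.
#'
#' @param image_px Frame side in pixels.
#' @param pixel_nm Pixel pitch in nanometres.
#' @param dendrite_mean,dendrite_sd Painted dendrite intensity model.
#' @param spine_mean,spine_sd Painted spine (head and neck) intensity model.
#' @param intensity_max Clip ceiling before the PSF.
#' @param psf_fwhm_nm PSF full width at half maximum.
#' @param dendrite_width_um Dendrite tube width.
#' @param spine_radius_um Mean spine-head radius (SD 0.1 um, floor 0.15 um).
#' @param neck_range_um Range of spine-neck lengths (uniform).
#' @param noise_gamma Photon-budget multiplier for the Poisson noise
#'   (larger is cleaner); `Inf` disables noise.
#' @return An object of class `render_params`.
#' @export
render_params <- function(image_px = 512L, pixel_nm = 72, dendrite_mean = 1000,
                          dendrite_sd = 100, spine_mean = 2000, spine_sd = 300,
                          intensity_max = 2000, psf_fwhm_nm = 600,
                          dendrite_width_um = 0.8, spine_radius_um = 0.4,
                          neck_range_um = c(0.2, 1.5), noise_gamma = 1) {
  structure(list(image_px = as.integer(image_px), pixel_nm = pixel_nm,
                 dendrite_mean = dendrite_mean, dendrite_sd = dendrite_sd,
                 spine_mean = spine_mean, spine_sd = spine_sd,
                 intensity_max = intensity_max, psf_fwhm_nm = psf_fwhm_nm,
                 dendrite_width_um = dendrite_width_um,
                 spine_radius_um = spine_radius_um,
                 neck_range_um = neck_range_um, noise_gamma = noise_gamma),
            class = "render_params")
}

#' Place potential synapses along a dendrite
#'
#' Poisson process: the number of sites is Poisson(density x length) and
#' positions are uniform on the branch, returned sorted.
#'
#' @param length_um Branch length in micrometres.
#' @param density_per_um Expected sites per micrometre.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of arclength positions in `[0, length_um]`.
#' @export
place_synapses <- function(length_um, density_per_um = 2.56, seed = NULL) {
  stopifnot(length_um > 0, density_per_um >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, density_per_um * length_um)
  sort(stats::runif(n, 0, length_um))
}

#' Evolve potential-synapse states
#'
#' Independent two-state Markov chains per site, initial states drawn from
#' the stationary distribution `p_on / (p_on + p_off)`.
#'
#' @param n_synapses Number of sites.
#' @param params A [turnover_params()].
#' @return Binary matrix `n_synapses x steps`.
#' @export
simulate_states <- function(n_synapses, params = turnover_params()) {
  set.seed(params$seed)
  p_stat <- if (params$p_on + params$p_off > 0)
    params$p_on / (params$p_on + params$p_off) else 0
  states <- matrix(0L, n_synapses, params$steps)
  if (n_synapses == 0L) return(states)
  s <- stats::rbinom(n_synapses, 1L, p_stat)
  states[, 1L] <- s
  for (t in seq_len(params$steps - 1L)) {
    u <- stats::runif(n_synapses)
    s <- ifelse(s == 1L,
                ifelse(u < params$p_off, 0L, 1L),
                ifelse(u < params$p_on, 1L, 0L))
    states[, t + 1L] <- s
  }
  states
}

#' Sample keyframes from a state matrix
#'
#' Takes `n_keyframes` equally spaced steps including the first and last
#' (spacing `floor(steps / (n_keyframes - 1))`, capped at the final step).
#'
#' @param states Binary matrix from [simulate_states()].
#' @param n_keyframes Number of keyframes (>= 2).
#' @return Binary matrix `n_synapses x n_keyframes`.
#' @export
keyframe_states <- function(states, n_keyframes = 26L) {
  steps <- ncol(states)
  if (n_keyframes < 2L) stop("n_keyframes must be >= 2")
  stopifnot(n_keyframes <= steps)
  stride <- floor(steps / (n_keyframes - 1L))
  idx <- pmin((seq_len(n_keyframes) - 1L) * stride + 1L, steps)
  states[, idx, drop = FALSE]
}

# smooth dendrite centerline spanning the frame; returns dense samples
# with arclength (um) and unit normals, plus pixels-per-um
dendrite_curve <- function(params, seed = NULL, wobble_px = 25) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$image_px
  px_um <- params$pixel_nm / 1000
  ctrl_c <- seq(4, n - 3, length.out = 6)
  ctrl_r <- n / 2 + cumsum(stats::rnorm(6, 0, wobble_px))
  ctrl_r <- ctrl_r - mean(ctrl_r) + n / 2
  ctrl_r <- pmin(pmax(ctrl_r, n * 0.2), n * 0.8)
  sp <- stats::spline(ctrl_c, ctrl_r, n = 4L * n)
  cols <- sp$x
  rows <- sp$y
  seg <- sqrt(diff(cols)^2 + diff(rows)^2) * px_um
  arclen <- c(0, cumsum(seg))
  # unit normals (perpendicular to the local tangent)
  tc <- c(diff(cols), utils::tail(diff(cols), 1))
  tr <- c(diff(rows), utils::tail(diff(rows), 1))
  tn <- sqrt(tc^2 + tr^2)
  list(rows = rows, cols = cols, arclen_um = arclen,
       normal_r = -tc / tn, normal_c = tr / tn, px_um = px_um)
}

# per-synapse static render attributes (side, neck length, head radius)
synapse_attributes <- function(n, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    side = sample(c(-1, 1), n, replace = TRUE),
    neck_um = stats::runif(n, params$neck_range_um[1], params$neck_range_um[2]),
    radius_um = pmax(stats::rnorm(n, params$spine_radius_um, 0.1), 0.15))
}

disc_range <- function(x0, rad, n) {
  lo <- max(1L, as.integer(floor(x0 - rad)))
  hi <- min(n, as.integer(ceiling(x0 + rad)))
  if (lo > hi) integer(0) else lo:hi
}

paint_disc <- function(canvas, r0, c0, rad, values) {
  rs <- disc_range(r0, rad, nrow(canvas))
  cs <- disc_range(c0, rad, ncol(canvas))
  if (length(rs) == 0L || length(cs) == 0L) return(canvas)
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  sel <- d2 <= rad^2
  canvas[rs, cs][sel] <- values(sum(sel))
  canvas
}

disc_mask <- function(n1, n2, r0, c0, rad) {
  m <- matrix(FALSE, n1, n2)
  rs <- disc_range(r0, rad, n1)
  cs <- disc_range(c0, rad, n2)
  if (length(rs) == 0L || length(cs) == 0L) return(m)
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  m[rs, cs] <- d2 <= rad^2
  m
}

#' Render one simulated frame
#'
#' Paints the dendrite tube and the currently-on spines (disc heads with
#' one-pixel necks), clips to `[0, intensity_max]`, blurs with the Gaussian
#' PSF and applies Poisson noise. Ground-truth masks refer to the painted
#' (pre-PSF) geometry.
#'
#' @param curve Centerline from the internal geometry generator.
#' @param positions_um Arclength positions of the on sites.
#' @param attrs Per-site attributes (side, neck length, head radius) for
#'   the on sites.
#' @param params A [render_params()].
#' @param seed Optional integer seed.
#' @param n_boutons Number of off-branch bright blobs (axons/boutons
#'   crossing the field of view) to add; they are not spines and do not
#'   appear in the spine ground truth.
#' @return List with `image` ([image2d()], final frame), `noiseless`
#'   (post-PSF, pre-noise matrix), `paint` (pre-PSF matrix), and `truth`
#'   (centers, head label matrix, dendrite/neck masks).
#' @export
render_frame <- function(curve, positions_um, attrs, params = render_params(),
                         seed = NULL, n_boutons = 0L) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$image_px
  px_um <- curve$px_um
  half_w <- params$dendrite_width_um / 2 / px_um
  # dendrite mask from distance to the rasterized centerline
  center_mask <- matrix(FALSE, n, n)
  ri <- pmin(pmax(round(curve$rows), 1L), n)
  ci <- pmin(pmax(round(curve$cols), 1L), n)
  center_mask[cbind(ri, ci)] <- TRUE
  dist_to_axis <- ebi_mat(EBImage::distmap(EBImage::Image(1 - center_mask)))
  dmask <- dist_to_axis <= half_w
  paint <- matrix(0, n, n)
  paint[dmask] <- stats::rnorm(sum(dmask), params$dendrite_mean,
                               params$dendrite_sd)
  k <- length(positions_um)
  head_labels <- matrix(0L, n, n)
  neck_mask <- matrix(FALSE, n, n)
  centers <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("row", "col")))
  if (k > 0L) {
    for (i in seq_len(k)) {
      j <- findInterval(positions_um[i], curve$arclen_um, all.inside = TRUE)
      ax <- c(curve$rows[j], curve$cols[j])
      nrm <- c(curve$normal_r[j], curve$normal_c[j]) * attrs$side[i]
      rad <- attrs$radius_um[i] / px_um
      off <- (params$dendrite_width_um / 2 + attrs$neck_um[i] +
                attrs$radius_um[i]) / px_um
      hc <- ax + nrm * off
      # heads pushed outside a small frame are painted clipped but are not
      # ground-truth detectable centers
      centers[i, ] <- if (all(hc >= 1) && all(hc <= n)) hc else NA_real_
      # neck: one-pixel line from shaft surface to head surface
      s0 <- params$dendrite_width_um / 2 / px_um
      s1 <- off - rad
      if (s1 > s0) {
        tpts <- seq(s0, s1, by = 0.5)
        pr <- pmin(pmax(round(ax[1] + nrm[1] * tpts), 1L), n)
        pc <- pmin(pmax(round(ax[2] + nrm[2] * tpts), 1L), n)
        neck_mask[cbind(pr, pc)] <- TRUE
      }
      hm <- disc_mask(n, n, hc[1], hc[2], rad)
      head_labels[hm] <- i
    }
    spine_mask <- head_labels > 0L | neck_mask
    paint[spine_mask] <- stats::rnorm(sum(spine_mask), params$spine_mean,
                                      params$spine_sd)
  }
  bouton_centers <- NULL
  if (n_boutons > 0L) {
    far <- dist_to_axis > (half_w + 3 / px_um)
    cand <- which(far, arr.ind = TRUE)
    pick <- cand[sample.int(nrow(cand), n_boutons), , drop = FALSE]
    for (b in seq_len(n_boutons)) {
      rad <- stats::runif(1, 0.15, 0.35) / px_um
      paint <- paint_disc(paint, pick[b, 1], pick[b, 2], rad,
                          function(m) stats::rnorm(m, params$spine_mean,
                                                   params$spine_sd))
    }
    bouton_centers <- pick
  }
  paint <- pmin(pmax(paint, 0), params$intensity_max)
  sigma_px <- params$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / params$pixel_nm
  noiseless <- ebi_mat(EBImage::gblur(EBImage::Image(paint),
                                        sigma = sigma_px))
  noiseless <- pmax(noiseless, 0)
  if (is.finite(params$noise_gamma)) {
    g <- params$noise_gamma
    img <- stats::rpois(length(noiseless), g * as.numeric(noiseless)) / g
    img <- matrix(img, n, n)
  } else {
    img <- noiseless
  }
  geom <- voxel_geometry(px_um, px_um, bit_depth = 12L)
  img <- pmin(img, 2^12 - 1)
  list(image = image2d(img, geom), noiseless = noiseless, paint = paint,
       truth = list(centers = centers, head_labels = head_labels,
                    neck_mask = neck_mask, dendrite_mask = dmask,
                    bouton_centers = bouton_centers,
                    attrs = if (k > 0L) attrs else NULL))
}

#' Simulate a dendritic branch over time
#'
#' Composes synapse placement, Markov turnover, keyframe sampling and frame
#' rendering into a fully ground-truthed synthetic time series.
#'
#' @param length_um Branch length carrying synapses.
#' @param density_per_um Potential-synapse density.
#' @param turnover A [turnover_params()].
#' @param render A [render_params()].
#' @param seed Master seed; all randomness derives from it.
#' @param n_boutons Off-branch blobs per frame (see [render_frame()]).
#' @return An object of class `simulated_dendrite` with fields `curve`,
#'   `positions_um`, `attrs`, `states` (site x keyframe), `frames` (list of
#'   render results), `days` (nominal acquisition day per keyframe) and
#'   `true_counts`.
#' @export
simulate_timeseries <- function(length_um = 30, density_per_um = 2.56,
                                turnover = turnover_params(),
                                render = render_params(), seed = 1L,
                                n_boutons = 0L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max,
                    4L + turnover$n_keyframes)
  curve <- dendrite_curve(render, seed = sub[1])
  usable <- min(length_um, max(curve$arclen_um))
  positions <- place_synapses(usable, density_per_um, seed = sub[2])
  attrs <- synapse_attributes(length(positions), render, seed = sub[3])
  tp <- turnover
  tp$seed <- sub[4]
  chain <- simulate_states(length(positions), tp)
  states <- keyframe_states(chain, turnover$n_keyframes)
  frames <- vector("list", turnover$n_keyframes)
  for (f in seq_len(turnover$n_keyframes)) {
    on <- states[, f] == 1L
    frames[[f]] <- render_frame(curve, positions[on],
                                attrs[on, , drop = FALSE], render,
                                seed = sub[4L + f], n_boutons = n_boutons)
  }
  structure(list(curve = curve, length_um = usable,
                 positions_um = positions, attrs = attrs, states = states,
                 frames = frames,
                 days = 75 * (seq_len(turnover$n_keyframes) - 1) /
                   (turnover$n_keyframes - 1),
                 true_counts = colSums(states == 1L),
                 turnover = turnover, render = render, seed = seed),
            class = "simulated_dendrite")
}

#' @export
print.simulated_dendrite <- function(x, ...) {
  cat(sprintf(
    "<simulated_dendrite> %.1f um, %d sites, %d keyframes, counts %d-%d\n",
    x$length_um, length(x$positions_um), ncol(x$states),
    min(x$true_counts), max(x$true_counts)))
  invisible(x)
}

#' Convert simulated frames to a time series of single-slice stacks
#'
#' @param sim A [simulate_timeseries()] result.
#' @return A [timeseries()].
#' @export
as_timeseries <- function(sim) {
  stopifnot(inherits(sim, "simulated_dendrite"))
  timeseries(lapply(sim$frames, function(f)
    zstack(f$image$data, f$image$geometry)))
}

#' Render a 3D spine phantom z-stack
#'
#' Sphere head, cylinder neck and tube dendrite (plus an optional
#' distractor tube that is closer to the head in Euclidean terms but not
#' intensity-connected to it), using the 2D intensity/PSF/noise model
#' extended to 3D. The ground-truth neck length is the gap between the
#' head surface and the dendrite surface, by construction.
#'
#' @param head_radius_um Spine-head radius.
#' @param neck_length_um Neck length (head surface to dendrite surface).
#' @param neck_tilt_deg Tilt of the neck axis out of the optical plane.
#' @param dendrite_radius_um Dendrite tube radius.
#' @param neck_radius_um Neck cylinder radius.
#' @param distractor_gap_um Gap between head surface and distractor tube
#'   surface, or `NULL` for no distractor.
#' @param geometry [voxel_geometry()] of the volume.
#' @param dims Volume dimensions (rows, cols, slices).
#' @param params A [render_params()] (intensity and PSF model).
#' @param seed Optional seed (used when noise is enabled).
#' @return List with `stack` ([zstack()]), `noiseless` array, and `truth`
#'   (head center/mask, neck mask/length, dendrite and distractor masks).
#' @export
make_phantom_zstack <- function(head_radius_um = 0.3, neck_length_um = 1.0,
                                neck_tilt_deg = 0, dendrite_radius_um = 0.4,
                                neck_radius_um = 0.1,
                                distractor_gap_um = NULL,
                                geometry = voxel_geometry(0.1, 0.1, 0.2, 12L),
                                dims = c(72L, 72L, 21L),
                                params = render_params(noise_gamma = Inf),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  # physical coordinates of voxel centers
  ry <- (seq_len(n1) - 1) * geometry$dy
  cx <- (seq_len(n2) - 1) * geometry$dx
  zz <- (seq_len(n3) - 1) * geometry$dz
  Y <- array(rep(ry, times = n2 * n3), c(n1, n2, n3))
  X <- array(rep(rep(cx, each = n1), times = n3), c(n1, n2, n3))
  Z <- array(rep(zz, each = n1 * n2), c(n1, n2, n3))
  # dendrite tube along x at 70% depth of the frame, mid slice
  ay <- ry[round(n1 * 0.7)]
  az <- zz[ceiling(n3 / 2)]
  dend <- sqrt((Y - ay)^2 + (Z - az)^2) <= dendrite_radius_um
  theta <- neck_tilt_deg * pi / 180
  u <- c(-cos(theta), 0, sin(theta))  # (y, x, z) direction, away from tube
  a0 <- c(ay, cx[ceiling(n2 / 2)], az)
  off <- dendrite_radius_um + neck_length_um + head_radius_um
  hc <- a0 + u * off
  if (hc[1] < head_radius_um || hc[3] < 0 || hc[3] > max(zz))
    stop("phantom geometry does not fit the volume")
  head <- sqrt((Y - hc[1])^2 + (X - hc[2])^2 + (Z - hc[3])^2) <=
    head_radius_um
  # neck cylinder between the two surfaces
  p0 <- a0 + u * dendrite_radius_um
  p1 <- a0 + u * (dendrite_radius_um + neck_length_um)
  seg <- p1 - p0
  L2 <- sum(seg^2)
  tpar <- if (L2 > 0)
    pmin(pmax(((Y - p0[1]) * seg[1] + (X - p0[2]) * seg[2] +
                 (Z - p0[3]) * seg[3]) / L2, 0), 1) else 0
  dneck <- sqrt((Y - (p0[1] + tpar * seg[1]))^2 +
                  (X - (p0[2] + tpar * seg[2]))^2 +
                  (Z - (p0[3] + tpar * seg[3]))^2)
  neck <- dneck <= neck_radius_um & neck_length_um > 0
  distractor <- array(FALSE, dims)
  if (!is.null(distractor_gap_um)) {
    dy2 <- hc[1] - (head_radius_um + distractor_gap_um +
                      dendrite_radius_um * 0.5)
    distractor <- sqrt((Y - dy2)^2 + (Z - az)^2) <= dendrite_radius_um * 0.5
  }
  paint <- array(0, dims)
  tube <- dend | distractor
  paint[tube] <- stats::rnorm(sum(tube), params$dendrite_mean,
                              params$dendrite_sd)
  sp <- head | neck
  paint[sp] <- stats::rnorm(sum(sp), params$spine_mean, params$spine_sd)
  paint <- pmin(pmax(paint, 0), params$intensity_max)
  sig_um <- params$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / 1000
  noiseless <- gaussian_blur3d(paint, c(sig_um / geometry$dy,
                                        sig_um / geometry$dx,
                                        sig_um / geometry$dz))
  if (is.finite(params$noise_gamma)) {
    g <- params$noise_gamma
    img <- array(stats::rpois(length(noiseless),
                              g * pmax(as.numeric(noiseless), 0)) / g, dims)
  } else {
    img <- noiseless
  }
  img <- pmin(img, 2^geometry$bit_depth - 1)
  head_center_vox <- c(hc[1] / geometry$dy, hc[2] / geometry$dx,
                       hc[3] / geometry$dz) + 1
  list(stack = zstack(img, geometry), noiseless = noiseless,
       truth = list(head_center_um = hc, head_center_vox = head_center_vox,
                    head_mask = head, neck_mask = neck,
                    neck_length_um = neck_length_um,
                    dendrite_mask = dend, distractor_mask = distractor))
}
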