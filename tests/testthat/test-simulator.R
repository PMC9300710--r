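test_that("synapse placement is a Poisson process on the branch", {
  expect_length(place_synapses(10, 0, seed = 1), 0L)
  pos <- place_synapses(30, 2.56, seed = 2)
  expect_true(all(diff(pos) >= 0))
  expect_true(all(pos >= 0 & pos <= 30))
  counts <- vapply(1:1000, function(s)
    length(place_synapses(30, 2.56, seed = s)), numeric(1))
  mu <- 2.56 * 30
  se <- sqrt(mu / 1000)  # Poisson mean over 1000 replicates
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("turnover chains respect their transition probabilities", {
  # absorbing off state
  p0 <- turnover_params(p_on = 0, p_off = 0.5, steps = 50, seed = 3)
  s0 <- simulate_states(20, p0)
  expect_true(all(s0[, 40:50] == 0L))
  # deterministic flip
  p1 <- turnover_params(p_on = 1, p_off = 1, steps = 10, seed = 3)
  s1 <- simulate_states(5, p1)
  expect_true(all(abs(s1[, -1] - s1[, -10]) == 1L))
  # stationary fraction at the default rates
  pd <- turnover_params(seed = 7)
  sd_ <- simulate_states(500, pd)
  chain_means <- rowMeans(sd_)
  se <- stats::sd(chain_means) / sqrt(500)
  expect_lt(abs(mean(chain_means) - 1e-3 / (1e-3 + 4.1e-3)), 3 * se)
})

test_that("empirical transition frequencies recover the printed rates", {
  pd <- turnover_params(seed = 13)
  s <- simulate_states(500, pd)
  prev <- s[, -ncol(s)]
  nxt <- s[, -1]
  n_off <- sum(prev == 0L)
  n_on <- sum(prev == 1L)
  p_on_hat <- sum(prev == 0L & nxt == 1L) / n_off
  p_off_hat <- sum(prev == 1L & nxt == 0L) / n_on
  expect_lt(abs(p_on_hat - 1e-3), 3 * sqrt(1e-3 * (1 - 1e-3) / n_off))
  expect_lt(abs(p_off_hat - 4.1e-3),
            3 * sqrt(4.1e-3 * (1 - 4.1e-3) / n_on))
})

test_that("keyframe sampling picks evenly spaced steps incl. endpoints", {
  s <- matrix(rep(1:2000, each = 2), 2, byrow = FALSE)
  dimnames(s) <- NULL
  ks <- keyframe_states(s, 26)
  # stride floor(2000/25) = 80: steps 1, 81, ..., 2001 capped at 2000
  expect_equal(ks[1, ], pmin((0:25) * 80 + 1, 2000))
  # identity when every step is a keyframe
  small <- matrix(sample(0:1, 30, replace = TRUE), 3)
  expect_equal(keyframe_states(small, 10), small)
  # static chain: identical columns
  static <- matrix(1L, 4, 100)
  kk <- keyframe_states(static, 5)
  expect_true(all(kk == 1L))
  expect_error(keyframe_states(small, 1), "n_keyframes")
})

test_that("rendered frames follow the painted intensity model", {
  sim <- cached_sim()
  fr <- sim$frames[[1]]
  # painted values live in [0, 2000]
  expect_gte(min(fr$paint), 0)
  expect_lte(max(fr$paint), 2000)
  expect_gte(min(fr$noiseless), 0)
  expect_lte(max(fr$noiseless), 2000)
  # dendrite paint is N(1000, 100): its mean is within 3 SE of 1000
  dend_only <- fr$truth$dendrite_mask & fr$truth$head_labels == 0L &
    !fr$truth$neck_mask
  v <- fr$paint[dend_only]
  expect_lt(abs(mean(v) - 1000), 3 * 100 / sqrt(length(v)))
  # no synapses: only the dendrite is painted
  curve <- sim$curve
  empty <- render_frame(curve, numeric(0),
                        sim$attrs[0, , drop = FALSE],
                        render_params(noise_gamma = Inf))
  expect_equal(sum(empty$truth$head_labels), 0L)
  expect_true(all(empty$paint[!empty$truth$dendrite_mask] == 0))
})

test_that("simulations are reproducible and dynamic", {
  a <- simulate_timeseries(seed = 5, turnover = turnover_params(n_keyframes = 3),
                           render = render_params(image_px = 128L))
  b <- simulate_timeseries(seed = 5, turnover = turnover_params(n_keyframes = 3),
                           render = render_params(image_px = 128L))
  for (f in 1:3)
    expect_identical(a$frames[[f]]$image$data, b$frames[[f]]$image$data)
  # nonzero rates make the count series non-constant for most seeds
  varying <- vapply(1:5, function(s) {
    sim <- simulate_timeseries(seed = s, render = render_params(image_px = 64L),
                               turnover = turnover_params(n_keyframes = 26))
    length(unique(sim$true_counts)) > 1
  }, logical(1))
  expect_true(any(varying))
})

test_that("isolated ground-truth centers sit on intensity maxima of the
           render", {
  sim <- cached_sim()
  fr <- sim$frames[[2]]
  ctr <- stats::na.omit(fr$truth$centers)
  img <- fr$noiseless
  px_um <- fr$image$geometry$dx
  for (i in seq_len(nrow(ctr))) {
    # overlapping spines merge into one blob; only isolated heads are
    # expected to carry their own maximum
    if (nrow(ctr) > 1) {
      dmin <- min(sqrt((ctr[-i, 1] - ctr[i, 1])^2 +
                         (ctr[-i, 2] - ctr[i, 2])^2)) * px_um
      if (dmin < 0.8) next
    }
    r <- round(ctr[i, 1]); c <- round(ctr[i, 2])
    box <- img[max(1, r - 2):min(nrow(img), r + 2),
               max(1, c - 2):min(ncol(img), c + 2)]
    p <- which(box == max(box), arr.ind = TRUE)[1, ]
    pr <- max(1, r - 2) + p[1] - 1L
    pc <- max(1, c - 2) + p[2] - 1L
    # the brightest pixel within 2 px of the center is a 3x3 local max
    nb <- img[max(1, pr - 1):min(nrow(img), pr + 1),
              max(1, pc - 1):min(ncol(img), pc + 1)]
    expect_equal(img[pr, pc], max(nb))
  }
})

test_that("3D phantoms are constructed to specification", {
  ph <- make_phantom_zstack(neck_length_um = 1.5, seed = 3)
  expect_equal(ph$truth$neck_length_um, 1.5)
  expect_true(any(ph$truth$head_mask))
  expect_true(any(ph$truth$neck_mask))
  # zero neck: tangent sphere, no neck voxels
  ph0 <- make_phantom_zstack(neck_length_um = 0, seed = 3)
  expect_equal(sum(ph0$truth$neck_mask), 0L)
  expect_equal(ph0$truth$neck_length_um, 0)
  # geometry that cannot fit errors out
  expect_error(make_phantom_zstack(neck_length_um = 30), "fit")
  # cross-module fixture: a known subpixel shift is recovered
  base <- apply(ph$stack$data, c(1, 2), max)
  shifted <- pmax(spinetrack:::fourier_shift2d(base, 0.75, -1.25), 0)
  est <- spinetrack:::phase_correlate(base, shifted, 100)
  expect_lt(max(abs(c(est$dy - 0.75, est$dx + 1.25))), 0.05)
})

test_that("training patches are centered on their ground-truth sites", {
  sim <- simulate_timeseries(seed = 101,
                             turnover = turnover_params(n_keyframes = 2),
                             render = render_params(noise_gamma = 4),
                             n_boutons = 2)
  patches <- patch_training_set(sim, n_per_class = 30, n_classes = 9L,
                                seed = 6)
  labels <- vapply(patches, `[[`, integer(1), "label")
  expect_gte(length(unique(labels)), 8L)
  # class-1 patches sit within 1 px of a true spine center
  ctrs <- lapply(sim$frames, function(f) stats::na.omit(f$truth$centers))
  for (p in patches[labels == 1L]) {
    ok <- any(vapply(ctrs, function(cc)
      nrow(cc) > 0 && min((cc[, 1] - p$center[1])^2 +
                            (cc[, 2] - p$center[2])^2) <= 2, logical(1)))
    expect_true(ok)
  }
  # class-9 patches contain no ground-truth foreground of their own frame
  # in their central half
  truth_fg <- lapply(sim$frames, function(f)
    f$truth$dendrite_mask | f$truth$head_labels > 0L | f$truth$neck_mask)
  for (p in patches[labels == 9L]) {
    side <- 47L  # round(3.4 / 0.072) forced odd
    q <- side %/% 4
    fg <- truth_fg[[p$frame]]
    rs <- max(1, p$center[1] - q):min(nrow(fg), p$center[1] + q)
    cs <- max(1, p$center[2] - q):min(ncol(fg), p$center[2] + q)
    expect_false(any(fg[rs, cs]))
  }
})
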