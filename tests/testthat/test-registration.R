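test_that("shift estimation recovers integer and subpixel translations", {
  sim <- cached_sim()
  a <- sim$frames[[1]]$image$data
  # self-registration
  e0 <- spinetrack:::phase_correlate(a, a, 100)
  expect_equal(c(e0$dy, e0$dx), c(0, 0))
  expect_lt(e0$peak_error, 1e-6)
  # exact integer circular shift
  b <- a[c(510:512, 1:509), c(3:512, 1:2)]  # shifted by (+3, -2)
  e1 <- spinetrack:::phase_correlate(a, b, 1)
  expect_equal(c(e1$dy, e1$dx), c(3, -2))
  # subpixel Fourier-applied shift, upsample 100
  b2 <- pmax(spinetrack:::fourier_shift2d(a, 1.25, -0.5), 0)
  e2 <- spinetrack:::phase_correlate(a, b2, 100)
  expect_lt(max(abs(c(e2$dy - 1.25, e2$dx + 0.5))), 0.05)
  # anti-symmetry within 1/upsample
  e3 <- spinetrack:::phase_correlate(b2, a, 100)
  expect_lt(abs(e2$dy + e3$dy), 0.011)
  expect_lt(abs(e2$dx + e3$dx), 0.011)
  expect_error(spinetrack:::phase_correlate(a * 0, a, 1), "degenerate")
})

test_that("global registration aligns stacks laterally and in z", {
  set.seed(3)
  geom <- voxel_geometry(0.1, 0.1, 0.3, 12L)
  # fixed lateral structure with a z-dependent intensity profile, so the
  # MIP is insensitive to slice offsets while slice correlation is not
  arr <- array(0, c(48, 48, 7))
  for (z in 1:7)
    arr[, , z] <- gaussian_blob(48, c(24, 20), 3, 300 + 80 * z) +
      gaussian_blob(48, c(12, 30), 2, 600 - 60 * z)
  ref <- zstack(arr, geom)
  movd <- array(0, dim(arr))
  for (z in 1:7) movd[, , z] <- spinetrack:::fourier_shift2d(arr[, , z],
                                                             2.5, -1.5)
  mov <- zstack(pmax(spinetrack:::shift_slices(movd, 1L), 0), geom)
  res <- global_register(ref, mov, upsample = 50L)
  expect_lt(abs(res$shift$dy - 2.5), 0.05)
  expect_lt(abs(res$shift$dx + 1.5), 0.05)
  expect_equal(res$shift$dz, 1L)
  # registering a stack to itself is the identity transform (within the
  # upsampled grid resolution)
  self <- global_register(ref, ref, upsample = 50L)
  expect_lte(max(abs(c(self$shift$dy, self$shift$dx))), 1 / 50 + 1e-9)
  expect_equal(self$shift$dz, 0L)
})

test_that("NMI behaves as a dependence measure", {
  set.seed(5)
  a <- matrix(runif(128^2), 128)
  b <- matrix(runif(128^2), 128)
  expect_equal(normalized_mutual_information(a, a), 2)
  expect_lt(abs(normalized_mutual_information(a, b, 32) - 1), 0.05)
  perm <- a[sample(nrow(a)), ]
  expect_lt(normalized_mutual_information(a, perm),
            normalized_mutual_information(a, a))
  expect_equal(normalized_mutual_information(matrix(3, 8, 8),
                                             matrix(3, 8, 8)), 2)
})

test_that("local ROI registration finds the translated spine", {
  sim <- cached_sim()
  frame <- sim$frames[[1]]$image
  ctr <- round(stats::na.omit(sim$frames[[1]]$truth$centers)[1, ])
  win <- roi_window(ctr, 15, 1)
  prev <- spinetrack:::crop_roi(frame, win)
  # radius 0 returns the input window
  w0 <- local_register_roi(prev, frame, win, search_radius = 0)
  expect_equal(w0$center, win$center)
  # current frame translated by (2, 1): center moves by (2, 1), matching
  # an exhaustive NMI scan over all offsets
  shifted <- image2d(pmax(spinetrack:::fourier_shift2d(frame$data, 2, 1), 0),
                     frame$geometry)
  w1 <- local_register_roi(prev, shifted, win, search_radius = 4)
  expect_equal(w1$center, win$center + c(2, 1))
  best <- -Inf
  for (dy in -4:4) for (dx in -4:4) {
    cand <- spinetrack:::crop_roi(shifted,
                                  roi_window(win$center + c(dy, dx), 15, 1))
    v <- normalized_mutual_information(prev, cand)
    if (v > best) { best <- v; off <- c(dy, dx) }
  }
  expect_equal(w1$center - win$center, off)
  # the window never moves beyond the search radius
  w2 <- local_register_roi(prev, shifted, win, search_radius = 1)
  expect_lte(max(abs(w2$center - win$center)), 1)
  expect_error(local_register_roi(prev, frame, roi_window(ctr, 600, 1), 2),
               "larger than image")
})

test_that("chained registration recovers accumulated drift", {
  sim <- cached_sim()
  base <- sim$frames[[1]]$image$data
  geom <- sim$frames[[1]]$image$geometry
  drift <- list(c(0, 0), c(1.5, -1), c(3, -2))
  stacks <- lapply(drift, function(d)
    zstack(pmax(spinetrack:::fourier_shift2d(base, d[1], d[2]), 0), geom))
  reg <- register_timeseries(timeseries(stacks), upsample = 50L,
                             z_correct = FALSE)
  expect_equal(reg$shifts$dy, c(0, 1.5, 3), tolerance = 0.05)
  expect_equal(reg$shifts$dx, c(0, -1, -2), tolerance = 0.05)
  # after registration every frame matches the first
  for (t in 2:3) {
    d <- reg$series$stacks[[t]]$data - reg$series$stacks[[1]]$data
    expect_lt(mean(abs(d)) / mean(base), 0.02)
  }
})
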