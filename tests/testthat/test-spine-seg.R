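test_that("seed extraction finds maxima regions plus the detected center", {
  blob <- gaussian_blob(41, c(21, 21), 4, 150, offset = 10)
  seeds <- find_seeds(blob, c(21, 21), h = 30)
  expect_gte(max(seeds), 1L)
  peak_label <- seeds[21, 21]
  expect_gt(peak_label, 0L)
  # flat ROI: only the injected center seed
  flat <- matrix(7, 31, 31)
  sf <- find_seeds(flat, c(10, 12))
  expect_equal(sum(sf > 0), 1L)
  expect_equal(sf[10, 12], 1L)
  # prominence rule: blob of prominence 100 survives h = 50, blob of 30
  # does not
  two <- gaussian_blob(61, c(18, 18), 3, 100) +
    gaussian_blob(61, c(45, 45), 3, 30)
  s2 <- find_seeds(two, c(30, 30), h = 50)
  labs_at <- c(s2[18, 18], s2[45, 45], s2[30, 30])
  expect_gt(labs_at[1], 0L)
  expect_equal(labs_at[2], 0L)
  expect_gt(labs_at[3], 0L)
})

test_that("seeded watershed respects seeds, boundaries and the mock
           fallback", {
  geom <- voxel_geometry(0.072)
  blob <- gaussian_blob(41, c(21, 21), 5, 200, offset = 5)
  seeds <- matrix(0L, 41, 41)
  seeds[21, 21] <- 1L
  ws <- watershed_segment(blob, seeds, c(21, 21),
                          boundary = matrix(TRUE, 41, 41))
  # single seed, boundary = full ROI: one catchment covers everything
  expect_true(all(ws$labels == 1L))
  # two seeds on two separated blobs: two disjoint regions
  two <- gaussian_blob(61, c(18, 18), 4, 200) +
    gaussian_blob(61, c(45, 45), 4, 200)
  seeds2 <- matrix(0L, 61, 61)
  seeds2[18, 18] <- 1L
  seeds2[45, 45] <- 2L
  ws2 <- watershed_segment(two, seeds2, c(18, 18),
                           boundary = two > 20)
  expect_equal(ws2$labels[18, 18], 1L)
  expect_equal(ws2$labels[45, 45], 2L)
  expect_equal(sum(ws2$labels == 1L & ws2$labels == 2L), 0L)
  # dim spine below the Otsu threshold triggers the circular mock boundary
  dim_roi <- gaussian_blob(41, c(21, 21), 3, 30, offset = 5) +
    gaussian_blob(41, c(5, 5), 2, 800)
  seeds3 <- find_seeds(dim_roi, c(21, 21), h = 10)
  ws3 <- watershed_segment(dim_roi, seeds3, c(21, 21), geometry = geom,
                           mock_radius_um = 0.6)
  expect_equal(ws3$provenance, "mock-boundary")
  region <- ws3$labels == ws3$labels[21, 21]
  expect_gt(sum(region), 0)
  d <- sqrt((row(region)[region] - 21)^2 + (col(region)[region] - 21)^2)
  expect_lte(max(d), 0.6 / geom$dx + 1)
})

test_that("cluster refinement trims dim halos but keeps uniform discs", {
  # homogeneous disc: nothing to exclude
  disc <- matrix(10, 41, 41)
  sel <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+") <= 100
  disc[sel] <- 200
  ref <- refine_segmentation(disc, sel, c(21, 21), f = 0.5)
  expect_gte(spinetrack:::dice(ref$mask, sel), 0.99)
  # bright core + dim annulus: refinement keeps the core
  ring <- matrix(10, 41, 41)
  core <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+") <= 25
  annulus <- !core & (outer((1:41 - 21)^2, (1:41 - 21)^2, "+") <= 100)
  ring[core] <- 200
  ring[annulus] <- 60
  ref2 <- refine_segmentation(ring, core | annulus, c(21, 21), f = 0.5)
  expect_gte(spinetrack:::dice(ref2$mask, core), 0.85)
  # the refined mask is always a subset of the region, contains its seed
  # and is connected
  expect_true(all(ref2$mask[!(core | annulus)] == FALSE))
  expect_true(ref2$mask[21, 21])
  lab <- spinetrack:::ebi_mat(EBImage::bwlabel(ref2$mask))
  expect_equal(max(lab), 1)
})

test_that("refinement never grows beyond the watershed region on
           simulated spines", {
  sim <- cached_sim()
  fr <- sim$frames[[1]]
  ctr <- stats::na.omit(fr$truth$centers)
  for (i in seq_len(min(nrow(ctr), 6))) {
    hm <- segment_spine_frame(fr$image, ctr[i, ], half_size = 25)
    expect_true(all(hm$watershed_mask[hm$mask]),
                info = sprintf("spine %d", i))
  }
})

test_that("segmentation is invariant to intensity scaling", {
  fr <- simulate_timeseries(seed = 77,
                            turnover = turnover_params(n_keyframes = 2),
                            render = render_params(noise_gamma = Inf))$frames[[1]]
  ctr <- stats::na.omit(fr$truth$centers)[2, ]
  ref_mask <- NULL
  for (alpha in c(0.25, 0.5, 0.75, 1)) {
    img <- image2d(fr$image$data * alpha, fr$image$geometry)
    hm <- segment_spine_frame(img, ctr, half_size = 25)
    if (is.null(ref_mask)) ref_mask <- hm$mask
    expect_gte(spinetrack:::dice(hm$mask, ref_mask), 0.95)
  }
})

test_that("per-spine time series tracks drift and shrinkage", {
  geom <- voxel_geometry(0.1)
  mk_frame <- function(center, radius) {
    img <- matrix(15, 96, 96)
    tube <- abs(row(img) - 80) <= 5
    img[tube] <- 900
    sel <- outer((1:96 - center[1])^2, (1:96 - center[2])^2,
                 "+") <= radius^2
    img[sel] <- 1500
    zstack(img, geom)
  }
  # static spine: identical masks at every time point
  static <- timeseries(lapply(1:5, function(t) mk_frame(c(40, 48), 6)))
  masks <- segment_spine_timeseries(static, c(40, 48), half_size = 20)
  for (t in 2:5) expect_identical(masks[[t]]$mask, masks[[1]]$mask)
  # drifting spine: mask center follows within 2 px
  drift <- timeseries(lapply(0:4, function(t) mk_frame(c(40, 42 + t), 6)))
  md <- segment_spine_timeseries(drift, c(40, 42), half_size = 20)
  for (t in 1:5) {
    px <- which(md[[t]]$mask, arr.ind = TRUE)
    cm <- colMeans(px)
    expect_lte(max(abs(cm - c(40, 41 + t))), 2)
  }
  # shrinking spine: areas decrease across the change
  radii <- c(8, 8, 6, 5, 4)
  shrink <- timeseries(lapply(radii, function(r) mk_frame(c(40, 48), r)))
  ms <- segment_spine_timeseries(shrink, c(40, 48), half_size = 20)
  areas <- vapply(ms, function(m) m$area_px, integer(1))
  expect_true(all(diff(areas) <= 0))
  expect_lt(areas[5], areas[1])
})
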