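# straight horizontal tube with optional attached discs (spines)
tube_image <- function(n = 160, width = 12, n_spines = 0, seed = 1) {
  set.seed(seed)
  img <- matrix(20, n, n)
  r0 <- n / 2
  tube <- abs(row(img) - r0) <= width / 2
  img[tube] <- 1000 + stats::rnorm(sum(tube), 0, 30)
  centers <- NULL
  if (n_spines > 0) {
    cols <- round(seq(20, n - 20, length.out = n_spines))
    for (i in seq_len(n_spines)) {
      side <- if (i %% 2 == 0) 1 else -1
      ctr <- c(r0 + side * (width / 2 + 7), cols[i])
      sel <- outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2,
                   "+") <= 25
      img[sel] <- 1600 + stats::rnorm(sum(sel), 0, 30)
      # thin neck
      for (s in seq(0, width / 2 + 4, 0.5))
        img[round(r0 + side * s), cols[i]] <- 1600
      centers <- rbind(centers, ctr)
    }
  }
  list(image = image2d(img, voxel_geometry(0.1)), tube = tube,
       centers = centers)
}

test_that("Otsu threshold separates bimodal intensities and matches an
           exhaustive variance scan", {
  half <- c(rep(10, 500), rep(200, 500))
  th <- otsu_threshold(matrix(half, 25))
  expect_gt(th, 10)
  expect_lt(th, 200)
  set.seed(9)
  x <- c(stats::rnorm(1e4, 50, 5), stats::rnorm(1e4, 180, 10))
  x <- x[x > 0]
  m <- matrix(x[1:19600], 140)
  th2 <- otsu_threshold(m)
  expect_gt(th2, 80)
  expect_lt(th2, 150)
  # the objective is flat between well-separated modes, so argmax locations
  # can differ; the chosen threshold must achieve (almost) the oracle's
  # between-class variance
  bcv <- function(x, t) {
    w0 <- mean(x <= t)
    if (w0 == 0 || w0 == 1) return(0)
    w0 * (1 - w0) * (mean(x[x <= t]) - mean(x[x > t]))^2
  }
  expect_gte(bcv(as.numeric(m), th2),
             0.999 * bcv(as.numeric(m), otsu_scan(m)))
  # histogram-shift covariance
  th3 <- otsu_threshold(m + 37)
  expect_lt(abs(th3 - th2 - 37), (max(m) - min(m)) / 256)
  expect_error(otsu_threshold(matrix(1, 5, 5)), "constant")
})

test_that("shaft segmentation removes attached spines", {
  ph <- tube_image(n_spines = 5, seed = 4)
  dm <- segment_dendrite(ph$image, median_window = 3L)
  expect_gte(spinetrack:::dice(dm$mask, ph$tube), 0.90)
  # no spine center survives inside the shaft mask
  for (i in seq_len(nrow(ph$centers)))
    expect_false(dm$mask[ph$centers[i, 1], ph$centers[i, 2]])
  # medial axis lies inside the original foreground
  ax <- round(as.matrix(dm$medial_axis[, c("row", "col")]))
  expect_gte(mean(ph$tube[ax]), 0.95)
})

test_that("a clean tube segments like its Otsu foreground", {
  ph <- tube_image(n_spines = 0)
  dm <- segment_dendrite(ph$image, median_window = 3L)
  filt <- median_filter2d(ph$image, 3L)
  fg <- filt$data > otsu_threshold(filt)
  expect_gte(spinetrack:::dice(dm$mask, fg), 0.95)
})

test_that("shaft radius is clamped and intensity is the pure median", {
  sim <- cached_sim()
  paint <- image2d(sim$frames[[1]]$paint, geom72())
  dm <- segment_dendrite(paint, median_window = 3L)
  r <- dm$local_radius
  med <- stats::median(r)
  expect_true(all(r >= med * 0.75 - 1e-9 & r <= med * 1.25 + 1e-9))
  # painted dendrite intensities are N(1000, 100): the median inside the
  # shaft stays in that regime
  expect_gt(dm$median_intensity, 900)
  expect_lt(dm$median_intensity, 1100)
  # the median is a pure statistic of the masked pixels
  expect_equal(dm$median_intensity,
               stats::median(paint$data[dm$mask]))
})

test_that("shaft mask never strays far from the medial axis", {
  ph <- tube_image(n_spines = 3, seed = 8)
  dm <- segment_dendrite(ph$image, median_window = 3L)
  ax <- as.matrix(dm$medial_axis[, c("row", "col")])
  px <- which(dm$mask, arr.ind = TRUE)
  maxr <- max(dm$local_radius)
  d2 <- vapply(seq_len(nrow(px)), function(i)
    min((ax[, 1] - px[i, 1])^2 + (ax[, 2] - px[i, 2])^2), numeric(1))
  expect_lte(sqrt(max(d2)), maxr + 1)
})

test_that("boundary adjustment grows, shrinks and approximately inverts", {
  blob <- gaussian_blob(60, c(30, 30), 8, 500, offset = 20)
  mask <- blob > 250
  img <- image2d(blob, voxel_geometry(0.1))
  expect_identical(adjust_boundary(mask, 0, img), mask)
  grown <- adjust_boundary(mask, 2, img)
  expect_true(all(mask[grown == FALSE] == FALSE))
  expect_true(all(grown[mask]))
  expect_gt(sum(grown), sum(mask))
  back <- adjust_boundary(grown, -2, img)
  expect_gte(spinetrack:::dice(back, mask), 0.95)
  expect_error(adjust_boundary(matrix(c(TRUE, rep(FALSE, 24)), 5), -8,
                               image2d(matrix(0, 5, 5),
                                       voxel_geometry(0.1))),
               "empty")
})
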