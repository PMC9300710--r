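# Independent oracles and shared fixtures for the test suite.

# Dijkstra on a 26-neighbour graph: independent oracle for fast-marching
# arrival times on small grids. Edge weight = physical step length /
# harmonic-mean speed of its endpoints.
dijkstra_26 <- function(speed, source, spacing = rep(1, length(dim(speed)))) {
  d <- dim(speed)
  was2d <- length(d) == 2L
  if (was2d) {
    d <- c(d, 1L)
    dim(speed) <- d
    spacing <- c(spacing, 1)
    source <- c(source, 1L)
  }
  n <- prod(d)
  idx <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  dist <- rep(Inf, n)
  visited <- rep(FALSE, n)
  dist[idx(source[1], source[2], source[3])] <- 0
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1,
                                dk = if (d[3] > 1) -1:1 else 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  wlen <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
                 (offs[, 3] * spacing[3])^2)
  for (rep in seq_len(n)) {
    u <- which.min(ifelse(visited, Inf, dist))
    if (!is.finite(dist[u])) break
    visited[u] <- TRUE
    k <- (u - 1L) %/% (d[1] * d[2]) + 1L
    rem <- (u - 1L) %% (d[1] * d[2])
    j <- rem %/% d[1] + 1L
    i <- rem %% d[1] + 1L
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      v <- idx(ii, jj, kk)
      if (visited[v]) next
      f <- 2 / (1 / speed[u] + 1 / speed[v])
      alt <- dist[u] + wlen[o] / f
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  if (was2d) matrix(dist, d[1], d[2]) else array(dist, d)
}

# exhaustive between-class-variance scan: oracle for the Otsu threshold
otsu_scan <- function(x, bins = 256L) {
  lo <- min(x); hi <- max(x)
  edges <- seq(lo, hi, length.out = bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), bins),
                bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  best <- -Inf; tbest <- NA
  for (t in 1:(bins - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1):bins] * mids[(t + 1):bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; tbest <- mids[t] }
  }
  tbest
}

# isotropic Gaussian blob image
gaussian_blob <- function(n, center, sigma, amplitude = 100, offset = 0) {
  r <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+")
  offset + amplitude * exp(-r / (2 * sigma^2))
}

geom72 <- function() voxel_geometry(0.072, 0.072, bit_depth = 12L)

# small deterministic low-noise simulation reused across tests
cached_sim <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_timeseries(
        seed = 202, turnover = turnover_params(n_keyframes = 3),
        render = render_params(noise_gamma = 4))
    val
  }
})

# small 2-class classifier trained on a simulator patch set (memoized)
cached_classifier <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sim <- simulate_timeseries(
        seed = 101, turnover = turnover_params(n_keyframes = 4),
        render = render_params(noise_gamma = 4), n_boutons = 3)
      patches <- patch_training_set(sim, n_per_class = 120, n_classes = 2L,
                                    seed = 5)
      val <<- train_classifier(patches,
                               classifier_config(n_classes = 2L,
                                                 small = TRUE, seed = 11L),
                               epochs = 8)
    }
    val
  }
})
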