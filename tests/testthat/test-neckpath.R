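test_that("speed maps normalize, erode and floor correctly", {
  geom <- voxel_geometry(0.1, 0.1, 0.1, 12L)
  cube <- zstack(array(500, c(11, 11, 5)), geom)
  sp0 <- build_speed_map(cube, erosion_radius = 0L)
  expect_equal(max(sp0$values), 1)
  expect_true(all(sp0$values == 1))
  # erosion_radius = 0 reproduces normalized intensity
  arr <- array(stats::runif(11 * 11 * 3, 1, 100), c(11, 11, 3))
  st <- zstack(arr, geom)
  spn <- build_speed_map(st, 0L)
  expect_equal(spn$values, pmax(arr / max(arr), 1e-3))
  # a 3 px line eroded by a radius-2 disk collapses while a wide block
  # survives (and sets the normalization)
  img <- array(0, c(31, 31, 1))
  img[10:12, , 1] <- 1000   # thin line
  img[20:31, , 1] <- 1000   # wide block
  sp_before <- build_speed_map(zstack(img, geom), 0L)
  spl <- build_speed_map(zstack(img, geom), 2L)
  expect_lt(max(spl$values[10:12, , 1]),
            0.5 * max(sp_before$values[10:12, , 1]))
  expect_equal(max(spl$values[24:28, 10:20, 1]), 1)
  # everything eroded away errors out
  tiny <- array(0, c(9, 9, 1))
  tiny[5, 5, 1] <- 10
  expect_error(build_speed_map(zstack(tiny, geom), 4L), "smaller")
})

test_that("arrival times solve the eikonal equation on uniform media", {
  ones <- array(1, c(21, 21, 21))
  T <- msfm_distance(ones, c(11, 11, 11))
  expect_equal(T[11, 11, 11], 0)
  g <- expand.grid(i = 1:21, j = 1:21, k = 1:21)
  d <- sqrt((g$i - 11)^2 + (g$j - 11)^2 + (g$k - 11)^2)
  rel <- abs(as.numeric(T) - d) / pmax(d, 1e-9)
  expect_lte(max(rel[d > 0.5]), 0.02)
  # doubling the speed halves every arrival time
  T2 <- msfm_distance(ones * 2, c(11, 11, 11))
  expect_equal(as.numeric(T2), as.numeric(T) / 2)
})

# worst-case overestimate of the 26/8-neighbour graph metric relative to
# Euclidean distance, over the integer directions present in the grid:
# a path for offset (a >= b >= c >= 0) costs (a-b) + (b-c) sqrt2 + c sqrt3
chamfer_bound <- function(half, three_d = TRUE) {
  worst <- 0
  for (a in 0:half) for (b in 0:a) for (c in (if (three_d) 0:b else 0)) {
    if (a == 0) next
    graph <- (a - b) + (b - c) * sqrt(2) + c * sqrt(3)
    worst <- max(worst, graph / sqrt(a^2 + b^2 + c^2) - 1)
  }
  worst
}

test_that("arrival times agree with a 26-neighbour Dijkstra oracle up to
           the graph metric's own discretization error", {
  # 2D: the 8-neighbour bound on a 7x7 grid is just under 8%
  sp2 <- matrix(1, 7, 7)
  Tm2 <- msfm_distance(sp2, c(4, 4))
  Td2 <- dijkstra_26(sp2, c(4, 4))
  expect_lte(max(abs(Tm2 - Td2) / pmax(Td2, 1)), 0.08)
  expect_lte(chamfer_bound(3, three_d = FALSE), 0.08)
  # 3D: directions like (3,1,1) make the graph metric overshoot by up to
  # 12.5%, which bounds the disagreement with the (near-exact) solver
  for (n in c(5L, 7L)) {
    sp <- array(1, c(n, n, n))
    src <- rep((n + 1) %/% 2, 3)
    Tm <- msfm_distance(sp, src)
    Td <- dijkstra_26(sp, src)
    expect_lte(max(abs(Tm - Td) / pmax(Td, 1)),
               chamfer_bound((n - 1) %/% 2) + 0.005)
  }
})

test_that("geodesic tracing descends to the source", {
  ones <- array(1, c(31, 31, 7))
  T <- msfm_distance(ones, c(16, 16, 4))
  # on-axis start: straight line with sub-voxel deviation
  p <- trace_path(T, c(16, 28, 4), c(16, 16, 4))
  expect_true(attr(p, "reached"))
  expect_lte(max(abs(p[, 1] - 16)), 0.5)
  expect_lte(max(abs(p[, 3] - 4)), 0.5)
  # arrival time decreases monotonically along the path
  tv <- spinetrack:::interp_trilinear(T, p[, 1], p[, 2], p[, 3])
  expect_true(all(diff(tv) < 1e-6))
  # start at source: single point
  p0 <- trace_path(T, c(16, 16, 4), c(16, 16, 4))
  expect_equal(nrow(p0), 1L)
  expect_error(trace_path(T * NA, c(1, 1, 1), c(16, 16, 4)), "finite")
})

test_that("the path follows a bright channel, not the Euclidean chord", {
  # L-shaped high-speed channel in a slow medium
  sp <- array(0.01, c(41, 41, 3))
  sp[35, 5:35, ] <- 1
  sp[5:35, 35, ] <- 1
  T <- msfm_distance(sp, c(35, 5, 2))
  p <- trace_path(T, c(5, 35, 2), c(35, 5, 2))
  expect_true(attr(p, "reached"))
  inside <- spinetrack:::interp_trilinear(sp, p[, 1], p[, 2], p[, 3]) > 0.5
  expect_gte(mean(inside), 0.95)
})

test_that("candidate base points are the nearest perimeter voxels", {
  mask <- matrix(FALSE, 21, 21)
  mask[15:19, ] <- TRUE
  b1 <- candidate_base_points(c(5, 11), mask, n = 1L)
  expect_equal(unname(b1[1, ]), c(15, 11))
  # exact tie: lower row wins
  mask2 <- matrix(FALSE, 11, 11)
  mask2[3, 6] <- TRUE
  mask2[9, 6] <- TRUE
  bt <- candidate_base_points(c(6, 6), mask2, n = 1L)
  expect_equal(unname(bt[1, ]), c(3, 6))
  # all n candidates cluster near the perpendicular foot on a tube
  bn <- candidate_base_points(c(5, 11), mask, n = 6L)
  expect_true(all(bn[, 1] == 15))
  expect_lte(max(abs(bn[, 2] - 11)), 3)
  expect_warning(candidate_base_points(c(2, 2),
                                       matrix(c(TRUE, rep(FALSE, 8)), 3),
                                       n = 5L), "perimeter")
})

test_that("path terms match hand arithmetic", {
  geom <- voxel_geometry(0.1, 0.1, 0.1, 12L)
  vol <- zstack(array(100, c(15, 15, 5)), geom)
  # axis-aligned 2-point path spanning 10 voxels at 0.1 um
  path <- rbind(c(2, 3, 3), c(12, 3, 3))
  tm <- path_terms(path, vol)
  expect_equal(tm$L, 1.0)
  expect_equal(tm$C, 10)
  expect_equal(tm$S, 0)  # constant volume
  # hand-made 4-point path over a hand-made intensity ramp
  ramp <- array(0, c(3, 3, 3))
  ramp[] <- seq_len(27)  # V(r,c,z) = r + 3(c-1) + 9(z-1)
  vr <- zstack(ramp, voxel_geometry(0.2, 0.2, 0.4, 12L))
  p4 <- rbind(c(1, 1, 1), c(2, 1, 1), c(2, 2, 1), c(2, 2, 2))
  t4 <- path_terms(p4, vr)
  expect_equal(t4$L, 0.2 + 0.2 + 0.4)
  expect_equal(t4$C, 3)
  # total intensity variation along the monotone ramp equals V(end)-V(start)
  expect_equal(t4$S, ramp[2, 2, 2] - ramp[1, 1, 1])
  expect_error(path_terms(path[1, , drop = FALSE], vol), ">= 2")
})

test_that("candidate selection minimizes the max-normalized cost", {
  mk <- function(L, C, S) list(path = rbind(c(1, 1, 1), c(2, 1, 1)),
                               L = L, C = C, S = S)
  # strict dominance
  sel <- select_neck_path(list(mk(1, 1, 1), mk(2, 3, 2)))
  expect_equal(sel$index, 1L)
  # hand arithmetic: (1,1,2) vs (2,2,1) -> costs 2.0 and 2.5
  sel2 <- select_neck_path(list(mk(1, 1, 2), mk(2, 2, 1)))
  expect_equal(sel2$index, 1L)
  expect_equal(sel2$cost, 2.0)
  # all equal: first by tie-break
  sel3 <- select_neck_path(list(mk(1, 1, 1), mk(1, 1, 1), mk(1, 1, 1)))
  expect_equal(sel3$index, 1L)
  # cost is invariant under common rescaling of one term
  sel4 <- select_neck_path(list(mk(10, 1, 2), mk(20, 2, 1)))
  expect_equal(sel4$index, sel2$index)
  expect_equal(sel4$cost, sel2$cost)
  expect_error(select_neck_path(list()), "no valid")
})

test_that("trimming keeps the portion between head and dendrite", {
  geom <- voxel_geometry(0.1, 0.1, 0.1, 12L)
  vol <- zstack(array(50, c(15, 15, 3)), geom)
  path <- cbind(2:11, rep(5, 10), rep(2, 10))
  head_mask <- matrix(FALSE, 15, 15)
  head_mask[2:4, 5] <- TRUE     # first 3 voxels
  dend_mask <- matrix(FALSE, 15, 15)
  dend_mask[10:11, 5] <- TRUE   # last 2 voxels
  tr <- trim_path(path, head_mask, dend_mask, vol)
  expect_true(tr$trimmed)
  expect_equal(nrow(tr$points), 5L)
  expect_equal(tr$points[, 1], 5:9)
  # path outside both masks is returned with a warning
  expect_warning(tr2 <- trim_path(path, matrix(FALSE, 15, 15),
                                  dend_mask, vol),
                 "does not intersect")
  expect_false(tr2$trimmed)
  # stubby spine: head touching dendrite leaves nothing
  all_mask <- head_mask
  all_mask[2:11, 5] <- TRUE
  tr3 <- trim_path(path, all_mask, dend_mask, vol)
  expect_true(tr3$zero_length)
  expect_equal(tr3$L, 0)
})

test_that("phantom necks are recovered to within 15% with the correct
           base point", {
  ph <- make_phantom_zstack(neck_length_um = 1.2, neck_tilt_deg = 15,
                            distractor_gap_um = 0.25, seed = 2)
  np <- extract_neck_path(ph$stack, ph$truth$head_center_vox,
                          ph$truth$dendrite_mask,
                          head_mask = ph$truth$head_mask)
  expect_lt(abs(np$length_um - 1.2) / 1.2, 0.15)
  b <- np$base_point
  expect_true(ph$truth$dendrite_mask[b[1], b[2], b[3]])
  # the geodesic never detours through the distractor tube
  hit <- spinetrack:::interp_trilinear(ph$truth$distractor_mask * 1,
                                       np$points[, 1], np$points[, 2],
                                       np$points[, 3])
  expect_true(all(hit < 0.5))
})
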