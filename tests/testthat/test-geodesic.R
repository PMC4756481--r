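test_that("central seed is the member nearest the mean, ties lexicographic", {
  expect_equal(central_seed(rbind(c(3, 4, 5))), c(3, 4, 5))
  # symmetric pair: tie broken lexicographically
  expect_equal(central_seed(rbind(c(0, 0, 2), c(0, 0, 0))), c(0, 0, 0))
  # mean z = 7 -> nearest member is (0,0,10), not the mean itself
  expect_equal(central_seed(rbind(c(0, 0, 0), c(0, 0, 10), c(0, 0, 11))),
               c(0, 0, 10))
  # physical scale changes the winner: compressing x makes the x-spread
  # cheap, so the y-central point takes over
  pts <- rbind(c(1, 1, 1), c(1, 9, 2), c(1, 5, 9))
  expect_equal(central_seed(pts, spacing = c(1, 1, 1)), c(1, 9, 2))
  expect_equal(central_seed(pts, spacing = c(1, 1, 0.1)), c(1, 5, 9))
})

test_that("fast marching with constant speed approximates Euclidean distance", {
  sp <- array(1, c(25, 25, 25))
  f <- fast_marching_distance(sp, c(13, 13, 13))
  expect_equal(f$values[13, 13, 13], 0)
  expect_lt(abs(f$values[23, 13, 13] - 10) / 10, 0.05) # 10 axial steps
  # monotone along any grid ray from the source
  expect_true(all(diff(f$values[13:25, 13, 13]) >= 0))
  expect_true(all(diff(f$values[13, 13:1, 13]) >= 0))
  # anisotropic spacing scales arrival times
  fz <- fast_marching_distance(sp, c(13, 13, 13), spacing = c(2, 1, 1))
  expect_lt(abs(fz$values[18, 13, 13] - 10) / 10, 0.05)
  expect_error(fast_marching_distance(sp, c(0, 5, 5)), "bounds")
})

test_that("fast marching agrees with a Dijkstra oracle on smooth speed fields", {
  set.seed(7)
  dims <- c(14, 14, 14)
  for (trial in 1:2) {
    sp <- markerseg:::gaussian_smooth3(array(runif(prod(dims), 0.2, 1), dims), 2)
    f <- fast_marching_distance(sp, c(7, 7, 7))
    slow <- 1 / sp
    idx <- function(m) m[, 1] + (m[, 2] - 1) * dims[1] +
      (m[, 3] - 1) * dims[1] * dims[2]
    co <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                seq_len(dims[3])))
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    ed <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
      sh <- sweep(co, 2, offs[r, ], `+`)
      ok <- sh[, 1] >= 1 & sh[, 1] <= dims[1] & sh[, 2] >= 1 &
        sh[, 2] <= dims[2] & sh[, 3] >= 1 & sh[, 3] <= dims[3]
      i1 <- idx(co[ok, , drop = FALSE])
      i2 <- idx(sh[ok, , drop = FALSE])
      data.frame(i1, i2, w = (slow[i1] + slow[i2]) / 2 * sqrt(sum(offs[r, ]^2)))
    }))
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$i1, to = ed$i2), directed = FALSE,
      vertices = seq_len(prod(dims)))
    d <- igraph::distances(g, v = as.character(idx(matrix(c(7, 7, 7), 1))),
                           weights = ed$w)
    rel <- abs(f$values[as.integer(colnames(d))] - d[1, ]) /
      pmax(d[1, ], 1e-9)
    expect_lt(mean(rel[d[1, ] > 0]), 0.10)
  }
})

test_that("geodesic descent reaches the source with decreasing times", {
  sp <- array(1, c(9, 9, 30))
  f <- fast_marching_distance(sp, c(5, 5, 3))
  expect_equal(nrow(geodesic_path(f, c(5, 5, 3))), 1L) # start == source
  path <- geodesic_path(f, c(5, 5, 28))
  times <- f$values[path]
  expect_true(all(diff(times) < 0))
  steps <- abs(diff(path))
  expect_true(all(steps <= 1)) # 26-adjacent
  # straight corridor: within 1 voxel of the straight segment (Bresenham)
  expect_true(all(path[, 1] %in% 4:6 & path[, 2] %in% 4:6))
  # unreachable start (obstacle) errors
  sp2 <- sp
  sp2[, , 15] <- 0
  f2 <- fast_marching_distance(sp2, c(5, 5, 3))
  expect_error(geodesic_path(f2, c(5, 5, 28)), "unreachable")
})

test_that("strokes cross the wall gap, never the wall", {
  tc <- two_chamber_phantom()
  g <- marker_graph(rbind(tc$seed_a, tc$seed_b), dim(tc$volume$data))
  g <- merge_segments(g, segment_ids(g)[1], segment_ids(g)[2])
  id <- segment_ids(g)
  mi <- build_marker_image(g, tc$volume, dilate = FALSE)
  stroke <- mi == id
  expect_equal(max(markerseg:::cpp_label_components(stroke, 26L)), 1L)
  expect_equal(sum(stroke & tc$wall_mask), 0L)
  # the stroke actually crosses to the far chamber through the gap plane
  xmid <- round(dim(tc$volume$data)[3] / 2)
  expect_true(any(which(stroke, arr.ind = TRUE)[, 3] == xmid))
})

test_that("marker image: singletons, connectivity, disjoint labels", {
  ph <- default_phantom()
  g <- marker_graph(ph$seeds, dim(ph$volume$data))
  mi <- build_marker_image(g, ph$volume)
  ids <- segment_ids(g)
  expect_setequal(sort(unique(mi[mi > 1])), ids)
  # one dilated blob per singleton segment
  expect_equal(max(markerseg:::cpp_label_components(mi == ids[1], 26L)), 1L)

  # multi-seed segment in a uniform image forms one 26-connected component
  vol <- flat_volume(c(16, 16, 16), 0.3)
  g2 <- marker_graph(rbind(c(3, 3, 3), c(12, 12, 12), c(3, 12, 6)),
                     dim(vol$data))
  g2 <- merge_segments(g2, segment_ids(g2)[1], segment_ids(g2)[2])
  g2 <- merge_segments(g2, segment_ids(g2)[1], segment_ids(g2)[2])
  expect_equal(n_segments(g2), 1L)
  mi2 <- build_marker_image(g2, vol)
  expect_equal(max(markerseg:::cpp_label_components(mi2 == segment_ids(g2), 26L)), 1L)

  # two separate segments never share marker voxels
  g3 <- marker_graph(rbind(c(3, 3, 3), c(12, 12, 12)), dim(vol$data))
  mi3 <- build_marker_image(g3, vol)
  ids3 <- segment_ids(g3)
  expect_equal(sum(mi3 == ids3[1] & mi3 == ids3[2]), 0L)
  expect_equal(sort(unique(mi3[mi3 > 0])), ids3)
})
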