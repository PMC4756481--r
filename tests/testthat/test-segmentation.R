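test_that("two markers in a uniform image split at the bisector plane", {
  vol <- flat_volume(c(9, 9, 20), 0.4)
  mk <- array(0L, dim(vol$data))
  mk[5, 5, 4] <- 2L
  mk[5, 5, 17] <- 3L
  mk[1, 1, 1] <- 1L
  map <- seeded_watershed(vol, mk)
  expect_identical(sort(unique(as.integer(map$labels))), c(1L, 2L, 3L))
  # marker voxels keep their own labels
  expect_equal(map$labels[5, 5, 4], 2L)
  expect_equal(map$labels[5, 5, 17], 3L)
  # along the axis between the markers the split sits near x = 10.5 (+-1)
  line <- map$labels[5, 5, 4:17]
  flip <- min(which(line == 3L)) + 3L # first x claimed by marker 3
  expect_true(flip >= 10 && flip <= 12)
  expect_error(seeded_watershed(vol, array(0L, dim(vol$data))), "empty")
})

test_that("a closed bright wall confines the flood (single-cell phantom)", {
  ph <- generate_phantom(phantom_spec(dims = c(32, 32, 32), n_cells = 1))
  g <- marker_graph(ph$seeds, dim(ph$volume$data))
  res <- run_iteration(ph$volume, g)
  ev <- match_and_score(res$label_map, ph$truth)
  expect_gte(mean_f(ev), 0.95)
})

test_that("label maps are complete and iterations deterministic", {
  ph <- default_phantom()
  res <- default_segmentation()
  expect_equal(sum(res$label_map$labels == 0L), 0L)
  expect_setequal(unique(as.integer(res$label_map$labels)),
                  c(1L, as.integer(rownames(ph$seeds))))
  res2 <- run_iteration(ph$volume, res$graph)
  expect_identical(res2$label_map$labels, res$label_map$labels)
})

test_that("graph edits reshape the next iteration's label map", {
  ph <- default_phantom()
  res <- default_segmentation()
  g <- res$graph
  ids <- segment_ids(g)
  a <- ids[5]
  b <- ids[6]
  region_a <- which(res$label_map$labels == a)
  region_b <- which(res$label_map$labels == b)

  gm <- merge_segments(g, a, b)
  resm <- run_iteration(ph$volume, gm)
  expect_false(b %in% unique(as.integer(resm$label_map$labels)))
  merged <- which(resm$label_map$labels == min(a, b))
  expect_true(all(region_a %in% merged))
  expect_true(all(region_b %in% merged))

  gd <- delete_segment(g, a)
  resd <- run_iteration(ph$volume, gd)
  expect_false(a %in% unique(as.integer(resd$label_map$labels)))
  # the old region is reclaimed by neighbours/background, not left unassigned
  expect_true(all(resd$label_map$labels[region_a] > 0L))
})

test_that("inner points maximize the boundary distance inside the segment", {
  ball <- digitized_ball(radius = 8)
  ctr <- (dim(ball) + 1) / 2
  ip <- segment_inner_point(mask_map(ball)$labels, 2L)
  expect_lte(max(abs(ip - ctr)), 1)

  # L-shape: brute-force distance check and containment in the thick arm
  lab <- array(1L, c(14, 24, 24))
  lab[6:9, 2:22, 2:7] <- 2L    # thin arm: 4 x 21 x 6
  lab[3:12, 13:22, 3:18] <- 2L # thick block: 10 x 10 x 16
  ipL <- segment_inner_point(lab, 2L)
  expect_equal(lab[ipL[1], ipL[2], ipL[3]], 2L)
  coords <- which(lab == 2L, arr.ind = TRUE)
  bnd <- which(lab != 2L, arr.ind = TRUE)
  bf_dist <- function(p) min(sqrt(rowSums(sweep(bnd, 2, p, `-`)^2)))
  d_ip <- bf_dist(ipL)
  set.seed(1)
  samp <- coords[sample(nrow(coords), 60), ]
  expect_true(all(apply(samp, 1, bf_dist) <= d_ip + 1e-9))
  expect_equal(d_ip, 5) # the thick block's inradius; thin arm peaks at 2.5
  expect_true(ipL[2] >= 13) # inside the thick block

  # 1-voxel segment degenerates to itself
  lab1 <- array(1L, c(3, 3, 3))
  lab1[2, 2, 2] <- 2L
  expect_equal(segment_inner_point(lab1, 2L), c(2L, 2L, 2L))

  # all inner points of the reference phantom lie strictly inside their cells
  res <- default_segmentation()
  pr <- propagate_seeds(res, default_phantom()$volume)
  ids <- as.integer(rownames(pr$inner_points))
  for (r in seq_along(ids)) {
    p <- pr$inner_points[r, ]
    expect_equal(res$label_map$labels[p[1], p[2], p[3]], ids[r])
  }
})

test_that("chain propagation holds up on static and drifting series", {
  frames <- generate_time_series(phantom_spec(), n_t = 3, drift = 0)
  dims <- dim(frames[[1]]$volume$data)
  ws <- workspace(lapply(frames, `[[`, "volume"))
  r0 <- run_iteration(frames[[1]]$volume, marker_graph(frames[[1]]$seeds, dims))
  chain <- batch_propagate(ws, 0, 2, initial = r0)
  for (i in 1:3) {
    expect_gte(mean_f(match_and_score(chain[[as.character(i - 1)]]$label_map,
                                      frames[[i]]$truth)), 0.95)
  }
  # t_start == t_end returns the existing result unchanged
  same <- batch_propagate(ws, 0, 0, initial = r0)
  expect_length(same, 1L)
  expect_identical(same[["0"]]$label_map$labels, r0$label_map$labels)

  framesd <- generate_time_series(phantom_spec(), n_t = 3, drift = c(0, 0, 2))
  wsd <- workspace(lapply(framesd, `[[`, "volume"))
  rd0 <- run_iteration(framesd[[1]]$volume,
                       marker_graph(framesd[[1]]$seeds, dims))
  chaind <- batch_propagate(wsd, 0, 2, initial = rd0)
  expect_gte(mean_f(match_and_score(chaind[["2"]]$label_map,
                                    framesd[[3]]$truth)), 0.90)
})

test_that("a missing volume stops the chain with partial results", {
  frames <- generate_time_series(phantom_spec(dims = c(32, 32, 32),
                                              n_cells = 8), n_t = 2, drift = 0)
  dims <- dim(frames[[1]]$volume$data)
  ws <- workspace(list(frames[[1]]$volume, "missing_file.tif",
                       frames[[2]]$volume))
  r0 <- run_iteration(frames[[1]]$volume, marker_graph(frames[[1]]$seeds, dims))
  out <- batch_propagate(ws, 0, 2, initial = r0)
  expect_length(out, 1L)
  expect_match(attr(out, "error"), "t = 1")
})

test_that("merging a spuriously split cell strictly raises its F-measure", {
  ph <- default_phantom()
  dims <- dim(ph$volume$data)
  # plant a second seed inside cell 5, well away from the true seed, so the
  # watershed genuinely splits the cell in two
  extra <- far_interior_point(ph, 5L)
  seeds <- rbind(ph$seeds, extra)
  g <- marker_graph(seeds, dims)
  r0 <- run_iteration(ph$volume, g)
  ev0 <- match_and_score(r0$label_map, ph$truth)
  f0 <- ev0$F[ev0$truth_id == 5L]
  # find the two candidate cell segments overlapping truth cell 5
  over <- table(r0$label_map$labels[ph$truth$labels == 5L])
  over <- over[as.integer(names(over)) >= 2L]
  expect_gte(length(over), 2L) # the planted seed did split the cell
  pair <- as.integer(names(sort(over, decreasing = TRUE))[1:2])
  g2 <- merge_segments(g, pair[1], pair[2])
  r1 <- run_iteration(ph$volume, g2)
  ev1 <- match_and_score(r1$label_map, ph$truth)
  f1 <- ev1$F[ev1$truth_id == 5L]
  expect_gt(f1, f0)
})
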