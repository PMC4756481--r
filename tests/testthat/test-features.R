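test_that("border/interior intensity features follow their closed forms", {
  # 1 slab segment: boundary shell bright (0.8), interior dim (0.2)
  dims <- c(12, 12, 12)
  lab <- array(1L, dims)
  lab[3:10, 3:10, 3:10] <- 2L
  v <- array(0, dims)
  inner <- array(FALSE, dims)
  inner[4:9, 4:9, 4:9] <- TRUE
  v[lab == 2L] <- 0.8
  v[inner] <- 0.2
  v[1, 1, 1] <- 1 # pin the [0,1] normalization so intensities stay as written
  tab <- compute_segment_features(label_map(lab), intensity_volume(v))
  expect_equal(tab$border_interior_ratio, 4, tolerance = 1e-9)
  expect_equal(tab$mean_boundary_intensity, 0.8)
  expect_equal(tab$mean_interior_intensity, 0.2)
  # identical distributions -> EMD 0; 8-bin shift -> 8/32 in intensity units
  expect_equal(emd_1d(c(1, 0, 0), c(1, 0, 0)), 0)
  p <- rep(0, 32); p[5] <- 1
  q <- rep(0, 32); q[13] <- 1
  expect_equal(emd_1d(p, q, 1 / 32), 0.25)
})

test_that("EMD is a metric on random histograms (symmetry, triangle)", {
  set.seed(11)
  for (i in 1:25) {
    a <- runif(8); b <- runif(8); c <- runif(8)
    dab <- emd_1d(a, b); dba <- emd_1d(b, a)
    expect_equal(dab, dba)
    expect_lte(dab, emd_1d(a, c) + emd_1d(c, b) + 1e-12)
    expect_gte(dab, 0)
  }
})

test_that("ball features hit their closed forms", {
  ball <- digitized_ball(radius = 10)
  tab <- cached("ball_features",
                compute_segment_features(mask_map(ball),
                                         flat_volume(dim(ball), 0.5)))
  ctr <- (dim(ball) + 1) / 2
  expect_lte(max(abs(c(tab$centroid_z, tab$centroid_y, tab$centroid_x) - ctr)),
             0.5)
  expect_gte(tab$sphericity, 0.90)
  expect_gte(tab$convexity, 0.95)
  expect_lt(abs(tab$elongation - 1), 0.1)
  expect_lt(abs(tab$flatness - 1), 0.1)
  # all boundary voxels are equidistant from the centre: histogram mass
  # concentrates in the top bins
  h <- tab$border_dist_hist[[1]]
  expect_gte(sum(tail(h, 2)), 0.8)
})

test_that("cuboid features match analytic moments", {
  cub <- digitized_cuboid(c(20, 10, 5))
  tab <- compute_segment_features(mask_map(cub), flat_volume(dim(cub), 0.5))
  expect_gte(tab$squareness, 0.95)
  # second moments of a side-n cuboid: (n^2 - 1) / 12 per axis
  expect_lt(abs(tab$lambda_max / tab$lambda_med - (20^2 - 1) / (10^2 - 1)),
            0.1 * 4)
  expect_lt(abs(tab$lambda_med / tab$lambda_min - (10^2 - 1) / (5^2 - 1)),
            0.1 * 4)
  expect_equal(tab$volume, sum(cub))
})

test_that("cylinder cylindricity uses the principal-axis enclosing cylinders", {
  cyl <- digitized_cylinder(radius = 5, height = 30)
  map <- mask_map(cyl)
  vol <- flat_volume(dim(cyl), 0.5)
  best <- compute_segment_features(map, vol, cylindricity_mode = "highest")
  worst <- compute_segment_features(map, vol, cylindricity_mode = "lowest")
  expect_gte(best$cylindricity, 0.85)
  expect_lte(worst$cylindricity, best$cylindricity)
})

test_that("degenerate segments report Inf sentinels, thin ratios survive", {
  lab <- array(1L, c(7, 7, 7))
  lab[4, 4, 2:6] <- 2L # collinear
  tab <- compute_segment_features(label_map(lab),
                                  flat_volume(c(7, 7, 7), 0.5))
  expect_true(is.infinite(tab$elongation) || is.infinite(tab$flatness))
  expect_true(is.finite(tab$volume))
  # zero interior mean -> ratio sentinel
  v <- array(0, c(7, 7, 7))
  v[4, 4, 4] <- 0 # all-zero volume: boundary mean 0 too, ratio Inf guarded
  lab2 <- array(1L, c(7, 7, 7))
  lab2[3:5, 3:5, 3:5] <- 2L
  tab2 <- compute_segment_features(label_map(lab2), intensity_volume(v))
  expect_true(is.infinite(tab2$border_interior_ratio) ||
                is.nan(tab2$border_interior_ratio))
})

test_that("features are scale-equivariant in the voxel spacing", {
  ball <- digitized_ball(radius = 8)
  t1 <- compute_segment_features(mask_map(ball), flat_volume(dim(ball), 0.5))
  t2 <- compute_segment_features(mask_map(ball, spacing = c(2, 2, 2)),
                                 flat_volume(dim(ball), 0.5,
                                             spacing = c(2, 2, 2)))
  expect_equal(t2$volume / t1$volume, 8)
  for (f in c("sphericity", "convexity", "squareness", "elongation",
              "flatness")) {
    expect_equal(t2[[f]], t1[[f]], tolerance = 0.02)
  }
})

test_that("convexity decreases strictly when a notch is carved", {
  ball <- digitized_ball(radius = 10)
  t1 <- cached("ball_features",
               compute_segment_features(mask_map(ball),
                                        flat_volume(dim(ball), 0.5)))
  notched <- ball
  ctr <- round((dim(ball) + 1) / 2)
  notched[(ctr[1] - 3):(ctr[1] + 3), (ctr[2] - 3):(ctr[2] + 3),
          ctr[3]:dim(ball)[3]] <- FALSE
  t2 <- compute_segment_features(mask_map(notched),
                                 flat_volume(dim(ball), 0.5))
  expect_gte(t1$convexity, 0.9)
  expect_lt(t2$convexity, t1$convexity)
})

test_that("AP-axis features follow constructed geometry", {
  dims <- c(16, 40, 16)
  # rod segment lying along y at 30% of a straight y axis
  lab <- array(1L, dims)
  lab[7:9, 10:16, 7:9] <- 2L
  vol <- flat_volume(dims, 0.5)
  axis <- ap_axis(rbind(c(8, 1, 8), c(8, 40, 8)))
  tab <- compute_segment_features(label_map(lab), vol, ap = axis)
  expect_lt(abs(tab$ap_position - (13 - 1) / 39), 0.02)
  expect_lte(tab$ap_angle, 5) # rod parallel to the axis
  expect_lt(abs(tab$ap_distance - 0), 1)
  # no axis -> AP features absent (NA), not zero
  tab0 <- compute_segment_features(label_map(lab), vol)
  expect_true(is.na(tab0$ap_position) && is.na(tab0$ap_angle))
  # perpendicular rod -> angle near 90
  lab2 <- array(1L, dims)
  lab2[7:9, 19:21, 3:13] <- 2L
  tab2 <- compute_segment_features(label_map(lab2), vol, ap = axis)
  expect_gte(tab2$ap_angle, 85)
})

test_that("surface distance is the centroid's depth below the specimen surface", {
  ball <- digitized_ball(radius = 10)
  tab <- cached("ball_features",
                compute_segment_features(mask_map(ball),
                                         flat_volume(dim(ball), 0.5)))
  expect_equal(tab$surface_distance, 10, tolerance = 1)
})

test_that("adjacency edges carry common-boundary statistics per direction", {
  dims <- c(4, 6, 10)
  lab <- array(2L, dims)
  lab[, , 6:10] <- 3L
  v <- array(0.2, dims)
  v[, , 5] <- 0.9 # bright on the k-side of the interface only
  adj <- build_adjacency(label_map(lab), intensity_volume(v))
  cells <- adj$edges[adj$edges$k >= 2 & adj$edges$j >= 2, ]
  expect_equal(nrow(cells), 2L) # both directions stored
  expect_equal(cells$n_shared, c(24L, 24L)) # 4 x 6 slab cross-section
  i23 <- cells$mean_intensity[cells$k == 2]
  i32 <- cells$mean_intensity[cells$k == 3]
  expect_gt(i23, i32) # directional intensities differ by construction

  # 2x2 checkerboard of 4 labels: no diagonal adjacency under the face rule
  lab2 <- array(1L, c(2, 8, 8))
  lab2[, 1:4, 1:4] <- 2L
  lab2[, 1:4, 5:8] <- 3L
  lab2[, 5:8, 1:4] <- 4L
  lab2[, 5:8, 5:8] <- 5L
  adj2 <- build_adjacency(label_map(lab2), flat_volume(c(2, 8, 8), 0.5))
  e <- adj2$edges[adj2$edges$k >= 2 & adj2$edges$j >= 2 &
                    adj2$edges$k < adj2$edges$j, ]
  expect_equal(nrow(e), 4L)
  expect_false(any(e$k == 2 & e$j == 5))
  expect_false(any(e$k == 3 & e$j == 4))
})

test_that("best-fit line resists outliers (M-estimator)", {
  set.seed(5)
  t <- runif(150, -20, 20)
  pts <- cbind(t, 0.5 * t, -t) + matrix(rnorm(450, 0, 0.3), ncol = 3)
  out <- matrix(runif(60, -15, 15), ncol = 3) # 20 gross outliers
  fit <- best_fit_line(rbind(pts, out))
  u <- c(1, 0.5, -1) / sqrt(2.25)
  expect_gte(abs(sum(fit$direction * u)), 0.99)
})
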