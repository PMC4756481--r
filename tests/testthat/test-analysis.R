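test_that("f_measure matches hand-computed precision/recall", {
  a <- array(FALSE, c(2, 5, 5))
  a[1, , ] <- TRUE
  expect_equal(f_measure(a, a), list(P = 1, R = 1, F = 1))
  b <- array(FALSE, c(2, 5, 5))
  b[2, , ] <- TRUE
  expect_equal(f_measure(a, b), list(P = 0, R = 0, F = 0))
  # |cand| = 100, |truth| = 50, overlap = 50 -> P 0.5, R 1, F 2/3
  cand <- 1:100
  truth <- 1:50
  pr <- f_measure(cand, truth)
  expect_equal(pr$P, 0.5)
  expect_equal(pr$R, 1)
  expect_equal(pr$F, 2 / 3)
  expect_error(f_measure(a, array(FALSE, c(2, 5, 5))), "empty")
  # symmetry under mask exchange
  set.seed(2)
  x <- sample(1000, 300)
  y <- sample(1000, 400)
  expect_equal(f_measure(x, y)$F, f_measure(y, x)$F)
})

test_that("matching scores each truth cell against its best candidate", {
  lab <- array(1L, c(2, 6, 6))
  lab[, 2:5, 2:5] <- 2L
  truth <- label_map(lab)
  expect_equal(mean_f(match_and_score(truth, truth)), 1)

  # truth cell split into two equal halves: best half P=1, R=0.5, F=2/3
  half <- lab
  half[, 2:5, 4:5] <- 3L
  ev <- match_and_score(label_map(half), truth)
  expect_equal(ev$F, 2 / 3)

  # permuting candidate ids leaves scores unchanged
  perm <- half
  perm[half == 2L] <- 9L
  perm[half == 3L] <- 2L
  expect_equal(match_and_score(label_map(perm), truth)$F, ev$F)

  # zero-overlap truth cell scores 0
  off <- array(1L, c(2, 6, 6))
  off[, 1, 1] <- 7L
  ev0 <- match_and_score(label_map(off), truth)
  expect_equal(ev0$F, 0)
})

test_that("region selection is a conjunction of position constraints", {
  ph <- default_phantom()
  axis_pts <- rbind(c(32, 32, 4), c(32, 32, 60))
  tab <- cached("features_ap",
                compute_segment_features(ph$truth, ph$volume,
                                         ap = ap_axis(axis_pts)))
  expect_setequal(select_region(tab, list()), tab$id)
  post <- select_region(tab, list(ap_position = c(0.5, 1)))
  frac <- length(post) / nrow(tab)
  expect_gt(frac, 0.25) # roughly half the cells sit in the posterior half
  expect_lt(frac, 0.75)
  expect_setequal(union(post, select_region(tab, list(ap_position = c(0, 0.5)))),
                  tab$id)
  expect_length(select_region(tab, list(ap_position = c(0.9, 0.1))), 0L)
  expect_error(select_region(tab, list(nonsense = c(0, 1))), "unsupported")
  tab_noap <- cached("features_truth",
                     compute_segment_features(ph$truth, ph$volume))
  expect_error(select_region(tab_noap, list(ap_position = c(0, 1))),
               "not computed")
})

test_that("time-series statistics: static series, division, conservation", {
  frames <- cached("division_series",
                   generate_time_series(phantom_spec(n_cells = 20),
                                        n_t = 2, drift = 0, divide_at = 1))
  tabs <- cached("division_tables", lapply(frames, function(fr) {
    r <- run_iteration(fr$volume, marker_graph(fr$seeds, dim(fr$volume$data)))
    compute_segment_features(r$label_map, fr$volume)
  }))
  st <- time_series_stats(tabs, c("volume", "sphericity"))
  vs <- st$summary[st$summary$feature == "volume", ]
  expect_equal(vs$n, c(20L, 40L)) # cells double at the division frame
  expect_lt(abs(vs$mean[2] / vs$mean[1] - 0.5), 0.2 * 0.5)
  # histogram mass equals the cell count at each t, shared binning
  hc <- st$histograms$volume$counts
  expect_equal(unname(rowSums(hc)), c(20, 40))
  expect_length(st$histograms$volume$breaks, 17L)

  # identical tables -> identical summaries; NULL entries skipped with warning
  expect_warning(st2 <- time_series_stats(list(tabs[[1]], NULL, tabs[[1]]),
                                          "volume"), "skipping")
  s2 <- st2$summary
  expect_equal(s2$mean[1], s2$mean[2])
  expect_equal(s2$t, c(0L, 2L))
})

test_that("k-means clustering recovers blobs and reports group statistics", {
  set.seed(8)
  mk_tab <- function(sep) {
    n <- 40
    data.frame(id = 1:(2 * n),
               volume = c(rnorm(n, 0, 0.5), rnorm(n, sep, 0.5)),
               sphericity = c(rnorm(n, 0, 0.5), rnorm(n, sep, 0.5)))
  }
  tab <- mk_tab(6)
  cs <- cluster_cells(tab, c("volume", "sphericity"), k = 2, seed = 1)
  truth <- rep(1:2, each = 40)
  agree <- max(mean(cs$assignments == truth), mean(cs$assignments == 3 - truth))
  expect_equal(agree, 1) # perfect recovery (ARI = 1)
  # k = n: every cell its own cluster, zero intra-cluster variance
  small <- tab[1:8, ]
  cs_n <- cluster_cells(small, c("volume", "sphericity"), k = 8, seed = 1)
  expect_equal(cs_n$intra_cluster_variance, 0, tolerance = 1e-12)
  expect_error(cluster_cells(small, "volume", k = 9), "exceeds")
  expect_error(cluster_cells(small, "volume", k = 1), "at least 2")
  # inter-cluster distance grows with blob separation
  seps <- c(2, 4, 8)
  inter <- vapply(seps, function(s)
    cluster_cells(mk_tab(s), c("volume", "sphericity"), k = 2,
                  seed = 1)$inter_cluster_distance, 0)
  expect_true(all(diff(inter) > 0))
})

test_that("ranking AUC behaves at its extremes", {
  expect_equal(ranking_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(ranking_auc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_error(ranking_auc(1:3, rep(TRUE, 3)), "both classes")
})
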