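# a small hand-built feature table + adjacency for sub-score contracts
toy_setup <- function(same_features = TRUE) {
  dims <- c(4, 6, 12)
  lab <- array(2L, dims)
  lab[, , 5:8] <- 3L
  lab[, , 9:12] <- 4L
  v <- flat_volume(dims, 0.5)
  map <- label_map(lab)
  tab <- compute_segment_features(map, v)
  if (!same_features) tab$volume[2] <- tab$volume[2] * 10
  list(tab = tab, adj = build_adjacency(map, v))
}

test_that("s1 is 0.5 at boundary/interior parity and monotone in the ratio", {
  ts <- toy_setup()
  sc <- sub_scores_s1_to_s4(ts$tab, ts$adj)
  expect_equal(sc$s1, rep(0.5, 3), tolerance = 1e-9) # flat volume: parity
  # synthetic table rows exercise monotonicity of the normalization
  tab <- ts$tab
  tab$mean_boundary_intensity <- c(0.2, 0.5, 0.8)
  tab$mean_interior_intensity <- c(0.8, 0.5, 0.2)
  sc2 <- sub_scores_s1_to_s4(tab, ts$adj)
  expect_equal(sc2$s1, c(0.2, 0.5, 0.8))
})

test_that("s4 is 1 for feature-identical neighbours, lower for an oddball", {
  sc_same <- sub_scores_s1_to_s4(toy_setup(TRUE)$tab, toy_setup(TRUE)$adj)
  expect_equal(sc_same$s4, rep(1, 3), tolerance = 1e-9)
  ts <- toy_setup(FALSE)
  sc <- sub_scores_s1_to_s4(ts$tab, ts$adj)
  expect_lt(max(sc$s4), 1)
  expect_true(all(sc$s4 >= 0 & sc$s4 <= 1))
})

test_that("a merged double-cell has the minimum s4 in its volume", {
  ph <- default_phantom()
  co <- cached("corrupt", corrupt_labels(ph, merges = 0.1, splits = 0,
                                         seed = 5))
  tab <- compute_segment_features(co$label_map, ph$volume)
  adj <- build_adjacency(co$label_map, ph$volume)
  sc <- sub_scores_s1_to_s4(tab, adj)
  merged <- co$merged_pairs[, 1]
  # the worst-ranked segments by neighbourhood similarity are merged ones
  expect_true(sc$id[which.min(sc$s4)] %in% merged)
})

test_that("isolated segments fall back to uninformative 0.5", {
  dims <- c(8, 8, 8)
  lab <- array(1L, dims)
  lab[3:6, 3:6, 3:6] <- 2L
  v <- flat_volume(dims, 0.5)
  sc <- sub_scores_s1_to_s4(compute_segment_features(label_map(lab), v),
                            build_adjacency(label_map(lab), v))
  expect_equal(sc$s2, 0.5)
  expect_equal(sc$s4, 0.5)
})

test_that("credit dissemination equals the exhaustive path-product oracle", {
  set.seed(99)
  for (trial in 1:200) {
    g <- random_credit_graph()
    s5 <- disseminate_credit(g$edges, seq_len(g$n), g$confirmed)
    oracle <- enumerate_credit(g$n, g$edges, g$confirmed)
    expect_lt(max(abs(s5[as.character(seq_len(g$n))] - oracle)), 1e-10)
  }
})

test_that("credit dissemination honours its stated contracts", {
  edges <- data.frame(k = c(1, 2), j = c(2, 3), d = c(1, 0.5))
  s5 <- disseminate_credit(edges, 1:4, confirmed = 1)
  expect_equal(unname(s5[c("1", "2", "3", "4")]), c(1, 1, 0.5, 0.5))
  # empty confirmed set: all uninformative
  expect_equal(unname(disseminate_credit(edges, 1:3, integer(0))),
               rep(0.5, 3))
  expect_error(disseminate_credit(edges, 1:3, confirmed = 9), "node set")
  # on connected graphs (every node reachable, so the unreachable default
  # never kicks in) confirming another segment never lowers any s5
  set.seed(13)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tree <- data.frame(k = 2:n, j = sapply(2:n, function(v) sample(v - 1, 1)))
    extra <- t(combn(n, 2))
    extra <- extra[sample(nrow(extra), 3), , drop = FALSE]
    ep <- unique(rbind(as.matrix(tree), extra))
    edges <- data.frame(k = ep[, 1], j = ep[, 2],
                        d = runif(nrow(ep), 0.1, 1))
    src <- sample(n, 2)
    s_a <- disseminate_credit(edges, 1:n, src[1])
    s_ab <- disseminate_credit(edges, 1:n, src)
    expect_true(all(s_ab >= s_a - 1e-12))
  }
})

test_that("label propagation separates well-separated clusters", {
  set.seed(4)
  n <- 30
  pos_block <- matrix(rnorm(4 * n, 0, 0.02), ncol = 4) + 0.9
  neg_block <- matrix(rnorm(4 * n, 0, 0.02), ncol = 4) + 0.1
  scores <- data.frame(id = 1:(2 * n), rbind(pos_block, neg_block))
  names(scores)[2:5] <- c("s1", "s2", "s3", "s4")
  fb <- user_feedback(confirmed = 1L, corrected = n + 1L)
  s6 <- train_classifier(scores, fb)
  expect_true(all(s6[1:n] > 0.9))
  expect_true(all(s6[(n + 1):(2 * n)] < 0.1))
  # clamped labels
  expect_equal(unname(s6["1"]), 1)
  expect_equal(unname(s6[as.character(n + 1)]), 0)
  # single-class feedback: no classifier
  expect_null(train_classifier(scores, user_feedback(confirmed = 1L)))
})

test_that("blend weight rewards many, balanced labels", {
  expect_equal(blend_weight(0, 0), 0)
  expect_equal(blend_weight(10, 0), 0)
  expect_equal(blend_weight(20, 20), 2 / 3)
  expect_lt(blend_weight(5, 5), blend_weight(10, 10))
  expect_lt(blend_weight(2, 18), blend_weight(10, 10))
  expect_true(blend_weight(1000, 1000) < 1)
})

test_that("cellness blend is exact", {
  expect_equal(combine_cellness(1, 1, 1, 1, 1, 1, 0.7), 1)
  expect_equal(combine_cellness(0.2, 0.4, 0.6, 0.8, 1.0), 0.6)
  # s1..s5 mean 0.4, s6 0.9, nu 0.5 -> 0.65
  expect_equal(combine_cellness(0.4, 0.4, 0.4, 0.4, 0.4, 0.9, 0.5), 0.65)
  # without negatives nu = 0 and cellness is exactly the five-score mean
  ph <- default_phantom()
  rep0 <- cached("report_nofb", cellness_report(ph$volume, ph$truth))
  expect_equal(rep0$nu, 0)
  expect_equal(rep0$scores$cellness,
               rowMeans(rep0$scores[, c("s1", "s2", "s3", "s4", "s5")]))
  expect_true(all(rep0$scores$cellness >= 0 & rep0$scores$cellness <= 1))
})

test_that("merge recommendations rank weak shared walls first", {
  dims <- c(4, 8, 12)
  lab <- array(2L, dims)
  lab[, , 5:8] <- 3L
  lab[, , 9:12] <- 4L
  v <- array(0.1, dims)
  v[, , 8:9] <- 0.9 # bright wall between 3 and 4; 2|3 wall left dark
  adj <- build_adjacency(label_map(lab), intensity_volume(v))
  rec <- merge_recommendations(adj)
  expect_equal(unname(sort(unlist(rec[1, c("k", "j")]))), c(2L, 3L))
  expect_true(all(rec$score >= 0 & rec$score <= 1))
  expect_true(!is.unsorted(rec$score))
  # each unordered pair appears exactly once
  expect_equal(anyDuplicated(paste(pmin(rec$k, rec$j), pmax(rec$k, rec$j))),
               0L)
})

test_that("an injected dim wall is the top merge recommendation", {
  ph <- generate_brick_phantom(phantom_spec(dims = c(48, 48, 48), seed = 3))
  dw <- inject_dim_wall(ph, factor = 0.2, seed = 103)
  rec <- merge_recommendations(build_adjacency(dw$label_map, dw$volume))
  expect_equal(unname(sort(unlist(rec[1, c("k", "j")]))), sort(dw$pair))
})

test_that("feedback disjointness is enforced", {
  expect_error(user_feedback(confirmed = 1:3, corrected = 3:5), "disjoint")
})
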