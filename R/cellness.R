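#' Z-scored shape feature space for segment similarity
#'
#' Concatenates (volume, sphericity, flatness, elongation) per segment,
#' z-scores each coordinate across the volume's segments, and derives the
#' scale factor `c = 1 / max pairwise distance` that maps feature-space
#' distances into `[0, 1]`. Non-finite entries (degenerate-segment
#' sentinels) are capped at the column maximum before scoring.
#'
#' @param table segment feature table from [compute_segment_features()].
#' @return list with `f` (matrix, rownames = ids) and `c` (scale factor).
#' @export
segment_feature_space <- function(table) {
  f <- as.matrix(table[, c("volume", "sphericity", "flatness", "elongation")])
  for (k in seq_len(ncol(f))) {
    fin <- is.finite(f[, k])
    if (!all(fin)) f[!fin, k] <- if (any(fin)) max(f[fin, k]) else 0
  }
  f <- scale(f)
  f[is.nan(f)] <- 0 # constant columns
  rownames(f) <- table$id
  cmax <- if (nrow(f) > 1) max(dist(f)) else 1
  list(f = f, c = if (cmax > 0) 1 / cmax else 1)
}

#' Feature-driven sub-scores s1-s4 of the cellness metric
#'
#' Quantifies the four characteristics of a correctly segmented cell:
#' `s1` -- the boundary is brighter than the interior, as the normalized
#' ratio `B / (B + S)` of mean boundary to mean interior intensity (0.5 at
#' parity, monotone in the raw ratio);
#' `s2` -- walls shared with neighbours are bright: the mean over
#' neighbouring cells of the common-boundary mean intensity, normalized
#' by the volume's 99th-percentile intensity and clipped to 1;
#' `s3` -- cells are mostly convex: the convexity feature;
#' `s4` -- cells resemble their neighbours: one minus the average scaled
#' feature-space distance to the adjacent segments, clipped to `[0, 1]`.
#' Segments with no cell neighbours get the uninformative 0.5 for s2/s4.
#'
#' @param table segment feature table.
#' @param adjacency matching `adjacency_graph`.
#' @param i99 99th-percentile intensity of the normalized volume
#'   (default 1).
#' @return data.frame with `id`, `s1`, `s2`, `s3`, `s4`.
#' @export
sub_scores_s1_to_s4 <- function(table, adjacency, i99 = 1) {
  fs <- segment_feature_space(table)
  ids <- table$id
  b <- table$mean_boundary_intensity
  s <- table$mean_interior_intensity
  s1 <- ifelse(b + s > 0, b / (b + s), 0.5)
  edges <- adjacency$edges
  cell_edges <- edges[edges$k >= 2L & edges$j >= 2L, ]
  s2 <- s4 <- rep(0.5, length(ids))
  for (i in seq_along(ids)) {
    e <- cell_edges[cell_edges$k == ids[i], ]
    if (nrow(e) == 0L) next
    s2[i] <- min(1, mean(e$mean_intensity) / i99)
    fk <- fs$f[as.character(ids[i]), ]
    dj <- vapply(as.character(e$j), function(j)
      sqrt(sum((fk - fs$f[j, ])^2)), 0)
    s4[i] <- min(1, max(0, 1 - mean(fs$c * dj)))
  }
  data.frame(id = ids, s1 = s1, s2 = s2, s3 = pmin(1, table$convexity),
             s4 = s4)
}

#' Disseminate confidence credit from confirmed segments (s5)
#'
#' Models the probability that a segment is correct given user-confirmed
#' segments: along a path through the segment adjacency graph the
#' probability is the product of pairwise similarities `d`, so the best
#' path is a shortest path under edge weights `w = -log d`, and
#' `s5 = exp(-cost)` of the cheapest path from any confirmed segment
#' (Dijkstra from each source). Confirmed segments score 1; segments
#' unreachable from every confirmed segment keep the uninformative
#' default, as does everything when no segment is confirmed.
#'
#' @param edges data.frame with columns `k`, `j`, `d` (pairwise
#'   similarity in `(0, 1]`; clipped to `[1e-6, 1]`).
#' @param node_ids all segment ids (isolated nodes included).
#' @param confirmed ids marked correct by the user.
#' @param default score for unreachable/uninformed segments (0.5).
#' @return named numeric vector of s5 scores.
#' @export
disseminate_credit <- function(edges, node_ids, confirmed, default = 0.5) {
  node_ids <- as.character(node_ids)
  s5 <- setNames(rep(default, length(node_ids)), node_ids)
  confirmed <- as.character(confirmed)
  if (length(confirmed) == 0L) return(s5)
  if (!all(confirmed %in% node_ids)) stop("confirmed ids not in node set")
  if (nrow(edges) > 0L) {
    d <- pmin(pmax(edges$d, 1e-6), 1)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$k), to = as.character(edges$j)),
      directed = FALSE, vertices = node_ids)
    cost <- igraph::distances(g, v = confirmed, to = node_ids,
                              weights = -log(d))
    best <- apply(cost, 2, min)
    reach <- is.finite(best)
    s5[colnames(cost)[reach]] <- exp(-best[reach])
  }
  s5[confirmed] <- 1
  s5
}

#' Similarity edges for credit dissemination
#'
#' Pairwise similarity `d = 1 - c * ||f_k - f_j||` over the unordered
#' adjacency pairs, clipped to `[1e-6, 1]`.
#'
#' @param adjacency an `adjacency_graph`.
#' @param fspace output of [segment_feature_space()].
#' @return data.frame with `k`, `j`, `d` (each unordered pair once,
#'   background excluded).
#' @export
similarity_edges <- function(adjacency, fspace) {
  e <- adjacency$edges
  e <- e[e$k >= 2L & e$j >= 2L & e$k < e$j, c("k", "j")]
  if (nrow(e) == 0L) return(data.frame(k = integer(), j = integer(),
                                       d = numeric()))
  e$d <- vapply(seq_len(nrow(e)), function(r) {
    dd <- sqrt(sum((fspace$f[as.character(e$k[r]), ] -
                      fspace$f[as.character(e$j[r]), ])^2))
    min(1, max(1e-6, 1 - fspace$c * dd))
  }, 0)
  e
}

#' Semi-supervised classifier score s6 by graph label propagation
#'
#' Works from very few labels: segments live in the 4-D `(s1, s2, s3, s4)`
#' score space; a Gaussian-kernel k-nearest-neighbour graph (k = 7, sigma
#' = median pairwise distance) is built over all segments, user-confirmed
#' segments are clamped to class "correct" (1) and corrected segments to
#' "incorrect" (0), and labels propagate until the harmonic solution
#' `F_U = (I - P_UU)^-1 P_UL y_L` is reached. The result is the
#' probability of the correct class. Needs at least one example of each
#' class; with single-class feedback no classifier is trained (`NULL`).
#'
#' @param scores data.frame from [sub_scores_s1_to_s4()].
#' @param feedback a [user_feedback()].
#' @param knn neighbours in the graph (default 7).
#' @return named numeric vector of s6 in `[0, 1]`, or `NULL`.
#' @export
train_classifier <- function(scores, feedback, knn = 7L) {
  pos <- intersect(feedback$confirmed, scores$id)
  neg <- intersect(feedback$corrected, scores$id)
  if (length(pos) == 0L || length(neg) == 0L) return(NULL)
  X <- as.matrix(scores[, c("s1", "s2", "s3", "s4")])
  ids <- as.character(scores$id)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  sigma <- median(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  W <- matrix(0, n, n)
  kk <- min(knn, n - 1L)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(kk + 1L)]
    W[i, nb] <- exp(-D[i, nb]^2 / (2 * sigma^2))
  }
  W <- pmax(W, t(W)) # symmetrize
  labelled <- ids %in% c(as.character(pos), as.character(neg))
  y <- as.numeric(ids %in% as.character(pos))[labelled]
  s6 <- setNames(numeric(n), ids)
  s6[labelled] <- y
  u <- which(!labelled)
  if (length(u) > 0L) {
    P <- W / pmax(rowSums(W), 1e-12)
    A <- diag(length(u)) - P[u, u, drop = FALSE] +
      diag(1e-9, length(u)) # ridge for isolated nodes
    fu <- solve(A, P[u, labelled, drop = FALSE] %*% y)
    s6[u] <- pmin(pmax(as.numeric(fu), 0), 1)
  }
  s6
}

#' Structured user feedback on a segmentation
#'
#' @param confirmed ids the user marked as correct (positive examples).
#' @param corrected ids the user corrected (negative examples); must be
#'   disjoint from `confirmed`.
#' @return A `user_feedback` object.
#' @export
user_feedback <- function(confirmed = integer(0), corrected = integer(0)) {
  if (length(intersect(confirmed, corrected)) > 0L)
    stop("confirmed and corrected sets must be disjoint")
  structure(list(confirmed = as.integer(confirmed),
                 corrected = as.integer(corrected)),
            class = "user_feedback")
}

#' Blend weight between the sub-score mean and the classifier
#'
#' Grows with the number of training examples and with class balance:
#' `nu = balance * saturation`, where `balance = 2 min(n_pos, n_neg) /
#' (n_pos + n_neg)` (0 when either class is empty) and
#' `saturation = n / (n + 20)` half-saturates at 20 labels. Always in
#' `[0, 1)` and monotone in the minority-class count.
#'
#' @param n_pos,n_neg numbers of positive / negative examples.
#' @param half_saturation label count at which saturation reaches 1/2.
#' @export
blend_weight <- function(n_pos, n_neg, half_saturation = 20) {
  n <- n_pos + n_neg
  if (n == 0 || min(n_pos, n_neg) == 0) return(0)
  balance <- 2 * min(n_pos, n_neg) / n
  balance * n / (n + half_saturation)
}

#' Combine sub-scores into the cellness confidence
#'
#' `cellness = (1 - nu) * mean(s1..s5) + nu * s6`; with `nu = 0` (or no
#' classifier) it is exactly the mean of the five sub-scores.
#'
#' @param s1,s2,s3,s4,s5 sub-score vectors in `[0, 1]`.
#' @param s6 classifier score (may be `NULL`/`NA` when untrained).
#' @param nu blend weight in `[0, 1]`.
#' @export
combine_cellness <- function(s1, s2, s3, s4, s5, s6 = NULL, nu = 0) {
  base <- (s1 + s2 + s3 + s4 + s5) / 5
  if (is.null(s6) || nu == 0) return(base)
  (1 - nu) * base + nu * s6
}

#' Ranked merge/deletion recommendations
#'
#' For every pair of neighbouring cell segments the merging score
#' `mean(B_kj) * |B_kj| / |B_k|` (common-wall mean intensity on the
#' `[0, 1]` scale, weighted by the wall's share of k's boundary) is
#' computed in both directions; each unordered pair is reported once with
#' the smaller directional score and the list is sorted ascending, so the
#' weakest shared walls -- the likeliest over-segmentations -- come
#' first.
#'
#' @param adjacency an `adjacency_graph`.
#' @return data.frame with `k`, `j`, `score`, sorted ascending.
#' @export
merge_recommendations <- function(adjacency) {
  e <- adjacency$edges
  e <- e[e$k >= 2L & e$j >= 2L, ]
  if (nrow(e) == 0L)
    return(data.frame(k = integer(), j = integer(), score = numeric()))
  e$score <- e$mean_intensity * e$n_shared / e$boundary_k
  a <- pmin(e$k, e$j)
  b <- pmax(e$k, e$j)
  key <- paste(a, b)
  sc <- tapply(e$score, key, min)
  ab <- do.call(rbind, strsplit(names(sc), " "))
  out <- data.frame(k = as.integer(ab[, 1]), j = as.integer(ab[, 2]),
                    score = as.numeric(sc))
  out <- out[order(out$score, out$k, out$j), ]
  rownames(out) <- NULL
  out
}

#' Full cellness evaluation of a segmentation
#'
#' Convenience orchestrator: computes features and adjacency, the
#' sub-scores s1-s4, credit dissemination s5 from the confirmed set, the
#' classifier score s6 and blend weight nu from the accumulated feedback,
#' the combined cellness, and the ranked merge recommendations.
#'
#' @param volume an [intensity_volume()].
#' @param map a [label_map()].
#' @param feedback a [user_feedback()] (default: none).
#' @param ap optional [ap_axis()].
#' @return A `cellness_report`: list with `scores` (data.frame `id`,
#'   `s1`..`s6`, `cellness`), `nu`, `recommendations`, `features`,
#'   `adjacency`.
#' @export
cellness_report <- function(volume, map, feedback = user_feedback(),
                            ap = NULL) {
  table <- compute_segment_features(map, volume, ap = ap)
  adjacency <- build_adjacency(map, volume)
  i99 <- quantile(normalized_view(volume), 0.99, names = FALSE)
  if (i99 <= 0) i99 <- 1
  sc <- sub_scores_s1_to_s4(table, adjacency, i99 = i99)
  fs <- segment_feature_space(table)
  sim <- similarity_edges(adjacency, fs)
  s5 <- disseminate_credit(sim, table$id,
                           intersect(feedback$confirmed, table$id))
  s6 <- train_classifier(sc, feedback)
  nu <- if (is.null(s6)) 0 else
    blend_weight(length(intersect(feedback$confirmed, table$id)),
                 length(intersect(feedback$corrected, table$id)))
  scores <- data.frame(sc,
                       s5 = unname(s5[as.character(sc$id)]),
                       s6 = if (is.null(s6)) NA_real_ else
                         unname(s6[as.character(sc$id)]))
  scores$cellness <- combine_cellness(scores$s1, scores$s2, scores$s3,
                                      scores$s4, scores$s5,
                                      if (is.null(s6)) NULL else scores$s6,
                                      nu)
  structure(list(scores = scores, nu = nu,
                 recommendations = merge_recommendations(adjacency),
                 features = table, adjacency = adjacency),
            class = "cellness_report")
}

#' @export
print.cellness_report <- function(x, ...) {
  cat(sprintf("cellness_report: %d segment(s), nu = %.3f, mean cellness = %.3f\n",
              nrow(x$scores), x$nu, mean(x$scores$cellness)))
  invisible(x)
}
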