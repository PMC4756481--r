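#' Volumetric precision, recall and F-measure of a candidate mask
#'
#' `P = |cand & truth| / |cand|`, `R = |cand & truth| / |truth|`,
#' `F = 2PR / (P + R)` (0 when `P + R = 0`).
#'
#' @param candidate,truth logical arrays (or index vectors) on the same
#'   grid.
#' @return list with `P`, `R`, `F`.
#' @export
f_measure <- function(candidate, truth) {
  if (is.logical(candidate)) candidate <- which(candidate)
  if (is.logical(truth)) truth <- which(truth)
  if (length(truth) == 0L) stop("empty ground-truth mask: F undefined")
  if (length(candidate) == 0L) return(list(P = 0, R = 0, F = 0))
  inter <- length(intersect(candidate, truth))
  P <- inter / length(candidate)
  R <- inter / length(truth)
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(P = P, R = R, F = F)
}

#' Match candidate segments to ground truth and score them
#'
#' Every ground-truth cell is matched to the candidate cell label with
#' maximal voxel overlap (a truth cell with no overlapping candidate cell
#' scores 0), and the volumetric F-measure is evaluated per cell. Scores
#' are invariant to candidate label permutations.
#'
#' @param candidate,truth [label_map()]s on the same grid.
#' @return An `evaluation_record`: data.frame with `truth_id`,
#'   `matched_id`, `P`, `R`, `F`; the per-volume mean F is in attribute
#'   `mean_f` and via [mean_f()].
#' @export
match_and_score <- function(candidate, truth) {
  if (!all(dim(candidate$labels) == dim(truth$labels)))
    stop("candidate and truth grids differ")
  cl <- candidate$labels
  tl <- truth$labels
  rows <- lapply(cell_ids(truth), function(tid) {
    tmask <- which(tl == tid)
    over <- table(cl[tmask])
    over <- over[as.integer(names(over)) >= 2L]
    if (length(over) == 0L)
      return(data.frame(truth_id = tid, matched_id = NA_integer_,
                        P = 0, R = 0, F = 0))
    mid <- as.integer(names(over)[which.max(over)])
    pr <- f_measure(which(cl == mid), tmask)
    data.frame(truth_id = tid, matched_id = mid, P = pr$P, R = pr$R,
               F = pr$F)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_f") <- mean(out$F)
  class(out) <- c("evaluation_record", class(out))
  out
}

#' Mean per-cell F-measure of an evaluation record
#' @param record output of [match_and_score()].
#' @export
mean_f <- function(record) attr(record, "mean_f")

#' Select a region of interest by constraining position features
#'
#' Keeps the segments whose position features all fall inside the given
#' ranges (conjunction). Supported constraints: `ap_position`,
#' `ap_distance`, `surface_distance`, `centroid_z`, `centroid_y`,
#' `centroid_x`, each as `c(min, max)`.
#'
#' @param table segment feature table.
#' @param constraints named list of `c(min, max)` ranges; an empty list
#'   selects everything.
#' @return integer vector of selected segment ids.
#' @export
select_region <- function(table, constraints = list()) {
  allowed <- c("ap_position", "ap_distance", "surface_distance",
               "centroid_z", "centroid_y", "centroid_x")
  keep <- rep(TRUE, nrow(table))
  for (nm in names(constraints)) {
    if (!nm %in% allowed)
      stop("unsupported position constraint: ", nm)
    vals <- table[[nm]]
    if (all(is.na(vals)))
      stop("feature not computed for this table: ", nm,
           " (was an AP axis supplied?)")
    rng <- constraints[[nm]]
    keep <- keep & !is.na(vals) & vals >= rng[1] & vals <= rng[2]
  }
  table$id[keep]
}

#' Per-time-point summaries of segment features
#'
#' For each time point with features available: mean, median and a
#' histogram of every requested feature over the (optionally
#' region-filtered) segments. Histogram binning is shared across time
#' points so per-t histograms are directly comparable.
#'
#' @param tables list of per-time-point segment feature tables (0-based
#'   time = position - 1); `NULL` entries are skipped with a warning.
#' @param features character vector of feature column names.
#' @param region optional constraint list passed to [select_region()].
#' @param bins histogram bins (default 16).
#' @return list with `summary` (data.frame `t`, `feature`, `n`, `mean`,
#'   `median`) and `histograms` (per feature: list with `breaks` and
#'   `counts`, a time-by-bin matrix).
#' @export
time_series_stats <- function(tables, features, region = NULL, bins = 16L) {
  keep_vals <- function(tab, feat) {
    ids <- if (is.null(region)) tab$id else select_region(tab, region)
    tab[[feat]][tab$id %in% ids]
  }
  present <- !vapply(tables, is.null, TRUE)
  if (any(!present))
    warning("skipping time point(s) without a segmentation: ",
            paste(which(!present) - 1L, collapse = ", "))
  rng <- lapply(features, function(feat) {
    range(unlist(lapply(tables[present], keep_vals, feat)), finite = TRUE)
  })
  names(rng) <- features
  summary_rows <- list()
  hists <- list()
  for (feat in features) {
    brk <- seq(rng[[feat]][1], rng[[feat]][2], length.out = bins + 1L)
    counts <- matrix(0, sum(present), bins,
                     dimnames = list(which(present) - 1L, NULL))
    ri <- 0L
    for (t in which(present)) {
      vals <- keep_vals(tables[[t]], feat)
      vals <- vals[is.finite(vals)]
      ri <- ri + 1L
      counts[ri, ] <- tabulate(pmin(pmax(findInterval(vals, brk,
                                                      rightmost.closed = TRUE),
                                         1L), bins), bins)
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(t = t - 1L, feature = feat, n = length(vals),
                   mean = mean(vals), median = median(vals))
    }
    hists[[feat]] <- list(breaks = brk, counts = counts)
  }
  list(summary = do.call(rbind, summary_rows), histograms = hists)
}

#' K-means clustering of cells in a user-defined feature space
#'
#' Z-scores the selected features and runs K-means with multiple random
#' restarts under a fixed seed; reports assignments, cluster centers (in
#' the normalized feature space), the inter-cluster distance (mean
#' pairwise center distance) and the intra-cluster variance (mean squared
#' distance to the assigned center).
#'
#' @param table segment feature table.
#' @param features feature column names to cluster on.
#' @param k number of clusters (2 <= k <= number of segments).
#' @param seed RNG seed.
#' @param restarts random restarts (default 10).
#' @return A `cluster_summary`: list with `assignments` (named by id),
#'   `centers`, `inter_cluster_distance`, `intra_cluster_variance`.
#' @export
cluster_cells <- function(table, features, k, seed = 0, restarts = 10L) {
  X <- as.matrix(table[, features, drop = FALSE])
  if (k > nrow(X)) stop("k exceeds the number of segments")
  if (k < 2L) stop("k must be at least 2")
  X <- scale(X)
  X[is.nan(X)] <- 0
  km <- if (k == nrow(X)) {
    # one point per cluster: the exact optimum, which kmeans() refuses
    list(cluster = seq_len(nrow(X)), centers = X, tot.withinss = 0)
  } else {
    with_seed(seed, kmeans(X, centers = k, nstart = restarts,
                           iter.max = 50L))
  }
  ctr <- km$centers
  inter <- if (k > 1) mean(dist(ctr)) else 0
  intra <- km$tot.withinss / nrow(X)
  structure(list(assignments = setNames(km$cluster, table$id),
                 centers = ctr,
                 inter_cluster_distance = inter,
                 intra_cluster_variance = intra),
            class = "cluster_summary")
}

#' Ranking AUC of a score against binary labels
#'
#' Probability (by the rank-sum statistic) that a randomly chosen
#' positive outranks a randomly chosen negative; 0.5 = chance.
#'
#' @param scores numeric scores.
#' @param positive logical vector, TRUE for the positive class.
#' @export
ranking_auc <- function(scores, positive) {
  r <- rank(scores)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
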