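#' Marker graph: seeds partitioned into segments by a disjoint set
#'
#' Nuclei seeds and user guidance markers are the nodes of a forest; seeds
#' in the same disjoint subset jointly describe one segment of the
#' segmentation. The partition is maintained as a union-find structure
#' (parent/rank arrays), so merge ("union") and membership ("find") are
#' near constant amortized time; a side index maps each live segment id to
#' a representative node so id lookups are O(1). Each subset carries a
#' persistent segment id (>= 2; 1 is the image background).
#'
#' @param points (n x 3) matrix of `(z, y, x)` voxel coordinates; duplicate
#'   positions collapse to a single node. May have zero rows (segmentation
#'   then requires user seeds).
#' @param dims volume dimensions `(nz, ny, nx)` used for bounds checking.
#' @param origin provenance of these seeds: "nucleus", "user" or
#'   "propagated".
#' @return A `marker_graph` object.
#' @export
marker_graph <- function(points, dims, origin = "nucleus") {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) > 0) {
    check_in_bounds(points, dims)
    points <- unique(round(points))
  }
  n <- nrow(points)
  seg_id <- if (n > 0) seq_len(n) + 1L else integer(0)
  structure(list(
    points = points,
    origin = rep(origin, n),
    parent = seq_len(n),
    rank = integer(n),
    active = rep(TRUE, n),
    seg_id = seg_id, # valid on roots only
    id_node = setNames(seq_len(n), seg_id), # one live node per segment id
    next_id = n + 2L,
    dims = as.integer(dims)
  ), class = "marker_graph")
}

#' @export
print.marker_graph <- function(x, ...) {
  cat(sprintf("marker_graph: %d seed(s), %d segment(s)\n",
              sum(x$active), n_segments(x)))
  invisible(x)
}

# union-find root (rank-balanced tree, depth O(log n))
mg_find <- function(graph, i) {
  p <- graph$parent
  while (p[i] != i) i <- p[i]
  i
}

#' Segment id of every active seed
#'
#' @param graph a [marker_graph()].
#' @return named integer vector (names = node indices) mapping each active
#'   node to its segment id.
#' @export
segment_assignments <- function(graph) {
  idx <- which(graph$active)
  ids <- vapply(idx, function(i) graph$seg_id[mg_find(graph, i)], 0L)
  setNames(ids, idx)
}

#' Segment ids present in the graph
#' @param graph a [marker_graph()].
#' @export
segment_ids <- function(graph) sort(as.integer(names(graph$id_node)))

#' Number of segments described by the graph
#' @param graph a [marker_graph()].
#' @export
n_segments <- function(graph) length(graph$id_node)

#' Seed coordinates describing one segment
#'
#' @param graph a [marker_graph()].
#' @param id segment id.
#' @return matrix of `(z, y, x)` rows.
#' @export
seeds_of_segment <- function(graph, id) {
  node <- graph$id_node[as.character(id)]
  if (is.na(node)) stop("unknown segment id: ", id)
  root <- mg_find(graph, node)
  idx <- which(graph$active)
  idx <- idx[vapply(idx, function(i) mg_find(graph, i) == root, TRUE)]
  graph$points[idx, , drop = FALSE]
}

#' Add a guidance seed
#'
#' With a `target_segment` the seed is unioned into that subset (modifying
#' the segment); without one it starts a new singleton subset (adding a new
#' segment). Adding a seed at a position the target subset already contains
#' is a no-op.
#'
#' @param graph a [marker_graph()].
#' @param p `(z, y, x)` coordinate.
#' @param target_segment optional existing segment id.
#' @param origin seed provenance, default "user".
#' @return Modified [marker_graph()].
#' @export
add_seed <- function(graph, p, target_segment = NULL, origin = "user") {
  p <- round(as.numeric(p))
  check_in_bounds(matrix(p, ncol = 3), graph$dims)
  if (!is.null(target_segment) &&
      is.na(graph$id_node[as.character(target_segment)]))
    stop("unknown segment id: ", target_segment)
  dup <- which(graph$active &
                 graph$points[, 1] == p[1] &
                 graph$points[, 2] == p[2] &
                 graph$points[, 3] == p[3])
  if (length(dup) > 0 && !is.null(target_segment)) {
    dup_id <- graph$seg_id[mg_find(graph, dup[1])]
    if (dup_id == target_segment) return(graph) # idempotent
  }
  n <- nrow(graph$points) + 1L
  graph$points <- rbind(graph$points, p)
  graph$origin <- c(graph$origin, origin)
  graph$parent <- c(graph$parent, n)
  graph$rank <- c(graph$rank, 0L)
  graph$active <- c(graph$active, TRUE)
  if (is.null(target_segment)) {
    graph$seg_id <- c(graph$seg_id, graph$next_id)
    graph$id_node[as.character(graph$next_id)] <- n
    graph$next_id <- graph$next_id + 1L
  } else {
    graph$seg_id <- c(graph$seg_id, NA_integer_)
    graph <- mg_union(graph, n, graph$id_node[as.character(target_segment)],
                      keep_id = target_segment)
  }
  graph
}

# union by rank; the surviving root carries keep_id and the id index is
# updated (the losing subset's id disappears)
mg_union <- function(graph, i, j, keep_id) {
  keep_id <- as.integer(keep_id)
  ri <- mg_find(graph, i)
  rj <- mg_find(graph, j)
  if (ri == rj) return(graph)
  drop_ids <- stats::na.omit(c(graph$seg_id[ri], graph$seg_id[rj]))
  if (graph$rank[ri] < graph$rank[rj]) {
    tmp <- ri; ri <- rj; rj <- tmp
  }
  graph$parent[rj] <- ri
  if (graph$rank[ri] == graph$rank[rj]) graph$rank[ri] <- graph$rank[ri] + 1L
  graph$seg_id[ri] <- keep_id
  graph$seg_id[rj] <- NA_integer_
  graph$id_node <- graph$id_node[!names(graph$id_node) %in%
                                   as.character(drop_ids)]
  graph$id_node[as.character(keep_id)] <- ri
  graph
}

#' Merge two segments
#'
#' Unions the two subsets; the smaller of the two ids survives. Merging a
#' segment with itself is a no-op.
#'
#' @param graph a [marker_graph()].
#' @param a,b segment ids.
#' @return Modified [marker_graph()].
#' @export
merge_segments <- function(graph, a, b) {
  if (a == b) return(graph)
  ia <- graph$id_node[as.character(a)]
  ib <- graph$id_node[as.character(b)]
  if (is.na(ia)) stop("unknown segment id: ", a)
  if (is.na(ib)) stop("unknown segment id: ", b)
  mg_union(graph, ia, ib, keep_id = min(a, b))
}

#' Delete a segment
#'
#' All seeds of the subset are eliminated; the image region they covered is
#' reclaimed by neighbouring segments or the background at the next
#' watershed iteration. Re-adding a seed later creates a fresh id.
#'
#' @param graph a [marker_graph()].
#' @param a segment id.
#' @return Modified [marker_graph()].
#' @export
delete_segment <- function(graph, a) {
  node <- graph$id_node[as.character(a)]
  if (is.na(node)) stop("unknown segment id: ", a)
  root <- mg_find(graph, node)
  idx <- which(graph$active)
  idx <- idx[vapply(idx, function(i) mg_find(graph, i) == root, TRUE)]
  graph$active[idx] <- FALSE
  graph$id_node <- graph$id_node[names(graph$id_node) != as.character(a)]
  graph
}

# ----------------------------------------------------------- seed file I/O

#' Read a seed list file
#'
#' Plain text, one seed per line: `z y x [segment_id]`. Lines starting with
#' `#` are comments.
#'
#' @param path file path.
#' @return list with `points` (n x 3 matrix) and `segment` (integer vector,
#'   `NA` where no id was given).
#' @export
read_seed_points <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- lapply(strsplit(lines, "\\s+"), as.numeric)
  nc <- lengths(parts)
  if (any(nc < 3 | nc > 4)) stop("seed lines must be `z y x [segment_id]`")
  pts <- do.call(rbind, lapply(parts, function(p) p[1:3]))
  seg <- vapply(parts, function(p) if (length(p) == 4) p[4] else NA_real_, 0)
  list(points = pts, segment = as.integer(seg))
}

#' Write a seed list file
#'
#' @param points (n x 3) matrix of `(z, y, x)` coordinates.
#' @param path output file.
#' @param segment optional integer vector of segment ids.
#' @export
write_seed_points <- function(points, path, segment = NULL) {
  points <- matrix(points, ncol = 3)
  lines <- apply(points, 1, function(p) paste(p, collapse = " "))
  if (!is.null(segment)) {
    lines <- ifelse(is.na(segment), lines, paste(lines, segment))
  }
  writeLines(lines, path)
  invisible(path)
}
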