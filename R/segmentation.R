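#' Seeded watershed transform of a membrane volume
#'
#' Priority-flooding of the intensity relief from the marker image: every
#' voxel is assigned the label of the marker whose flood, rising through
#' the intensity landscape, reaches it first. Raw intensity is the
#' altitude (no gradient preprocessing); an optional Gaussian
#' pre-smoothing is available. Flooding uses 6-connectivity and ties are
#' broken by flood level, then lower marker id, then insertion order, so
#' the result is deterministic. The output is a total tessellation: no
#' voxel is left unassigned.
#'
#' If the marker image contains no background marker (label 1), one is
#' generated from the dark part of the volume's outer one-voxel shell
#' (voxels at or below the shell's 5th intensity percentile).
#'
#' @param volume an [intensity_volume()].
#' @param markers integer array of marker labels (0 = none, 1 =
#'   background, >= 2 = cells), e.g. from [build_marker_image()].
#' @param smooth_sigma Gaussian pre-smoothing in voxels (default 0 = off).
#' @return A [label_map()].
#' @export
seeded_watershed <- function(volume, markers, smooth_sigma = 0) {
  if (!any(markers > 0)) stop("empty marker image")
  relief <- normalized_view(volume)
  if (smooth_sigma > 0) relief <- gaussian_smooth3(relief, smooth_sigma)
  if (!any(markers == 1L)) {
    markers <- add_background_shell_markers(markers, relief)
  }
  storage.mode(markers) <- "integer"
  lab <- cpp_watershed(relief, markers)
  label_map(lab, volume$spacing)
}

# background markers on the dark outer shell (<= 5th percentile of shell)
add_background_shell_markers <- function(markers, relief) {
  dims <- dim(relief)
  shell <- array(FALSE, dims)
  shell[c(1, dims[1]), , ] <- TRUE
  shell[, c(1, dims[2]), ] <- TRUE
  shell[, , c(1, dims[3])] <- TRUE
  thr <- quantile(relief[shell], 0.05, names = FALSE)
  sel <- shell & relief <= thr & markers == 0L
  if (!any(sel)) sel <- shell & markers == 0L
  markers[sel] <- 1L
  markers
}

# separable Gaussian smoothing along each axis (reflecting boundaries)
gaussian_smooth3 <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(a, axis) {
    out <- array(0, dim(a))
    for (o in seq(-r, r)) {
      idx <- seq_len(dim(a)[axis]) + o
      idx <- pmin(pmax(idx, 1L), dim(a)[axis]) # replicate edges
      sl <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + k[o + r + 1] * sl
    }
    out
  }
  sm1(sm1(sm1(arr, 1L), 2L), 3L)
}

#' Run one interactive segmentation iteration
#'
#' Composes [build_marker_image()] and [seeded_watershed()] for the
#' current state of the marker graph. Re-running on an unchanged graph
#' reproduces the identical label map.
#'
#' @param volume an [intensity_volume()].
#' @param graph a [marker_graph()].
#' @param background_seeds optional background seed matrix (see
#'   [build_marker_image()]).
#' @param iteration iteration counter to record.
#' @param provenance one of "initial", "user_corrected", "propagated".
#' @param ... passed to [build_marker_image()].
#' @return A `segmentation_result`: list with `label_map`, `iteration`,
#'   `graph` and `provenance`.
#' @export
run_iteration <- function(volume, graph, background_seeds = NULL,
                          iteration = 0L, provenance = "initial", ...) {
  markers <- build_marker_image(graph, volume, background_seeds, ...)
  map <- seeded_watershed(volume, markers)
  structure(list(label_map = map, iteration = as.integer(iteration),
                 graph = graph, provenance = provenance),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: iteration %d (%s), %d segment(s)\n",
              x$iteration, x$provenance, length(cell_ids(x$label_map))))
  invisible(x)
}

#' Inner point of a segment (distance-transform maximum)
#'
#' The voxel of the segment maximizing the Euclidean distance to the
#' segment boundary; for a one-voxel segment it is that voxel. Computed on
#' the segment's bounding box for efficiency.
#'
#' @param labels integer label array.
#' @param id segment id.
#' @param spacing voxel spacing.
#' @return `(z, y, x)` coordinate (1-based).
#' @export
segment_inner_point <- function(labels, id, spacing = c(1, 1, 1)) {
  coords <- which(labels == id, arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("unknown segment id: ", id)
  if (nrow(coords) == 1L) return(as.integer(coords[1, ]))
  lo <- pmax(apply(coords, 2, min) - 1L, 1L)
  hi <- pmin(apply(coords, 2, max) + 1L, dim(labels))
  sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == id
  d <- cpp_edt(sub, as.numeric(spacing))
  best <- which.max(d)
  as.integer(arrayInd(best, dim(sub)) + lo - 1L)
}

#' Propagate a segmentation's seeds to an adjacent time point
#'
#' Transfers one interior point per segment -- the maximum of the distance
#' transform from the segment boundary, taken inside the segment -- plus a
#' background seed set obtained by eroding the current background region
#' by 3 voxels. Seeds falling outside the next volume's grid are clipped
#' away.
#'
#' @param result a `segmentation_result` (or [label_map()]).
#' @param next_volume the [intensity_volume()] of the adjacent time point.
#' @return A `propagated_seeds` object: list with `inner_points` (matrix
#'   with rownames = segment ids) and `background` (matrix of voxels).
#' @export
propagate_seeds <- function(result, next_volume) {
  map <- if (inherits(result, "segmentation_result")) result$label_map else result
  lab <- map$labels
  ids <- cell_ids(map)
  pts <- t(vapply(ids, function(id)
    segment_inner_point(lab, id, map$spacing), integer(3)))
  rownames(pts) <- ids
  bg_mask <- lab == BACKGROUND_LABEL
  bg <- which(cpp_edt(bg_mask, c(1, 1, 1)) > 3, arr.ind = TRUE)
  dims <- dim(next_volume$data)
  keep <- pts[, 1] <= dims[1] & pts[, 2] <= dims[2] & pts[, 3] <= dims[3]
  pts <- pts[keep, , drop = FALSE]
  keep_bg <- bg[, 1] <= dims[1] & bg[, 2] <= dims[2] & bg[, 3] <= dims[3]
  bg <- bg[keep_bg, , drop = FALSE]
  structure(list(inner_points = pts, background = bg),
            class = "propagated_seeds")
}

#' Segment a volume from propagated seeds
#'
#' Builds a marker image in which each propagated inner point keeps its
#' source segment id (so labels correspond across time points) and the
#' eroded background region is the background marker, then runs the
#' seeded watershed.
#'
#' @param volume an [intensity_volume()].
#' @param propagated a `propagated_seeds` object.
#' @param iteration iteration index to record.
#' @return A `segmentation_result` with provenance "propagated".
#' @export
segment_from_propagated <- function(volume, propagated, iteration = 0L) {
  dims <- dim(volume$data)
  img <- array(0L, dims)
  ids <- as.integer(rownames(propagated$inner_points))
  for (r in seq_along(ids)) {
    p <- propagated$inner_points[r, ]
    img[p[1], p[2], p[3]] <- ids[r]
  }
  if (nrow(propagated$background) > 0) {
    free <- img[propagated$background] == 0L
    img[propagated$background[free, , drop = FALSE]] <- 1L
  }
  img <- dilate_markers(img)
  map <- seeded_watershed(volume, img)
  graph <- marker_graph(propagated$inner_points, dims, origin = "propagated")
  structure(list(label_map = map, iteration = as.integer(iteration),
                 graph = graph, provenance = "propagated"),
            class = "segmentation_result")
}

#' Chain-propagate a segmentation across time points
#'
#' Starting from an existing segmentation at `t_start`, repeatedly
#' transfers inner-point and background seeds to the adjacent time point
#' and re-segments, walking towards `t_end` (forwards or backwards). No
#' corrections are applied along the chain.
#'
#' @param ws a [workspace()] supplying the volumes.
#' @param t_start 0-based time point with an existing segmentation.
#' @param t_end 0-based final time point (inclusive).
#' @param initial the `segmentation_result` (or [label_map()]) at
#'   `t_start`; if `NULL`, taken from the workspace `labels` slot.
#' @return Named list of `segmentation_result`s for every visited time
#'   point, including `t_start` (names = time indices). If a volume is
#'   missing mid-chain, the partial results are returned with an
#'   `error` attribute describing the failure.
#' @export
batch_propagate <- function(ws, t_start, t_end, initial = NULL) {
  if (is.null(initial)) {
    initial <- ws$labels[[t_start + 1L]]
    if (is.null(initial)) stop("no segmentation available at t_start = ", t_start)
    if (is.character(initial)) initial <- read_label_map(initial, ws$spacing)
  }
  if (inherits(initial, "label_map")) {
    initial <- structure(list(label_map = initial, iteration = 0L,
                              graph = NULL, provenance = "initial"),
                         class = "segmentation_result")
  }
  out <- list()
  out[[as.character(t_start)]] <- initial
  if (t_start == t_end) return(out)
  step <- if (t_end > t_start) 1L else -1L
  prev <- initial
  for (t in seq(t_start + step, t_end, by = step)) {
    vol <- tryCatch(get_volume(ws, t), error = function(e) e)
    if (inherits(vol, "error")) {
      attr(out, "error") <- sprintf("missing volume at t = %d: %s", t,
                                    conditionMessage(vol))
      return(out)
    }
    seeds <- propagate_seeds(prev, vol)
    prev <- segment_from_propagated(vol, seeds, iteration = abs(t - t_start))
    out[[as.character(t)]] <- prev
  }
  out
}
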