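#' 3-D intensity volume with anisotropic voxel scale
#'
#' The basic container for a single-channel microscopy stack. Data are stored
#' as a numeric array in fixed `(z, y, x)` axis order (one z slice per TIFF
#' page) and carry the physical voxel size along each axis. All voxel
#' coordinates used throughout the package are 1-based `(z, y, x)` indices
#' into this array; physical quantities multiply by `spacing`.
#'
#' @param data numeric array; 2-D input is promoted to a single-slice volume
#'   with a warning.
#' @param spacing physical units per voxel along `(z, y, x)`; all > 0.
#' @return An `intensity_volume` object: list with `data` and `spacing`.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) == 2L) {
    warning("2-D image promoted to a 3-D volume with a single z slice")
    data <- array(data, dim = c(1L, dim(data)))
  }
  if (length(dim(data)) != 3L) stop("`data` must be a 2-D or 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (z, y, x)")
  structure(list(data = data, spacing = spacing), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "intensity_volume: %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g, range [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.intensity_volume <- function(x) dim(x$data)

#' Min-max normalized view of a volume on the unit interval
#'
#' Constant volumes map to all zeros.
#'
#' @param volume an [intensity_volume()].
#' @return numeric array with values in `[0, 1]`, same shape.
#' @export
normalized_view <- function(volume) {
  v <- volume$data
  r <- range(v)
  if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else array(0, dim(v))
}

#' Label map over a volume grid
#'
#' Integer array of segment ids on the same grid as its parent volume.
#' Label 1 is reserved for the image background, ids >= 2 are cells, and 0
#' marks transiently unassigned voxels during computation only; a completed
#' segmentation contains no zeros. Gaps in the id set are allowed (e.g.
#' after deleting a segment).
#'
#' @param labels integer array (3-D).
#' @param spacing voxel spacing `(z, y, x)` inherited from the parent volume.
#' @return A `label_map` object.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative")
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  ids <- cell_ids(x)
  cat(sprintf("label_map: %d x %d x %d (z,y,x), %d cell segment(s)\n",
              d[1], d[2], d[3], length(ids)))
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' Cell segment ids present in a label map
#'
#' @param map a [label_map()].
#' @return sorted integer vector of ids >= 2 (background and unassigned
#'   voxels excluded).
#' @export
cell_ids <- function(map) {
  ids <- sort(unique(as.integer(map$labels)))
  ids[ids >= 2L]
}

#' Reserved background label
#' @export
BACKGROUND_LABEL <- 1L

# bounds check for (z,y,x) coordinate rows against a dim vector
check_in_bounds <- function(pts, dims) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
    pts[, 2] >= 1 & pts[, 2] <= dims[2] &
    pts[, 3] >= 1 & pts[, 3] <= dims[3]
  if (!all(ok)) stop("point(s) out of volume bounds")
  invisible(TRUE)
}
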