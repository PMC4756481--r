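#' Read a 3-D volume from a (multi-page) TIFF stack
#'
#' Pages map to z slices, so a 26-page 512x512 stack becomes a
#' `(26, 512, 512)` volume in `(z, y, x)` order. Raw sample values are kept
#' (no rescaling); use [normalized_view()] for a `[0, 1]` view.
#'
#' @param path TIFF file path.
#' @param channel channel index for multi-channel pages (default 1).
#' @param spacing physical voxel size `(z, y, x)`; TIFF files rarely carry
#'   reliable 3-D resolution metadata, so it is supplied here (default 1).
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path, channel = 1L, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (identical(attr(pages[[1]], "bits.per.sample"), 32L)) {
    # 32-bit samples are floats: as.is would reinterpret the raw bits
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (channel > dim(p)[3]) stop("channel ", channel, " not present")
      p[, , channel]
    } else p
  })
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  if (nz == 1L) {
    vol <- suppressWarnings(intensity_volume(arr, spacing))
    warning("single-page TIFF promoted to a 3-D volume with depth 1")
    return(vol)
  }
  intensity_volume(arr, spacing)
}

#' Write a volume as a multi-page TIFF stack
#'
#' @param volume an [intensity_volume()] with data in `[0, 1]` (use
#'   [normalized_view()] first if needed) or raw integers up to 16 bits.
#' @param path output file.
#' @param bits 16 (integer samples, exact for integer data up to 65535) or
#'   32 (float samples).
#' @export
write_volume <- function(volume, path, bits = 32L) {
  if (!nzchar(path)) stop("empty output path")
  v <- volume$data
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  if (bits == 16L) {
    pages <- lapply(pages, function(p) p / 65535)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write a label map as a lossless integer TIFF stack
#'
#' One page per z slice; label ids are preserved exactly, including gaps in
#' the id set. Maps with up to 65535 labels are stored as 16-bit samples,
#' larger ones as 32-bit float samples (exact for ids below 2^24).
#'
#' @param map a [label_map()].
#' @param path output file.
#' @export
write_label_map <- function(map, path) {
  if (!nzchar(path)) stop("empty output path")
  mx <- max(map$labels)
  if (mx > 2^32 - 1) stop("label ids exceed 32-bit range")
  lab <- map$labels
  pages <- lapply(seq_len(dim(lab)[1]), function(z) lab[z, , ])
  if (mx <= 65535) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    if (mx >= 2^24) warning("label ids >= 2^24 may lose precision")
    tiff::writeTIFF(lapply(pages, function(p) p / 2^32), path,
                    bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing to attach.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("cannot read label map: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (identical(attr(pages[[1]], "bits.per.sample"), 32L)) {
    pages <- tiff::readTIFF(path, all = TRUE) # float samples: labels / 2^32
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) as.integer(round(p * 2^32)))
  }
  nz <- length(pages)
  arr <- array(0L, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  label_map(arr, spacing)
}

# ---------------------------------------------------------------- contours

# Trace the in-slice boundary polygons of a 2-D logical mask on the voxel
# corner lattice. Returns a list of closed polygons, each an (m x 2) matrix of
# (y, x) corner coordinates (half-integer), collinear runs simplified.
trace_slice_polygons <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  ny <- nrow(mask)
  nx <- ncol(mask)
  inside <- function(y, x) y >= 1 & y <= ny & x >= 1 & x <= nx & mask[cbind(y, x)]
  edges_from <- list()
  edges_to <- list()
  n <- 0L
  add_edge <- function(y1, x1, y2, x2) {
    n <<- n + 1L
    edges_from[[n]] <<- c(y1, x1)
    edges_to[[n]] <<- c(y2, x2)
  }
  for (r in seq_len(nrow(idx))) {
    y <- idx[r, 1]
    x <- idx[r, 2]
    # directed so that the segment interior stays on the right-hand side
    if (y == 1 || !inside(y - 1, x)) add_edge(y - 0.5, x - 0.5, y - 0.5, x + 0.5)
    if (y == ny || !inside(y + 1, x)) add_edge(y + 0.5, x + 0.5, y + 0.5, x - 0.5)
    if (x == 1 || !inside(y, x - 1)) add_edge(y + 0.5, x - 0.5, y - 0.5, x - 0.5)
    if (x == nx || !inside(y, x + 1)) add_edge(y - 0.5, x + 0.5, y + 0.5, x + 0.5)
  }
  from_key <- vapply(edges_from, function(p) paste(p, collapse = ","), "")
  used <- rep(FALSE, n)
  by_start <- split(seq_len(n), from_key)
  polys <- list()
  for (e0 in seq_len(n)) {
    if (used[e0]) next
    loop <- list(edges_from[[e0]])
    used[e0] <- TRUE
    cur <- edges_to[[e0]]
    start <- edges_from[[e0]]
    while (!isTRUE(all.equal(cur, start))) {
      loop[[length(loop) + 1L]] <- cur
      cand <- by_start[[paste(cur, collapse = ",")]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break # defensive; cannot happen on valid masks
      used[cand[1]] <- TRUE
      cur <- edges_to[[cand[1]]]
    }
    poly <- do.call(rbind, loop)
    # drop collinear intermediate vertices
    m <- nrow(poly)
    if (m > 2L) {
      prev <- poly[c(m, seq_len(m - 1L)), , drop = FALSE]
      nxt <- poly[c(seq(2L, m), 1L), , drop = FALSE]
      keep <- !((prev[, 1] == nxt[, 1] & prev[, 1] == poly[, 1]) |
                  (prev[, 2] == nxt[, 2] & prev[, 2] == poly[, 2]))
      poly <- poly[keep, , drop = FALSE]
    }
    polys[[length(polys) + 1L]] <- poly
  }
  polys
}

#' Export per-slice segment contours as an XML document
#'
#' For every z slice and every segment present in it, the closed polygon(s)
#' of the segment's in-slice boundary are traced on the voxel corner lattice
#' (vertices at half-integer positions between voxels). Slices where a
#' segment is absent emit no polygon for it.
#'
#' @param map a [label_map()].
#' @return An `xml2` document: `<contours>` / `<slice z=...>` /
#'   `<polygon segment=... points="x,y x,y ..."/>`.
#' @export
export_contours_xml <- function(map) {
  doc <- xml2::xml_new_root("contours")
  lab <- map$labels
  ids <- cell_ids(map)
  for (z in seq_len(dim(lab)[1])) {
    slice <- lab[z, , ]
    present <- intersect(unique(as.integer(slice)), ids)
    if (length(present) == 0L) next
    sl <- xml2::xml_add_child(doc, "slice", z = as.character(z))
    for (id in sort(present)) {
      polys <- trace_slice_polygons(slice == id)
      for (poly in polys) {
        pts <- paste(sprintf("%g,%g", poly[, 2], poly[, 1]), collapse = " ")
        xml2::xml_add_child(sl, "polygon", segment = as.character(id),
                            points = pts)
      }
    }
  }
  doc
}

#' Export a segment feature table as an XML document
#'
#' One `<segment>` element per row with one `<feature>` child per measured
#' quantity. Features that were not computed (e.g. anterior-posterior axis
#' features when no axis was supplied) are emitted with
#' `status="not computed"` rather than a value, so absence is never
#' conflated with zero.
#'
#' @param table a segment feature table from [compute_segment_features()].
#' @param time time point index recorded on the root element (default 0).
#' @return An `xml2` document.
#' @export
export_measurements_xml <- function(table, time = 0L) {
  doc <- xml2::xml_new_root("measurements", time = as.character(time))
  feature_cols <- setdiff(names(table), "id")
  for (r in seq_len(nrow(table))) {
    seg <- xml2::xml_add_child(doc, "segment",
                               id = as.character(table$id[r]))
    for (fc in feature_cols) {
      val <- table[[fc]][r]
      if (is.list(val)) next # histogram-valued columns are not exported
      if (is.na(val)) {
        xml2::xml_add_child(seg, "feature", name = fc,
                            status = "not computed")
      } else {
        xml2::xml_add_child(seg, "feature", name = fc,
                            value = sprintf("%.6g", val))
      }
    }
  }
  doc
}

#' Parse a measurements XML document back into a data frame
#'
#' Inverse of [export_measurements_xml()] (to the 6 significant digits the
#' export carries); not-computed features come back as `NA`.
#'
#' @param doc an `xml2` document or a file path.
#' @return data.frame with an `id` column and one column per feature.
#' @export
read_measurements_xml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  segs <- xml2::xml_find_all(doc, "//segment")
  rows <- lapply(segs, function(s) {
    feats <- xml2::xml_find_all(s, "feature")
    vals <- vapply(feats, function(f) {
      v <- xml2::xml_attr(f, "value")
      if (is.na(v)) NA_real_ else as.numeric(v)
    }, 0)
    names(vals) <- xml2::xml_attr(feats, "name")
    c(id = as.numeric(xml2::xml_attr(s, "id")), vals)
  })
  as.data.frame(do.call(rbind, rows))
}

# ---------------------------------------------------------------- workspace

#' Multi-time-point workspace
#'
#' Ordered collection of per-time-point channel references (file paths or
#' in-memory [intensity_volume()] objects) plus shared metadata. Time
#' indices are contiguous from 0 (list position minus one).
#'
#' @param volumes list of file paths and/or [intensity_volume()] objects.
#' @param spacing shared voxel spacing `(z, y, x)`.
#' @param seeds optional list (same length) of seed-point matrices or file
#'   paths, or `NULL` entries.
#' @param labels optional list of [label_map()] objects / paths.
#' @param ap_axis optional anterior-posterior axis polyline, an (m x 3)
#'   matrix of `(z, y, x)` points.
#' @return A `workspace` object.
#' @export
workspace <- function(volumes, spacing = c(1, 1, 1), seeds = NULL,
                      labels = NULL, ap_axis = NULL) {
  if (!is.list(volumes)) volumes <- as.list(volumes)
  nt <- length(volumes)
  pad <- function(x) {
    if (is.null(x)) return(vector("list", nt))
    if (length(x) != nt) stop("per-time-point lists must match volume count")
    x
  }
  structure(list(volumes = volumes, spacing = as.numeric(spacing),
                 seeds = pad(seeds), labels = pad(labels),
                 ap_axis = ap_axis),
            class = "workspace")
}

#' @export
print.workspace <- function(x, ...) {
  cat(sprintf("workspace: %d time point(s), t = 0..%d\n",
              length(x$volumes), length(x$volumes) - 1L))
  invisible(x)
}

#' Number of time points in a workspace
#' @param ws a [workspace()].
#' @export
n_time_points <- function(ws) length(ws$volumes)

#' Fetch the volume at time point t
#'
#' @param ws a [workspace()].
#' @param t 0-based time index.
#' @return An [intensity_volume()] (file references are read on demand).
#' @export
get_volume <- function(ws, t) {
  if (t < 0 || t >= n_time_points(ws)) stop("time point out of range: ", t)
  v <- ws$volumes[[t + 1L]]
  if (inherits(v, "intensity_volume")) return(v)
  read_volume(v, spacing = ws$spacing)
}

#' Append two workspaces, concatenating their time ranges
#'
#' A workspace covering `t = 0..n-1` appended with one covering `0..m-1`
#' yields `0..n+m-1` with per-time-point content unchanged.
#'
#' @param a,b [workspace()] objects with identical spacing.
#' @return Combined [workspace()].
#' @export
append_workspaces <- function(a, b) {
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("workspaces with different voxel spacing cannot be appended")
  workspace(c(a$volumes, b$volumes), spacing = a$spacing,
            seeds = c(a$seeds, b$seeds), labels = c(a$labels, b$labels),
            ap_axis = a$ap_axis)
}

#' Write a workspace description to a human-editable key-value file
#'
#' In-memory volumes/labels cannot be referenced from a file and raise an
#' error; write them to TIFF first.
#'
#' @param ws a [workspace()].
#' @param path output file.
#' @export
write_workspace <- function(ws, path) {
  lines <- c(sprintf("spacing = %g %g %g", ws$spacing[1], ws$spacing[2],
                     ws$spacing[3]))
  for (t in seq_along(ws$volumes)) {
    v <- ws$volumes[[t]]
    if (!is.character(v)) stop("in-memory volume at t=", t - 1L,
                               " cannot be written; save it to TIFF first")
    lines <- c(lines, sprintf("volume %d = %s", t - 1L, v))
    if (is.character(ws$seeds[[t]]))
      lines <- c(lines, sprintf("seeds %d = %s", t - 1L, ws$seeds[[t]]))
    if (is.character(ws$labels[[t]]))
      lines <- c(lines, sprintf("labels %d = %s", t - 1L, ws$labels[[t]]))
  }
  if (!is.null(ws$ap_axis)) {
    pts <- apply(ws$ap_axis, 1, function(p) paste(p, collapse = ","))
    lines <- c(lines, paste("ap_axis =", paste(pts, collapse = "; ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a workspace description file
#'
#' @param path file written by [write_workspace()] (or by hand).
#' @return A [workspace()].
#' @export
read_workspace <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) m[2], "")
  vals <- vapply(kv, function(m) m[3], "")
  spacing <- c(1, 1, 1)
  if ("spacing" %in% keys)
    spacing <- as.numeric(strsplit(vals[keys == "spacing"][1], "\\s+")[[1]])
  get_indexed <- function(prefix) {
    sel <- grepl(paste0("^", prefix, " \\d+$"), keys)
    idx <- as.integer(sub(paste0("^", prefix, " "), "", keys[sel]))
    out <- list()
    out[idx + 1L] <- as.list(vals[sel])
    out
  }
  vols <- get_indexed("volume")
  if (length(vols) == 0L || any(vapply(vols, is.null, TRUE)))
    stop("workspace file must list contiguous `volume t = path` entries from t = 0")
  seeds <- get_indexed("seeds")
  labels <- get_indexed("labels")
  length(seeds) <- length(vols)
  length(labels) <- length(vols)
  ap <- NULL
  if ("ap_axis" %in% keys) {
    pts <- strsplit(vals[keys == "ap_axis"][1], ";")[[1]]
    ap <- do.call(rbind, lapply(pts, function(p)
      as.numeric(strsplit(trimws(p), ",")[[1]])))
  }
  workspace(vols, spacing = spacing, seeds = seeds, labels = labels,
            ap_axis = ap)
}
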