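#' Anterior-posterior axis from user marker points
#'
#' Interpolates the ordered anterior-to-posterior marker polyline with a
#' cubic spline per coordinate, arc-length reparameterized and resampled
#' at roughly one-voxel steps; unit tangents come from finite differences.
#'
#' @param points (m x 3) matrix of `(z, y, x)` marker points, anterior
#'   first (m >= 2).
#' @param spacing voxel spacing used to measure arc length.
#' @return An `ap_axis` object: list with `points` (dense physical
#'   coordinates), `tangents`, `arc` (cumulative arc length) and `length`.
#' @export
ap_axis <- function(points, spacing = c(1, 1, 1)) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2L) stop("an AP axis needs at least 2 points")
  phys <- sweep(points, 2, spacing, `*`)
  chord <- c(0, cumsum(sqrt(rowSums(diff(phys)^2))))
  n_out <- max(16L, ceiling(max(chord)))
  s_out <- seq(0, max(chord), length.out = n_out)
  dense <- sapply(1:3, function(k) {
    if (nrow(phys) == 2L) {
      phys[1, k] + (phys[2, k] - phys[1, k]) * s_out / max(chord)
    } else {
      spline(chord, phys[, k], xout = s_out, method = "natural")$y
    }
  })
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  tang <- rbind(dense[2, ] - dense[1, ],
                (dense[-(1:2), , drop = FALSE] -
                   dense[seq_len(nrow(dense) - 2L), , drop = FALSE]) / 2,
                dense[nrow(dense), ] - dense[nrow(dense) - 1L, ])
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = dense, tangents = tang, arc = arc,
                 length = max(arc)),
            class = "ap_axis")
}

#' Robust best-fit line through a point cloud (M-estimator)
#'
#' Iteratively reweighted least squares with Tukey bisquare weights: the
#' line direction is the leading eigenvector of the weighted covariance
#' and the line point the weighted mean, re-estimated for 10 iterations.
#'
#' @param coords (n x 3) matrix of physical coordinates.
#' @param iters IRLS iterations (default 10).
#' @return list with unit `direction` and `point`.
#' @export
best_fit_line <- function(coords, iters = 10L) {
  w <- rep(1, nrow(coords))
  ctr <- colMeans(coords)
  dir <- c(1, 0, 0)
  for (it in seq_len(iters)) {
    ctr <- colSums(coords * w) / sum(w)
    cc <- sweep(coords, 2, ctr, `-`)
    cv <- crossprod(cc * sqrt(w)) / sum(w)
    eg <- eigen(cv, symmetric = TRUE)
    dir <- eg$vectors[, 1]
    resid <- sqrt(pmax(rowSums(cc^2) - as.numeric(cc %*% dir)^2, 0))
    s <- median(resid) * 1.4826 + 1e-9
    u <- resid / (4.685 * s)
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
    if (sum(w) < 3) {
      w <- rep(1, nrow(coords))
      break
    }
  }
  list(direction = as.numeric(dir), point = as.numeric(ctr))
}

#' 1-D Earth Mover's Distance between two histograms
#'
#' For 1-D histograms with common bins the EMD reduces to the L1 distance
#' between the cumulative distributions times the bin width.
#'
#' @param p,q histogram masses (normalized to sum 1 internally).
#' @param bin_width width of a bin in intensity units.
#' @return non-negative scalar.
#' @export
emd_1d <- function(p, q, bin_width = 1 / length(p)) {
  p <- p / sum(p)
  q <- q / sum(q)
  sum(abs(cumsum(p) - cumsum(q))) * bin_width
}

# inner-boundary mask: voxels whose label differs from >= 1 face neighbour
# (image border faces count as boundary)
boundary_mask <- function(lab) {
  dims <- dim(lab)
  b <- array(FALSE, dims)
  b[c(1, dims[1]), , ] <- TRUE
  b[, c(1, dims[2]), ] <- TRUE
  b[, , c(1, dims[3])] <- TRUE
  for (axis in 1:3) {
    n <- dims[axis]
    lo <- seq_len(n - 1L)
    hi <- seq(2L, n)
    a1 <- switch(axis, lab[lo, , , drop = FALSE], lab[, lo, , drop = FALSE],
                 lab[, , lo, drop = FALSE])
    a2 <- switch(axis, lab[hi, , , drop = FALSE], lab[, hi, , drop = FALSE],
                 lab[, , hi, drop = FALSE])
    d <- a1 != a2
    if (axis == 1) {
      b[lo, , ] <- b[lo, , , drop = FALSE] | d
      b[hi, , ] <- b[hi, , , drop = FALSE] | d
    } else if (axis == 2) {
      b[, lo, ] <- b[, lo, , drop = FALSE] | d
      b[, hi, ] <- b[, hi, , drop = FALSE] | d
    } else {
      b[, , lo] <- b[, , lo, drop = FALSE] | d
      b[, , hi] <- b[, , hi, drop = FALSE] | d
    }
  }
  b
}

# exposed-face surface area (face count weighted by physical face areas),
# with a correction factor toward the area of the underlying smooth surface
surface_area <- function(coords_idx, lab, id, spacing, correction = 0.678) {
  dims <- dim(lab)
  face_area <- c(spacing[2] * spacing[3], # z-normal face
                 spacing[1] * spacing[3], # y-normal
                 spacing[1] * spacing[2]) # x-normal
  total <- 0
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- coords_idx
      nb[, axis] <- nb[, axis] + s
      inb <- nb[, axis] >= 1L & nb[, axis] <= dims[axis]
      exposed <- sum(!inb) + sum(lab[nb[inb, , drop = FALSE]] != id)
      total <- total + exposed * face_area[axis]
    }
  }
  total * correction
}

#' Per-segment features of a labelled volume
#'
#' Computes, for every cell segment, the border, position and shape/size
#' descriptors used by the confidence metric and the analysis layer:
#' border-to-interior intensity ratio and the Earth Mover's Distance
#' between their 32-bin intensity histograms; centroid (physical units),
#' centroid distance to the specimen surface, robust best-fit line, and --
#' when an AP axis is supplied -- relative position along, angle with and
#' distance to the axis; volume, border-to-centroid distance histogram
#' (normalized to max 1), sphericity, squareness, cylindricity, convexity,
#' eigenvalue entropy, elongation and flatness from PCA of the voxel
#' coordinates.
#'
#' Degenerate segments (collinear/coplanar) report `Inf` for elongation
#' and/or flatness; AP features are `NA` when no axis is given (absent,
#' not zero).
#'
#' @param map a [label_map()].
#' @param volume the parent [intensity_volume()].
#' @param ap optional [ap_axis()].
#' @param cylindricity_mode `"lowest"` (default) scores a segment by the
#'   worst-fitting of the three principal-axis enclosing cylinders,
#'   `"highest"` by the best-fitting one.
#' @param hist_bins intensity histogram bins (default 32).
#' @return data.frame (one row per segment) with columns `id`,
#'   `border_interior_ratio`, `border_interior_emd`, `centroid_z/y/x`,
#'   `surface_distance`, `line_dir_z/y/x`, `line_point_z/y/x`,
#'   `ap_position`, `ap_angle`, `ap_distance`, `volume`, `sphericity`,
#'   `squareness`, `cylindricity`, `convexity`, `eigen_entropy`,
#'   `elongation`, `flatness`, `lambda_max/med/min`, `n_voxels`,
#'   `n_boundary`, plus a list column `border_dist_hist`.
#' @export
compute_segment_features <- function(map, volume, ap = NULL,
                                     cylindricity_mode = c("lowest", "highest"),
                                     hist_bins = 32L) {
  cylindricity_mode <- match.arg(cylindricity_mode)
  lab <- map$labels
  v <- normalized_view(volume)
  spacing <- volume$spacing
  ids <- cell_ids(map)
  bmask <- boundary_mask(lab)
  # specimen surface distance field: distance of foreground to background
  fg <- lab >= 2L
  dist_surface <- cpp_edt(fg, spacing)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    sel <- lab == id
    coords <- which(sel, arr.ind = TRUE)
    nvox <- nrow(coords)
    on_b <- bmask[coords]
    bcoords <- coords[on_b, , drop = FALSE]
    icoords <- coords[!on_b, , drop = FALSE]
    if (nrow(icoords) == 0L) icoords <- coords # thin segment: no interior
    if (nrow(bcoords) == 0L) bcoords <- coords
    b_int <- v[bcoords]
    i_int <- v[icoords]
    ratio <- if (mean(i_int) == 0) Inf else mean(b_int) / mean(i_int)
    brk <- seq(0, 1, length.out = hist_bins + 1L)
    hb <- tabulate(pmin(findInterval(b_int, brk, rightmost.closed = TRUE),
                        hist_bins), hist_bins)
    hi <- tabulate(pmin(findInterval(i_int, brk, rightmost.closed = TRUE),
                        hist_bins), hist_bins)
    emd <- emd_1d(hb, hi, bin_width = 1 / hist_bins)
    phys <- sweep(coords, 2, spacing, `*`)
    ctr <- colMeans(phys)
    ctr_vox <- pmin(pmax(round(ctr / spacing), 1), dim(lab))
    surf_d <- dist_surface[ctr_vox[1], ctr_vox[2], ctr_vox[3]]
    fit <- if (nvox >= 2) best_fit_line(phys) else
      list(direction = c(NA, NA, NA), point = ctr)
    ap_pos <- ap_ang <- ap_dist <- NA_real_
    if (!is.null(ap)) {
      dd <- sqrt(colSums((t(ap$points) - ctr)^2))
      j <- which.min(dd)
      ap_pos <- ap$arc[j] / ap$length
      ap_dist <- dd[j]
      if (!any(is.na(fit$direction))) {
        ca <- abs(sum(ap$tangents[j, ] * fit$direction))
        ap_ang <- acos(pmin(ca, 1)) * 180 / pi
      }
    }
    vol_k <- nvox * prod(spacing)
    bphys <- sweep(bcoords, 2, spacing, `*`)
    bdist <- sqrt(rowSums(sweep(bphys, 2, ctr, `-`)^2))
    if (max(bdist) > 0) bdist <- bdist / max(bdist)
    bhist <- tabulate(pmin(findInterval(bdist, seq(0, 1, length.out = hist_bins + 1L),
                                        rightmost.closed = TRUE), hist_bins),
                      hist_bins)
    bhist <- bhist / sum(bhist)
    area <- surface_area(coords, lab, id, spacing)
    sphericity <- min(1, (36 * pi * vol_k^2)^(1 / 3) / area)
    cc <- sweep(phys, 2, ctr, `-`)
    ev <- eigen(cov_or_zero(cc), symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    axes <- ev$vectors
    proj <- cc %*% axes
    hax <- apply(abs(axes), 2, function(u) sum(u * spacing))
    ext <- apply(proj, 2, function(p) diff(range(p))) + hax
    squareness <- min(1, vol_k / prod(ext))
    cyl <- vapply(1:3, function(a) {
      h <- ext[a]
      others <- setdiff(1:3, a)
      rad <- sqrt(rowSums(proj[, others, drop = FALSE]^2))
      r <- max(rad) + mean(hax[others]) / 2
      min(1, vol_k / (pi * r^2 * h))
    }, 0)
    cylindricity <- if (cylindricity_mode == "lowest") min(cyl) else max(cyl)
    hull <- cpp_hull_volume(bphys)
    convexity <- if (hull > 0) min(1, vol_k / hull) else 1
    lamn <- lam / max(sum(lam), 1e-12)
    entropy <- -sum(ifelse(lamn > 0, lamn * log(lamn), 0))
    elongation <- if (lam[2] > 1e-9) lam[1] / lam[2] else Inf
    flatness <- if (lam[3] > 1e-9) lam[2] / lam[3] else Inf
    rows[[i]] <- data.frame(
      id = id,
      border_interior_ratio = ratio, border_interior_emd = emd,
      centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3],
      surface_distance = surf_d,
      line_dir_z = fit$direction[1], line_dir_y = fit$direction[2],
      line_dir_x = fit$direction[3],
      line_point_z = fit$point[1], line_point_y = fit$point[2],
      line_point_x = fit$point[3],
      ap_position = ap_pos, ap_angle = ap_ang, ap_distance = ap_dist,
      volume = vol_k, sphericity = sphericity, squareness = squareness,
      cylindricity = cylindricity, convexity = convexity,
      eigen_entropy = entropy, elongation = elongation, flatness = flatness,
      lambda_max = lam[1], lambda_med = lam[2], lambda_min = lam[3],
      n_voxels = nvox, n_boundary = sum(on_b),
      mean_boundary_intensity = mean(b_int),
      mean_interior_intensity = mean(i_int)
    )
    rows[[i]]$border_dist_hist <- list(bhist)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cov_or_zero <- function(cc) {
  if (nrow(cc) < 2L) return(diag(0, 3)) else cov(cc)
}

#' Segment adjacency graph with common-boundary statistics
#'
#' Two labels are adjacent when they share at least one face-adjacent
#' voxel pair. For each ordered pair `(k, j)` the edge stores the set size
#' `|B_kj|` of k-side boundary voxels touching j, the mean intensity over
#' those voxels (on the `[0, 1]` normalized volume), and `|B_k|`, the size
#' of k's full inner boundary. Both directions of every edge are kept
#' (their intensities may differ); the graph is symmetric as a relation.
#'
#' @param map a [label_map()].
#' @param volume the parent [intensity_volume()].
#' @return An `adjacency_graph`: list with `edges` (data.frame `k`, `j`,
#'   `n_shared`, `mean_intensity`, `boundary_k`) and `boundary_sizes`
#'   (named vector, full inner-boundary size per label).
#' @export
build_adjacency <- function(map, volume) {
  lab <- map$labels
  v <- normalized_view(volume)
  dims <- dim(lab)
  n <- length(lab)
  recs <- vector("list", 6L)
  r <- 0L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (axis in 1:3) {
    lo <- seq_len(dims[axis] - 1L)
    hi <- seq(2L, dims[axis])
    a1 <- switch(axis, lab[lo, , , drop = FALSE], lab[, lo, , drop = FALSE],
                 lab[, , lo, drop = FALSE])
    a2 <- switch(axis, lab[hi, , , drop = FALSE], lab[, hi, , drop = FALSE],
                 lab[, , hi, drop = FALSE])
    sel <- which(a1 != a2)
    # linear index of the low-side voxel of each differing face
    sub <- arrayInd(sel, dim(a1))
    idx1 <- 1L + (sub[, 1] - 1L) * strides[1] + (sub[, 2] - 1L) * strides[2] +
      (sub[, 3] - 1L) * strides[3]
    idx2 <- idx1 + strides[axis]
    r <- r + 1L
    recs[[r]] <- data.table::data.table(k = lab[idx1], j = lab[idx2],
                                        voxel = idx1)
    r <- r + 1L
    recs[[r]] <- data.table::data.table(k = lab[idx2], j = lab[idx1],
                                        voxel = idx2)
  }
  dt <- unique(data.table::rbindlist(recs))
  dt[, intensity := v[voxel]]
  k <- j <- voxel <- intensity <- NULL # NSE bindings
  edges <- dt[, list(n_shared = .N, mean_intensity = mean(intensity)),
              by = list(k, j)]
  bsz <- dt[, list(boundary = length(unique(voxel))), by = k]
  boundary_sizes <- setNames(bsz$boundary, bsz$k)
  # image-border voxels also belong to the inner boundary |B_k|
  bm <- boundary_mask(lab)
  full_b <- tapply(rep(1L, sum(bm)), lab[bm], sum)
  boundary_sizes <- setNames(as.integer(full_b), names(full_b))
  edges <- as.data.frame(edges)
  edges$boundary_k <- boundary_sizes[as.character(edges$k)]
  edges <- edges[order(edges$k, edges$j), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, boundary_sizes = boundary_sizes),
            class = "adjacency_graph")
}

#' Neighbour ids of a segment in an adjacency graph
#'
#' @param adjacency an `adjacency_graph`.
#' @param id segment id.
#' @param include_background keep the background label (default FALSE).
#' @export
neighbors_of <- function(adjacency, id, include_background = FALSE) {
  js <- adjacency$edges$j[adjacency$edges$k == id]
  if (!include_background) js <- js[js >= 2L]
  sort(unique(js))
}
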