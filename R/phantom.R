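#' Specification of a synthetic membrane phantom
#'
#' The phantom emulates the structure of a membrane/cell-wall channel: an
#' ellipsoidal "specimen" filled with a Voronoi tessellation of cells whose
#' shared faces (and the specimen surface) carry bright membrane signal,
#' plus Gaussian noise and optional random wall dropout mimicking weak
#' staining. The defaults are the reference study conditions used across
#' the test suite.
#'
#' @param dims grid shape `(nz, ny, nx)` (default 64^3).
#' @param n_cells number of cells (default 30).
#' @param membrane_level membrane intensity (default 0.8).
#' @param interior_level cell interior intensity (default 0.2).
#' @param background_level intensity outside the specimen (default 0.05).
#' @param noise_sd additive Gaussian noise sigma (default 0.05).
#' @param thickness membrane thickness in voxels (default 2).
#' @param dropout fraction of membrane area removed in random patches
#'   (default 0).
#' @param seed RNG seed (default 0).
#' @param spacing voxel spacing `(z, y, x)`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dims = c(64, 64, 64), n_cells = 30,
                         membrane_level = 0.8, interior_level = 0.2,
                         background_level = 0.05, noise_sd = 0.05,
                         thickness = 2, dropout = 0, seed = 0,
                         spacing = c(1, 1, 1)) {
  stopifnot(membrane_level > interior_level, dropout >= 0, dropout < 1,
            n_cells >= 1)
  structure(list(dims = as.integer(dims), n_cells = as.integer(n_cells),
                 membrane_level = membrane_level,
                 interior_level = interior_level,
                 background_level = background_level,
                 noise_sd = noise_sd, thickness = thickness,
                 dropout = dropout, seed = as.integer(seed),
                 spacing = as.numeric(spacing)),
            class = "phantom_spec")
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# ellipsoid geometry shared by the generators: centre, semi-axes (major
# axis along x so the anterior-posterior axis is well defined)
phantom_ellipsoid <- function(dims) {
  ctr <- (dims + 1) / 2
  semi <- c(0.85, 0.85, 1) * (dims / 2 - 3)
  list(ctr = ctr, semi = semi)
}

# normalized ellipsoid coordinate (<= 1 inside) for an (n x 3) matrix
ellipsoid_r <- function(pts, ell) {
  sqrt(rowSums(sweep(sweep(pts, 2, ell$ctr, `-`), 2, ell$semi, `/`)^2)
  )
}

# Poisson-disk (dart throwing) generator placement inside the ellipsoid
sample_generators <- function(spec, ell, cap = 0.82) {
  vol_ell <- 4 / 3 * pi * prod(ell$semi)
  rmin <- 0.7 * (cap / 0.82) * (vol_ell / spec$n_cells)^(1 / 3)
  pts <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(pts) < spec$n_cells) {
    tries <- tries + 1L
    if (tries > 500L * spec$n_cells)
      stop("infeasible packing: cannot place ", spec$n_cells,
           " generators at minimum distance ", signif(rmin, 3))
    cand <- ell$ctr + runif(3, -1, 1) * ell$semi * cap
    if (ellipsoid_r(matrix(cand, ncol = 3), ell) > cap) next
    if (nrow(pts) > 0 &&
        min(sqrt(rowSums(sweep(pts, 2, cand, `-`)^2))) < rmin) next
    pts <- rbind(pts, cand)
  }
  pts
}

# rasterize generators into (volume, truth, seeds) given an ellipsoid mask
rasterize_phantom <- function(spec, generators, noise_seed) {
  dims <- spec$dims
  ell <- phantom_ellipsoid(dims)
  grid <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                                x = seq_len(dims[3])))
  inside <- ellipsoid_r(grid, ell) <= 1
  n <- nrow(grid)
  lab <- rep(1L, n)
  membrane <- rep(FALSE, n)
  gi <- grid[inside, , drop = FALSE]
  # nearest and second-nearest generator
  d2 <- matrix(0, nrow(gi), nrow(generators))
  for (g in seq_len(nrow(generators))) {
    d2[, g] <- sqrt((gi[, 1] - generators[g, 1])^2 +
                      (gi[, 2] - generators[g, 2])^2 +
                      (gi[, 3] - generators[g, 3])^2)
  }
  nearest <- max.col(-d2, ties.method = "first")
  dn <- d2[cbind(seq_len(nrow(gi)), nearest)]
  d2[cbind(seq_len(nrow(gi)), nearest)] <- Inf
  dsecond <- apply(d2, 1, min)
  lab[inside] <- nearest + 1L # cell ids start at 2
  membrane[inside] <- (dsecond - dn) < spec$thickness
  lab_arr <- array(lab, dims)
  # specimen surface wall, centred on the ellipsoid boundary so that half
  # of its thickness lies inside the specimen and half outside
  inside_arr <- array(inside, dims)
  half <- spec$thickness / 2
  shell <- (inside_arr & cpp_edt(inside_arr, c(1, 1, 1)) <= half) |
    (!inside_arr & cpp_edt(!inside_arr, c(1, 1, 1)) <= half)
  mem_arr <- array(membrane, dims) | shell
  # membranes carry a PSF-like Gaussian cross-section peaking exactly at
  # the Voronoi face / specimen surface, as stained walls do under the
  # microscope (sigma = thickness / 2)
  sigma_m <- spec$thickness / 2
  face_dist <- array(Inf, dims)
  face_dist[inside_arr] <- (dsecond - dn) / 2
  surf_dist <- ifelse(inside_arr, cpp_edt(inside_arr, c(1, 1, 1)) - 0.5,
                      cpp_edt(!inside_arr, c(1, 1, 1)) - 0.5)
  profile <- pmax(exp(-face_dist^2 / (2 * sigma_m^2)),
                  exp(-surf_dist^2 / (2 * sigma_m^2)))
  base <- array(spec$background_level, dims)
  base[inside_arr] <- spec$interior_level
  v <- base + (spec$membrane_level - base) * profile
  seeds <- round(generators)
  rownames(seeds) <- seq_len(nrow(generators)) + 1L
  with_seed(noise_seed, {
    if (spec$dropout > 0) {
      mem_idx <- which(mem_arr & !shell)
      patch_r <- 2.5
      patch_size <- 4 / 3 * pi * patch_r^3 * spec$thickness / (2 * patch_r)
      n_patch <- ceiling(spec$dropout * length(mem_idx) / max(patch_size, 1))
      if (n_patch > 0 && length(mem_idx) > 0) {
        ctrs <- arrayInd(sample(mem_idx, min(n_patch, length(mem_idx))), dims)
        for (r in seq_len(nrow(ctrs))) {
          box <- abs(sweep(arrayInd(mem_idx, dims), 2, ctrs[r, ], `-`))
          hit <- sqrt(rowSums(box^2)) <= patch_r
          v[mem_idx[hit]] <- spec$interior_level
        }
      }
    }
    v <- v + rnorm(length(v), 0, spec$noise_sd)
  })
  v <- pmin(pmax(v, 0), 1)
  v <- array(v, dims)
  list(volume = intensity_volume(v, spec$spacing),
       truth = label_map(lab_arr, spec$spacing),
       seeds = seeds,
       generators = generators,
       spec = spec)
}

#' Generate a membrane phantom with ground truth
#'
#' Deterministic for a given spec (same seed gives a bitwise-identical
#' phantom). The returned truth label map tiles the entire grid:
#' background 1 outside the specimen, cell ids >= 2 inside (membrane
#' voxels belong to the nearest cell).
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_truth`: list with `volume` ([intensity_volume()]),
#'   `truth` ([label_map()]), `seeds` (one interior point per cell,
#'   rownames = cell ids), `generators` and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  generators <- with_seed(spec$seed, {
    ell <- phantom_ellipsoid(spec$dims)
    sample_generators(spec, ell)
  })
  out <- rasterize_phantom(spec, generators, noise_seed = spec$seed + 1L)
  class(out) <- "phantom_truth"
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s grid, %d cell(s)\n",
              paste(x$spec$dims, collapse = "x"), nrow(x$seeds)))
  invisible(x)
}

#' Generate a phantom time series with drift and optional division
#'
#' The generator points translate rigidly by `drift` voxels per frame; at
#' frame `divide_at` (if given) every cell's generator is replaced by two
#' offset generators, so the cell count doubles and mean cell volume
#' roughly halves. The noise realization differs per frame.
#'
#' @param spec a [phantom_spec()].
#' @param n_t number of frames (>= 1).
#' @param drift `(z, y, x)` translation per frame in voxels (scalar =
#'   x-only drift).
#' @param divide_at optional 0-based frame index at which cells divide.
#' @return list of `phantom_truth` objects, one per frame.
#' @export
generate_time_series <- function(spec = phantom_spec(), n_t = 3,
                                 drift = c(0, 0, 0), divide_at = NULL) {
  stopifnot(n_t >= 1)
  if (length(drift) == 1L) drift <- c(0, 0, drift)
  ell <- phantom_ellipsoid(spec$dims)
  # shrink the initial placement so the drifting tissue stays inside
  total <- (n_t - 1) * sqrt(sum(drift^2))
  cap <- max(0.4, 0.82 - total / min(ell$semi))
  generators <- with_seed(spec$seed, sample_generators(spec, ell, cap))
  frames <- vector("list", n_t)
  for (t in seq_len(n_t) - 1L) {
    g <- sweep(generators, 2, t * drift, `+`)
    if (!is.null(divide_at) && t >= divide_at) {
      g <- with_seed(spec$seed + 7L, {
        delta <- 0.35 * (4 / 3 * pi * prod(ell$semi) / nrow(g))^(1 / 3)
        u <- matrix(rnorm(3 * nrow(g)), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        gg <- rbind(g + delta * u, g - delta * u)
        # daughters of surface cells are pulled back inside the specimen
        r <- ellipsoid_r(gg, ell)
        out <- r > 0.9
        if (any(out)) {
          gg[out, ] <- ell$ctr +
            sweep(gg[out, , drop = FALSE], 2, ell$ctr, `-`) * (0.9 / r[out])
        }
        gg
      })
    }
    if (any(ellipsoid_r(g, ell) > 0.95))
      stop("drift pushes cells outside the specimen at frame ", t)
    sp <- spec
    sp$n_cells <- nrow(g)
    frames[[t + 1L]] <- rasterize_phantom(sp, g, noise_seed = spec$seed + 100L + t)
    class(frames[[t + 1L]]) <- "phantom_truth"
  }
  frames
}

# unique unordered face-adjacent label pairs of a label array
label_adjacent_pairs <- function(lab) {
  pairs <- list()
  dims <- dim(lab)
  slice <- function(a, axis, drop_last) {
    n <- dims[axis]
    idx <- if (drop_last) seq_len(n - 1L) else seq(2L, n)
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  for (axis in 1:3) {
    a <- slice(lab, axis, TRUE)
    b <- slice(lab, axis, FALSE)
    sel <- a != b
    pairs[[axis]] <- cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  unique(do.call(rbind, pairs))
}

#' Corrupt a ground-truth label map with merges and splits
#'
#' Creates the "incorrect segment" class used to exercise the confidence
#' metric: a fraction of adjacent cell pairs is merged (simulating missed
#' walls) and a fraction of cells is split by a random plane through the
#' centroid (simulating spurious walls / double-detected nuclei).
#'
#' @param truth a `phantom_truth` or [label_map()].
#' @param merges fraction of cells merged into a neighbour, in `[0, 1)`.
#' @param splits fraction of cells split in two, in `[0, 1)`.
#' @param seed RNG seed.
#' @return list with `label_map` (corrupted), `corrupted_ids` (ids of all
#'   affected segments in the output map), `merged_pairs` and `split_ids`.
#' @export
corrupt_labels <- function(truth, merges = 0.1, splits = 0.1, seed = 0) {
  map <- if (inherits(truth, "phantom_truth")) truth$truth else truth
  lab <- map$labels
  ids <- cell_ids(map)
  n <- length(ids)
  n_m <- round(merges * n)
  n_s <- round(splits * n)
  merged_pairs <- matrix(0L, 0, 2)
  split_ids <- integer(0)
  with_seed(seed, {
    if (n_m > 0) {
      adj <- label_adjacent_pairs(lab)
      adj <- adj[adj[, 1] >= 2L & adj[, 2] >= 2L, , drop = FALSE]
      adj <- adj[sample(nrow(adj)), , drop = FALSE]
      used <- integer(0)
      for (r in seq_len(nrow(adj))) {
        if (nrow(merged_pairs) >= n_m) break
        if (any(adj[r, ] %in% used)) next
        merged_pairs <- rbind(merged_pairs, adj[r, ])
        used <- c(used, adj[r, ])
      }
      for (r in seq_len(nrow(merged_pairs))) {
        lab[lab == merged_pairs[r, 2]] <- merged_pairs[r, 1]
      }
    }
    if (n_s > 0) {
      remaining <- setdiff(cell_ids(label_map(lab)), as.vector(merged_pairs))
      pick <- sample(remaining, min(n_s, length(remaining)))
      next_id <- max(lab) + 1L
      for (id in pick) {
        coords <- which(lab == id, arr.ind = TRUE)
        ctr <- colMeans(coords)
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        side <- as.matrix(sweep(coords, 2, ctr, `-`)) %*% u > 0
        if (!any(side) || all(side)) next
        lab[coords[side, , drop = FALSE]] <- next_id
        split_ids <- c(split_ids, id, next_id)
        next_id <- next_id + 1L
      }
    }
  })
  list(label_map = label_map(lab, map$spacing),
       corrupted_ids = sort(unique(c(merged_pairs[, 1], split_ids))),
       merged_pairs = merged_pairs, split_ids = split_ids)
}

#' Brick-tissue phantom: jittered cuboidal cells
#'
#' A compact tissue of roughly cuboidal cells (in the spirit of plant
#' epidermis) obtained by cutting a box with jittered axis-aligned
#' planes. Unlike the Voronoi phantom, every internal wall is a full
#' cell-face cross-section, so all true shared walls have substantial
#' area -- the geometry needed to probe merge-recommendation ranking
#' without the confound of tiny corner contacts.
#'
#' @param spec a [phantom_spec()]; `n_cells` is ignored in favour of
#'   `n_bricks`.
#' @param n_bricks bricks per axis `(z, y, x)` (default `c(2, 3, 3)`).
#' @param jitter cut-plane jitter as a fraction of brick size (default
#'   0.2).
#' @return A `phantom_truth` (see [generate_phantom()]).
#' @export
generate_brick_phantom <- function(spec = phantom_spec(dims = c(48, 48, 48)),
                                   n_bricks = c(2, 3, 3), jitter = 0.2) {
  dims <- spec$dims
  margin <- 3
  with_seed(spec$seed, {
    cuts <- lapply(1:3, function(a) {
      inner <- seq(margin + 0.5, dims[a] - margin + 0.5,
                   length.out = n_bricks[a] + 1L)
      w <- diff(inner[1:2])
      inner[-c(1, length(inner))] <- inner[-c(1, length(inner))] +
        runif(n_bricks[a] - 1L, -jitter * w, jitter * w)
      inner
    })
    grid <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    iv <- lapply(1:3, function(a)
      findInterval(grid[[a]], cuts[[a]])) # 0 = outside low, n+1 outside high
    inside1 <- lapply(1:3, function(a)
      iv[[a]] >= 1L & iv[[a]] <= n_bricks[a])
    lab <- array(1L, dims)
    idx <- as.matrix(expand.grid(z = iv[[1]], y = iv[[2]], x = iv[[3]]))
    ok <- as.vector(outer(outer(inside1[[1]], inside1[[2]], `&`),
                          inside1[[3]], `&`))
    brick_of <- (pmin(pmax(idx[, 1], 1L), n_bricks[1]) - 1L) +
      n_bricks[1] * (pmin(pmax(idx[, 2], 1L), n_bricks[2]) - 1L) +
      n_bricks[1] * n_bricks[2] * (pmin(pmax(idx[, 3], 1L), n_bricks[3]) - 1L)
    lab[ok] <- brick_of[ok] + 2L
    # distance to the nearest cut plane (including the box faces) per axis
    sigma_m <- spec$thickness / 2
    plane_d <- lapply(1:3, function(a)
      vapply(grid[[a]], function(p) min(abs(p - cuts[[a]])), 0))
    dmin <- pmin(array(rep(plane_d[[1]], times = dims[2] * dims[3]), dims),
                 array(rep(rep(plane_d[[2]], each = dims[1]),
                           times = dims[3]), dims),
                 array(rep(plane_d[[3]], each = dims[1] * dims[2]), dims))
    inside_arr <- lab >= 2L
    near_box <- array(TRUE, dims)
    for (a in 1:3) {
      rng <- range(cuts[[a]])
      coord <- switch(a,
                      array(rep(grid[[1]], times = dims[2] * dims[3]), dims),
                      array(rep(rep(grid[[2]], each = dims[1]),
                                times = dims[3]), dims),
                      array(rep(grid[[3]], each = dims[1] * dims[2]), dims))
      near_box <- near_box & coord > rng[1] - 3 * sigma_m &
        coord < rng[2] + 3 * sigma_m
    }
    profile <- exp(-dmin^2 / (2 * sigma_m^2)) * near_box
    base <- array(spec$background_level, dims)
    base[inside_arr] <- spec$interior_level
    v <- base + (spec$membrane_level - base) * profile
    v <- v + rnorm(length(v), 0, spec$noise_sd)
    v <- array(pmin(pmax(v, 0), 1), dims)
    ids <- sort(unique(lab[lab >= 2L]))
    seeds <- t(vapply(ids, function(id)
      round(colMeans(which(lab == id, arr.ind = TRUE))), numeric(3)))
    rownames(seeds) <- ids
    out <- list(volume = intensity_volume(v, spec$spacing),
                truth = label_map(lab, spec$spacing),
                seeds = seeds, generators = seeds, spec = spec)
    class(out) <- "phantom_truth"
    out
  })
}

#' Corrupt a nuclei seed set (detector-failure emulation)
#'
#' Emulates an imperfect nuclei detector: a fraction of true seeds is
#' dropped (missed nuclei, causing merged segments) and a fraction of
#' spurious seeds is added at random interior locations (false
#' detections, causing split segments).
#'
#' @param phantom a `phantom_truth`.
#' @param drop fraction of true seeds removed.
#' @param extra fraction of spurious seeds added (relative to the true
#'   count).
#' @param seed RNG seed.
#' @return (m x 3) matrix of corrupted seed coordinates.
#' @export
corrupt_seeds <- function(phantom, drop = 0.2, extra = 0.2, seed = 0) {
  seeds <- phantom$seeds
  n <- nrow(seeds)
  lab <- phantom$truth$labels
  with_seed(seed, {
    keep <- sort(sample(n, n - round(drop * n)))
    out <- seeds[keep, , drop = FALSE]
    n_extra <- round(extra * n)
    if (n_extra > 0) {
      fg <- which(lab >= 2L)
      pick <- arrayInd(sample(fg, 5L * n_extra), dim(lab))
      # keep spurious seeds away from membranes (a detector fires on
      # nuclei-like dark blobs, not on walls)
      v <- phantom$volume$data[pick]
      pick <- pick[order(v)[seq_len(n_extra)], , drop = FALSE]
      out <- rbind(out, pick)
    }
    rownames(out) <- NULL
    out
  })
}

#' Two-chamber phantom for geodesic wall-avoidance checks
#'
#' A box split by a bright wall with a single circular gap. Geodesic
#' strokes between seeds placed in the two chambers must pass through the
#' gap rather than across the wall.
#'
#' @param dims grid shape (default `c(16, 24, 40)`).
#' @param gap_radius radius of the hole in the wall (default 2.5 voxels).
#' @param membrane_level,interior_level,noise_sd intensity model.
#' @param seed RNG seed for the noise.
#' @return list with `volume`, `wall_mask` (logical array), `seed_a`,
#'   `seed_b` (voxels on either side of the wall).
#' @export
two_chamber_phantom <- function(dims = c(16, 24, 40), gap_radius = 2.5,
                                membrane_level = 0.8, interior_level = 0.1,
                                noise_sd = 0.02, seed = 0) {
  v <- array(interior_level, dims)
  wall <- array(FALSE, dims)
  xmid <- round(dims[3] / 2)
  wall[, , xmid] <- TRUE
  zc <- round(dims[1] / 2)
  yc <- round(dims[2] * 0.3) # off-centre gap so straight lines miss it
  grid <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2])))
  hole <- sqrt((grid[, 1] - zc)^2 + (grid[, 2] - yc)^2) <= gap_radius
  wall[cbind(grid[hole, ], xmid)] <- FALSE
  v[wall] <- membrane_level
  v <- with_seed(seed, v + rnorm(length(v), 0, noise_sd))
  v <- array(pmin(pmax(v, 0), 1), dims)
  list(volume = intensity_volume(v),
       wall_mask = wall,
       seed_a = c(zc, round(dims[2] * 0.7), round(dims[3] * 0.25)),
       seed_b = c(zc, round(dims[2] * 0.7), round(dims[3] * 0.75)))
}

#' Inject a spurious dim wall into a phantom
#'
#' Splits one cell of the ground truth in two by a plane through its
#' centroid and paints a weak wall (a stated fraction of the true membrane
#' level) at the interface in the intensity volume -- the classic
#' over-segmentation artifact that merge recommendations should rank
#' first.
#'
#' @param phantom a `phantom_truth`.
#' @param factor dim-wall intensity as a fraction of the membrane level
#'   (default 0.2).
#' @param seed RNG seed (cell choice and plane orientation).
#' @return list with `volume`, `label_map` (cell split in two) and `pair`
#'   (the two ids sharing the spurious wall).
#' @export
inject_dim_wall <- function(phantom, factor = 0.2, seed = 0) {
  lab <- phantom$truth$labels
  v <- phantom$volume$data
  spec <- phantom$spec
  with_seed(seed, {
    ids <- cell_ids(phantom$truth)
    sizes <- tabulate(lab, nbins = max(lab))[ids]
    id <- sample(ids[sizes >= quantile(sizes, 0.5)], 1)
    coords <- which(lab == id, arr.ind = TRUE)
    ctr <- colMeans(coords)
    # division-like split: across the cell's longest principal axis, as a
    # dividing cell would, so neither daughter is a sliver
    cc <- sweep(coords, 2, ctr, `-`)
    u <- eigen(cov(cc), symmetric = TRUE)$vectors[, 1]
    proj <- as.matrix(cc) %*% u
    new_id <- max(lab) + 1L
    lab[coords[proj > 0, , drop = FALSE]] <- new_id
    wall_sel <- abs(proj) < spec$thickness / 2
    v[coords[wall_sel, , drop = FALSE]] <-
      pmin(pmax(factor * spec$membrane_level +
                  rnorm(sum(wall_sel), 0, spec$noise_sd), 0), 1)
    list(volume = intensity_volume(v, spec$spacing),
         label_map = label_map(lab, spec$spacing),
         pair = c(id, new_id))
  })
}
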