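# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, expr, .fixture_cache)
  get(name, .fixture_cache)
}

# the reference phantom: 64^3, 30 cells, defaults
default_phantom <- function() cached("phantom", generate_phantom(phantom_spec()))

default_segmentation <- function() cached("seg", {
  ph <- default_phantom()
  run_iteration(ph$volume, marker_graph(ph$seeds, dim(ph$volume$data)))
})

# label map with a single foreground segment (id 2) from a logical mask
mask_map <- function(mask, spacing = c(1, 1, 1)) {
  lab <- array(1L, dim(mask))
  lab[mask] <- 2L
  label_map(lab, spacing)
}

flat_volume <- function(dims, level = 0.5, spacing = c(1, 1, 1)) {
  intensity_volume(array(level, dims), spacing)
}

digitized_ball <- function(radius = 10, pad = 3) {
  n <- 2L * (radius + pad)
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  mask <- array(FALSE, c(n, n, n))
  mask[co[rowSums(sweep(co, 2, rep(ctr, 3))^2) <= radius^2, ]] <- TRUE
  mask
}

digitized_cuboid <- function(sides = c(20, 10, 5), pad = 4) {
  dims <- sides + 2L * pad
  mask <- array(FALSE, dims)
  mask[pad + seq_len(sides[1]), pad + seq_len(sides[2]),
       pad + seq_len(sides[3])] <- TRUE
  mask
}

digitized_cylinder <- function(radius = 5, height = 30, pad = 4) {
  dims <- c(height + 2L * pad, 2L * (radius + pad), 2L * (radius + pad))
  ctr <- (dims[2] + 1) / 2
  mask <- array(FALSE, dims)
  co <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                              seq_len(dims[3])))
  sel <- co[, 1] > pad & co[, 1] <= pad + height &
    (co[, 2] - ctr)^2 + (co[, 3] - ctr)^2 <= radius^2
  mask[co[sel, ]] <- TRUE
  mask
}

# a voxel of cell `id` far from its true seed but >= 2.5 voxels inside the
# cell -- planting a seed there forces a genuine two-part split
far_interior_point <- function(phantom, id) {
  lab <- phantom$truth$labels
  seed <- phantom$seeds[rownames(phantom$seeds) == id, ]
  d <- markerseg:::cpp_edt(lab == id, c(1, 1, 1))
  cand <- which(lab == id & d >= 2.5, arr.ind = TRUE)
  cand[which.max(rowSums(sweep(cand, 2, seed, `-`)^2)), ]
}

# exhaustive-enumeration oracle for credit dissemination: the best product
# of similarities over ALL simple paths from any confirmed node
enumerate_credit <- function(n, edges, confirmed, default = 0.5) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    adj[[edges$k[r]]] <- rbind(adj[[edges$k[r]]], c(edges$j[r], edges$d[r]))
    adj[[edges$j[r]]] <- rbind(adj[[edges$j[r]]], c(edges$k[r], edges$d[r]))
  }
  best <- rep(NA_real_, n)
  for (src in confirmed) {
    walk <- function(v, visited, prod) {
      if (is.na(best[v]) || prod > best[v]) best[v] <<- prod
      a <- adj[[v]]
      if (is.null(a)) return()
      for (r in seq_len(nrow(a))) {
        u <- a[r, 1]
        if (!(u %in% visited)) walk(u, c(visited, u), prod * a[r, 2])
      }
    }
    walk(src, src, 1)
  }
  out <- rep(default, n)
  out[!is.na(best)] <- best[!is.na(best)]
  out[confirmed] <- 1
  out
}

random_credit_graph <- function(n_max = 8, e_max = 14) {
  n <- sample(3:n_max, 1)
  pairs <- t(combn(n, 2))
  ne <- min(sample(2:e_max, 1), nrow(pairs))
  ep <- pairs[sample(nrow(pairs), ne), , drop = FALSE]
  list(n = n,
       edges = data.frame(k = ep[, 1], j = ep[, 2], d = runif(ne, 0.1, 1)),
       confirmed = sample(n, sample(1:3, 1)))
}
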