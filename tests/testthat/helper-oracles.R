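# Shared fixtures and independent oracles for the suite. Oracles are coded
# from the stated rules with different data structures than the package
# implementation (linear min-scan flood instead of a heap; Floyd-Warshall
# instead of igraph), so agreement is a genuine cross-check.

# memoised small meshes
.mesh_cache <- new.env(parent = emptyenv())
test_icosphere <- function(subdivisions, medial_wall_frac = 0) {
  key <- paste0("s", subdivisions, "_", medial_wall_frac)
  if (is.null(.mesh_cache[[key]]))
    .mesh_cache[[key]] <- icosphere(subdivisions,
                                    medial_wall_frac = medial_wall_frac)
  .mesh_cache[[key]]
}

# brute-force watershed oracle: 3-ring plateau seeding, then a flood that
# repeatedly scans all unassigned defined vertices for the smallest
# (value, index) vertex with at least one labeled neighbor
oracle_flood <- function(values, mesh) {
  nv <- n_vertices(mesh)
  adj <- lapply(seq_len(nv), function(v) {
    tri <- mesh$triangles
    nb <- c(tri[tri[, 1] == v, 2:3], tri[tri[, 2] == v, c(1, 3)],
            tri[tri[, 3] == v, 1:2])
    sort(unique(nb))
  })
  def <- !mesh$medial_wall & !is.na(values)
  ring3 <- function(v) {
    out <- v
    for (i in 1:3) {
      nxt <- unique(unlist(adj[out]))
      out <- union(out, nxt[def[nxt]])
    }
    setdiff(out, v)
  }
  cand <- rep(FALSE, nv)
  for (v in which(def)) cand[v] <- all(values[v] <= values[ring3(v)])
  labels <- integer(nv)
  nl <- 0L
  seen <- rep(FALSE, nv)
  for (v in which(cand)) {          # plateau components, seed = min index
    if (seen[v]) next
    comp <- c()
    queue <- v
    seen[v] <- TRUE
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]])
        if (!seen[w] && cand[w] && def[w] && values[w] == values[u]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
    }
    nl <- nl + 1L
    labels[min(comp)] <- nl
  }
  boundary <- rep(FALSE, nv)
  repeat {
    open <- which(def & labels == 0L & !boundary)
    if (length(open) == 0) break
    has_nb <- vapply(open, function(v) any(labels[adj[[v]]] > 0L), logical(1))
    open <- open[has_nb]
    if (length(open) == 0) break
    v <- open[order(values[open], open)][1]   # linear min-scan "pop"
    ls <- unique(labels[adj[[v]]])
    ls <- ls[ls > 0L]
    if (length(ls) == 1L) labels[v] <- ls else boundary[v] <- TRUE
  }
  boundary[def & labels == 0L & !boundary] <- TRUE
  list(labels = labels, boundary = boundary)
}

# all-pairs shortest path lengths by Floyd-Warshall on a binary adjacency
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# oracle local efficiency: explicit formula on Floyd-Warshall distances
oracle_local_efficiency <- function(adj, node) {
  nbrs <- which(adj[node, ] == 1)
  if (length(nbrs) < 2) return(0)
  d <- oracle_floyd_warshall(adj[nbrs, nbrs, drop = FALSE])
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (length(nbrs) * (length(nbrs) - 1))
}

# threshold oracle replicating the stated rule: top frac of upper-triangle
# off-diagonal entries, ties by pair index
oracle_threshold <- function(r, frac) {
  n <- nrow(r)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[pairs]
  ord <- order(-vals, seq_along(vals))
  m <- ceiling(frac * nrow(pairs))
  adj <- matrix(0, n, n)
  for (i in ord[seq_len(m)]) {
    adj[pairs[i, 1], pairs[i, 2]] <- 1
    adj[pairs[i, 2], pairs[i, 1]] <- 1
  }
  adj
}

# border map of a planted parcellation: 1 where a vertex or its 1-ring
# touches at least two parcels
planted_border_map <- function(parc, mesh) {
  nv <- n_vertices(mesh)
  tri <- mesh$triangles
  adj <- lapply(seq_len(nv), function(v) {
    nb <- c(tri[tri[, 1] == v, 2:3], tri[tri[, 2] == v, c(1, 3)],
            tri[tri[, 3] == v, 1:2])
    sort(unique(nb))
  })
  out <- numeric(nv)
  for (v in which(!mesh$medial_wall)) {
    labs <- unique(parc$labels[c(v, adj[[v]])])
    labs <- labs[labs > 0]
    if (length(labs) >= 2) out[v] <- 1
  }
  scalar_map(out, mesh)
}

drop_zero <- function(labels) ifelse(labels > 0, labels, NA_integer_)

# minimal parcellation stand-in for network-level tests that supply
# precomputed parcel x time matrices
fake_parc <- function(n) {
  structure(list(labels = rep(seq_len(n), each = 1L),
                 boundary = logical(n),
                 parcel_table = data.frame(id = seq_len(n), hemisphere = "L",
                                           vertex_count = 1L),
                 hemisphere = "L"),
            class = "parcellation")
}
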