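# Watershed parcellation of a group local gradient map and parcel
# bookkeeping. Parcels are the watershed regions; ambiguous (boundary)
# vertices and the medial wall carry label 0, so borders separate parcels
# exactly as the flooding found them — no thresholding, no manual editing.

new_parcellation <- function(labels, mesh, boundary, provenance = "") {
  labels <- as.integer(labels)
  ids <- sort(unique(labels[labels > 0L]))
  # densify ids to 1..n
  if (length(ids) > 0L && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  n <- max(labels, 0L)
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  parcel_table <- data.frame(
    id = seq_len(n),
    hemisphere = rep(mesh$hemisphere, n),
    vertex_count = sizes)
  structure(list(labels = labels, boundary = as.logical(boundary),
                 parcel_table = parcel_table, provenance = provenance,
                 hemisphere = mesh$hemisphere),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation: ", nrow(x$parcel_table), " parcels (hemisphere ",
      x$hemisphere, ")\n  border vertices: ", sum(x$boundary),
      "; labeled vertices: ", sum(x$labels > 0L), "\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Watershed parcellation of a local gradient map
#'
#' Runs the same watershed flood as \code{\link{watershed_boundary_map}}
#' (3-ring minima seeds, globally ascending region growth, ambiguous
#' vertices become borders) but keeps the region labels: each basin of the
#' group local gradient map is one parcel. No thresholding and no manual
#' editing are applied.
#'
#' @param group_map local gradient map (per-vertex, \code{NA} = undefined).
#' @param mesh a \code{cortical_mesh}.
#' @param provenance free-text source description stored in the result.
#' @return a \code{parcellation}: per-vertex labels (0 = border or medial
#'   wall), boundary flags, and a parcel table of per-parcel vertex counts.
#' @export
watershed_parcellate <- function(group_map, mesh, provenance = "group map") {
  fl <- watershed_flood(group_map, mesh)
  new_parcellation(fl$labels, mesh, fl$boundary, provenance = provenance)
}

# parcel adjacency: two parcels are adjacent if joined by a mesh edge or by
# a shared border vertex touching both
parcel_adjacency_pairs <- function(parc, mesh) {
  tri <- mesh$triangles
  e <- unique(rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)]))
  la <- parc$labels[e[, 1L]]
  lb <- parc$labels[e[, 2L]]
  direct <- cbind(pmin(la, lb), pmax(la, lb))[la > 0L & lb > 0L & la != lb, ,
                                              drop = FALSE]
  adj <- mesh_adjacency(mesh)
  border <- which(parc$labels == 0L & !mesh$medial_wall)
  via_border <- lapply(border, function(v) {
    labs <- unique(parc$labels[adj[[v]]])
    labs <- labs[labs > 0L]
    if (length(labs) < 2L) return(NULL)
    pairs <- t(utils::combn(sort(labs), 2L))
    pairs
  })
  unique(rbind(direct, do.call(rbind, via_border)))
}

#' Merge over-segmented parcels
#'
#' Applies an explicit merge list (merging is data, not an automatic
#' over-segmentation detector). Each merge set must be connected through
#' parcel adjacency (shared edges or shared border vertices); border
#' vertices lying entirely between members of one merge set are absorbed
#' into the surviving parcel, and ids are re-densified to 1..n.
#'
#' @param parc a \code{parcellation}.
#' @param merge_list list of integer vectors; each vector's parcels are
#'   merged into its first element.
#' @param mesh the \code{cortical_mesh} of the parcellation.
#' @return merged \code{parcellation} with parcel count reduced by the
#'   number of absorbed ids.
#' @export
merge_parcels <- function(parc, merge_list, mesh) {
  if (length(merge_list) == 0L) return(parc)
  n <- nrow(parc$parcel_table)
  adj_pairs <- parcel_adjacency_pairs(parc, mesh)
  g <- igraph::graph_from_edgelist(adj_pairs, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  labels <- parc$labels
  boundary <- parc$boundary
  adj <- mesh_adjacency(mesh)
  for (set in merge_list) {
    set <- as.integer(set)
    if (any(set < 1L | set > n)) stop("unknown parcel id in merge set")
    if (length(unique(set)) < 2L) stop("merge sets need >= 2 parcels")
    sub <- igraph::induced_subgraph(g, set)
    if (igraph::components(sub)$no != 1L)
      stop("merge set {", paste(set, collapse = ", "),
           "} is not edge-adjacent (union disconnected)")
    target <- set[1L]
    labels[labels %in% set] <- target
    # absorb borders whose labeled neighbors all lie in the merged parcel
    for (v in which(labels == 0L & !mesh$medial_wall)) {
      nb <- labels[adj[[v]]]
      nb <- unique(nb[nb > 0L])
      if (length(nb) == 1L && nb == target) {
        labels[v] <- target
        boundary[v] <- FALSE
      }
    }
  }
  new_parcellation(labels, mesh, boundary,
                   provenance = paste0(parc$provenance, " + merges"))
}

#' Parcel count and size summary
#'
#' @param parc a \code{parcellation}.
#' @return list with \code{n_parcels}, \code{counts_by_hemisphere},
#'   \code{sizes} (vertices per parcel, label 0 excluded) and
#'   \code{size_histogram} (a table of parcel sizes).
#' @export
parcel_stats <- function(parc) {
  list(n_parcels = nrow(parc$parcel_table),
       counts_by_hemisphere = table(parc$parcel_table$hemisphere),
       sizes = parc$parcel_table$vertex_count,
       size_histogram = table(parc$parcel_table$vertex_count))
}
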