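# Spatial gradients of connectivity on the mesh and watershed boundary
# mapping. Row v of the second-order connectivity matrix is treated as a
# scalar map seeded at v; its first spatial derivative magnitude is the
# gradient map of that seed, watershed flooding of each gradient map yields
# a binary boundary map, and the vertex-wise average of all V boundary maps
# is the local gradient map: values near 1 mark putative areal borders.

# Per-triangle linear-interpolation gradient operator, memoised per mesh.
# For triangle (p1, p2, p3) with normal N = (p2-p1) x (p3-p1), the gradient
# of the hat function of vertex i is (N x e_i) / |N|^2 with e_i the
# opposite edge; the per-triangle gradient of a map is the value-weighted
# sum, which lies in the triangle plane (the local tangent plane of the
# sphere). Vertex magnitudes are area-weighted averages over incident
# triangles; triangles touching the medial wall are excluded.
mesh_gradient_operator <- function(mesh) {
  if (!is.null(mesh$cache$gradop)) return(mesh$cache$gradop)
  tri <- mesh$triangles
  nt <- nrow(tri)
  nv <- n_vertices(mesh)
  p1 <- mesh$sphere[tri[, 1L], , drop = FALSE]
  p2 <- mesh$sphere[tri[, 2L], , drop = FALSE]
  p3 <- mesh$sphere[tri[, 3L], , drop = FALSE]
  cross3 <- function(a, b)
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n <- cross3(p2 - p1, p3 - p1)
  n2 <- rowSums(n^2)
  area <- sqrt(n2) / 2
  degenerate <- which(area <= 1e-12 * mesh$radius^2)
  if (length(degenerate) > 0L)
    stop("degenerate (zero-area) triangle(s): ",
         paste(head(degenerate, 5L), collapse = ", "))
  g1 <- cross3(n, p3 - p2) / n2   # gradient of hat function at p1
  g2 <- cross3(n, p1 - p3) / n2
  g3 <- cross3(n, p2 - p1) / n2
  ii <- rep(seq_len(nt), 3L)
  jj <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  gop <- lapply(1:3, function(d)
    Matrix::sparseMatrix(i = ii, j = jj, x = c(g1[, d], g2[, d], g3[, d]),
                         dims = c(nt, nv)))
  # vertex averaging: area-weighted mean over incident non-medial triangles
  tri_ok <- !(mesh$medial_wall[tri[, 1L]] | mesh$medial_wall[tri[, 2L]] |
                mesh$medial_wall[tri[, 3L]])
  w <- area * tri_ok
  A <- Matrix::sparseMatrix(i = jj, j = ii, x = rep(w, 3L),
                            dims = c(nv, nt))
  rs <- Matrix::rowSums(A)
  keep <- rs > 0
  A[keep, ] <- A[keep, , drop = FALSE] / rs[keep]
  op <- list(gx = gop[[1L]], gy = gop[[2L]], gz = gop[[3L]], avg = A,
             vertex_ok = keep & !mesh$medial_wall)
  mesh$cache$gradop <- op
  op
}

#' Spatial gradient magnitude of a scalar map
#'
#' First spatial derivative of the map on the triangle mesh: per-triangle
#' linear-interpolation gradient vectors in the tangent plane, with
#' magnitudes area-averaged to vertices over incident triangles. Medial-wall
#' vertices and vertices with no valid incident triangle are \code{NA}.
#'
#' @param values scalar map (per-vertex numeric, \code{NA} = undefined).
#' @param mesh a \code{cortical_mesh}.
#' @return nonnegative per-vertex gradient magnitude map.
#' @export
spatial_gradient <- function(values, mesh) {
  out <- gradient_columns(matrix(values, ncol = 1L), mesh)
  scalar_map(out[, 1L], mesh)
}

# gradient magnitudes of each column of a V x n matrix of maps
gradient_columns <- function(mat, mesh) {
  op <- mesh_gradient_operator(mesh)
  col_bad <- colSums(is.na(mat[!mesh$medial_wall, , drop = FALSE])) > 0
  m0 <- ifelse(is.na(mat), 0, mat)
  gx <- as.matrix(op$gx %*% m0)
  gy <- as.matrix(op$gy %*% m0)
  gz <- as.matrix(op$gz %*% m0)
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  out <- as.matrix(op$avg %*% mag)
  out[!op$vertex_ok, ] <- NA_real_
  out[, col_bad] <- NA_real_
  out
}

#' Gradient matrix of second-order connectivity
#'
#' Applies \code{\link{spatial_gradient}} to every row of the RSFC-2nd
#' matrix: row v of the result is the gradient-magnitude map of the
#' connectivity profile seeded at vertex v.
#'
#' @param rsfc2 V x V second-order connectivity matrix.
#' @param mesh a \code{cortical_mesh}.
#' @return V x V nonnegative gradient matrix (undefined rows propagate as
#'   \code{NA} rows).
#' @export
gradient_matrix <- function(rsfc2, mesh) {
  if (nrow(rsfc2) != n_vertices(mesh))
    stop("matrix size does not match the mesh")
  t(gradient_columns(t(rsfc2), mesh))
}

# shared watershed core: labels (0 = border/undefined) + boundary flags
watershed_flood <- function(values, mesh) {
  csr <- mesh_adjacency_csr(mesh)
  defined <- !mesh$medial_wall
  if (all(is.na(values[defined])))
    stop("watershed input is undefined everywhere off the medial wall")
  .ws_flood(as.numeric(values), defined, csr$ptr, csr$idx)
}

#' Watershed boundary map of one gradient map
#'
#' Seeds are local minima of 3-ring neighborhoods (one seed per equal-value
#' plateau, lowest vertex index); regions grow in globally ascending
#' gradient order, and a vertex adjacent to two or more distinct regions
#' when reached is an ambiguous location: it is marked 1 (boundary), all
#' other defined vertices 0.
#'
#' @param gradient_row nonnegative gradient-magnitude map.
#' @param mesh a \code{cortical_mesh}.
#' @return binary scalar map (1 = boundary, \code{NA} = medial wall).
#' @export
watershed_boundary_map <- function(gradient_row, mesh) {
  fl <- watershed_flood(gradient_row, mesh)
  scalar_map(as.numeric(fl$boundary), mesh)
}

#' Local gradient map: average of binary boundary maps
#'
#' @param boundary_maps list of binary per-vertex maps (or a V x n matrix
#'   with one map per column), all on the same mesh.
#' @return per-vertex mean in [0, 1] with attribute \code{n_boundary_maps}.
#' @export
local_gradient_map <- function(boundary_maps) {
  if (is.list(boundary_maps)) {
    if (length(boundary_maps) == 0L) stop("empty boundary map list")
    boundary_maps <- do.call(cbind, boundary_maps)
  }
  if (NCOL(boundary_maps) == 0L) stop("empty boundary map list")
  vals <- boundary_maps[!is.na(boundary_maps)]
  if (!all(vals %in% c(0, 1)))
    stop("boundary maps must be binary")
  out <- rowMeans(boundary_maps)
  attr(out, "n_boundary_maps") <- ncol(boundary_maps)
  out
}

#' Local gradient map of one scan
#'
#' The per-scan pipeline: first-order RSFC, Fisher z, second-order
#' connectivity, gradient matrix, watershed boundary map of every row, and
#' their vertex-wise average. Watershed runs on the raw gradient rows
#' (averaging steps are explicitly unsmoothed).
#'
#' @param ts scan time series (\code{scan_timeseries} or matrix).
#' @param mesh a \code{cortical_mesh}.
#' @param rsfc2 optionally, a precomputed second-order matrix (skips the
#'   connectivity steps; used when visit-level RSFC-2nd averaging is on).
#' @param smooth_sigma Gaussian width (mm) for spatial smoothing of the
#'   vertex time courses before connectivity, the surface pipeline's
#'   pre-smoothing step; use \code{\link{scaled_smoothing_sigma}} for the
#'   mesh-resolution equivalent of the reference 2.55 mm kernel. 0
#'   disables smoothing.
#' @return local gradient map in [0, 1] with attribute
#'   \code{n_boundary_maps}.
#' @export
scan_gradient_map <- function(ts, mesh, rsfc2 = NULL, smooth_sigma = 0) {
  if (is.null(rsfc2)) {
    x <- ts_matrix(ts)
    if (smooth_sigma > 0) x <- smooth_columns(x, mesh, smooth_sigma)
    r <- compute_rsfc(x)
    z <- fisher_z(r)
    rsfc2 <- compute_second_order(z)
  }
  gm <- gradient_matrix(rsfc2, mesh)
  csr <- mesh_adjacency_csr(mesh)
  res <- .ws_boundary_rows(gm, !mesh$medial_wall, csr$ptr, csr$idx)
  if (res$n_valid == 0L) stop("no defined gradient rows")
  out <- res$counts / res$n_valid
  # vertices undefined in every gradient map (medial wall and its triangle
  # ring) stay undefined rather than reading as zero-gradient basins
  out[colSums(!is.na(gm)) == 0L] <- NA_real_
  out <- scalar_map(out, mesh)
  attr(out, "n_boundary_maps") <- res$n_valid
  out
}

#' Hierarchical averaging of local gradient maps
#'
#' Unweighted means taken level by level (scan -> session -> visit ->
#' age group -> age independent) so each unit of the grouped level
#' contributes equally: AP/PA maps average into a session map, session maps
#' into a visit map, visit maps into an age-group map, and the age-group
#' maps average (each group weighted equally) into the age-independent map.
#' No smoothing is applied at any level.
#'
#' @param maps V x n matrix of local gradient maps (one per column) or list
#'   of maps.
#' @param meta data.frame with one row per map; must contain the grouping
#'   columns needed for the requested level (\code{session_id},
#'   \code{visit_id}, \code{age_group}).
#' @param to target level: `"session"`, `"visit"`, `"age_group"` or
#'   `"age_independent"`.
#' @return list with \code{maps} (V x groups matrix, columns named by
#'   group) and \code{meta} (collapsed metadata).
#' @export
combine_maps <- function(maps, meta,
                         to = c("session", "visit", "age_group",
                                "age_independent")) {
  to <- match.arg(to)
  if (is.list(maps)) maps <- do.call(cbind, maps)
  if (ncol(maps) != nrow(meta))
    stop("one metadata row per map is required")
  levels_chain <- c("session_id", "visit_id", "age_group")
  n_steps <- switch(to, session = 1L, visit = 2L, age_group = 3L,
                    age_independent = 4L)
  for (step in seq_len(min(n_steps, 3L))) {
    key <- levels_chain[step]
    if (is.null(meta[[key]]))
      stop("metadata lacks grouping column '", key, "'")
    groups <- factor(meta[[key]], levels = unique(meta[[key]]))
    idx <- split(seq_len(ncol(maps)), groups)
    maps <- vapply(idx, function(i) rowMeans(maps[, i, drop = FALSE]),
                   numeric(nrow(maps)))
    meta <- meta[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (n_steps == 4L) {
    maps <- matrix(rowMeans(maps), ncol = 1L,
                   dimnames = list(NULL, "age_independent"))
    meta <- data.frame(age_group = "age_independent")
  }
  list(maps = maps, meta = meta)
}

#' Cross-group overlap consistency of high-gradient vertices
#'
#' Each map is binarized to its top fraction of defined values and the
#' binary maps are summed: a vertex value of m means the vertex is
#' high-gradient in m of the input maps.
#'
#' @param maps list or V x n matrix of local gradient maps.
#' @param top_frac fraction of highest defined values kept, in (0, 1].
#' @return integer-valued per-vertex map in \{0, ..., n maps\}.
#' @export
overlap_consistency <- function(maps, top_frac) {
  if (is.list(maps)) {
    if (length(maps) == 0L) stop("empty map list")
    maps <- do.call(cbind, maps)
  }
  if (NCOL(maps) == 0L) stop("empty map list")
  bins <- apply(maps, 2L, binarize_top, frac = top_frac)
  out <- rowSums(bins, na.rm = TRUE)
  out[rowSums(!is.na(bins)) == 0L] <- NA_real_
  out
}
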