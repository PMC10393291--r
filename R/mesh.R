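# Triangle-mesh and spherical-geometry primitives shared by all pipeline
# stages. Meshes are spherical cortical surfaces: each vertex has a 3D
# position (mm), a position on a sphere of fixed radius (default 100 mm,
# FreeSurfer-style), and a medial-wall flag. Vertex and triangle indices are
# 1-based throughout the package; the GIFTI I/O layer converts to the
# format's 0-based convention.

#' Construct a spherical cortical surface mesh
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates in mm.
#' @param triangles integer T x 3 matrix of 1-based vertex indices.
#' @param sphere numeric V x 3 matrix of per-vertex positions on a sphere of
#'   radius \code{radius}; defaults to \code{vertices} projected onto that
#'   sphere.
#' @param radius sphere radius in mm. All spherical distances (smoothing
#'   kernels, Hausdorff distances) are reported on this sphere.
#' @param medial_wall logical vector of length V flagging non-cortical
#'   vertices that are excluded from every functional computation.
#' @param hemisphere label, `"L"` or `"R"`.
#'
#' @return An object of class \code{cortical_mesh}: a list with fields
#'   \code{vertices}, \code{triangles}, \code{sphere}, \code{radius},
#'   \code{medial_wall}, \code{hemisphere} and a private cache environment
#'   used to memoise adjacency, gradient operators and smoothing kernels.
#'
#' Invariants checked at construction: all triangle indices in range, every
#' edge shared by at most two triangles (2-manifold), all sphere positions
#' within \code{1e-6 * radius} of the sphere.
#' @export
cortical_mesh <- function(vertices, triangles, sphere = NULL, radius = 100,
                          medial_wall = NULL, hemisphere = "L") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("'vertices' must be a V x 3 matrix")
  if (ncol(triangles) != 3L) stop("'triangles' must be a T x 3 matrix")
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv))
    stop("triangle indices out of range [1, ", nv, "]")
  if (is.null(sphere)) {
    nrm <- sqrt(rowSums(vertices^2))
    if (any(nrm == 0)) stop("cannot project zero vertex onto sphere")
    sphere <- vertices * (radius / nrm)
  } else {
    sphere <- as.matrix(sphere)
    storage.mode(sphere) <- "double"
    if (!all(dim(sphere) == c(nv, 3L)))
      stop("'sphere' must match the vertex count")
  }
  dev <- abs(sqrt(rowSums(sphere^2)) - radius)
  if (any(dev > 1e-6 * radius))
    stop("sphere coordinates off the radius-", radius,
         " sphere (max deviation ", format(max(dev)), " mm)")
  if (is.null(medial_wall)) medial_wall <- rep(FALSE, nv)
  medial_wall <- as.logical(medial_wall)
  if (length(medial_wall) != nv)
    stop("'medial_wall' must have one flag per vertex")
  hemisphere <- match.arg(hemisphere, c("L", "R"))

  # 2-manifold check: each undirected edge in at most 2 triangles
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(3L, 1L)])
  ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  if (any(table(ekey) > 2L))
    stop("mesh is not 2-manifold: an edge belongs to more than 2 triangles")

  mesh <- structure(
    list(vertices = vertices, triangles = triangles, sphere = sphere,
         radius = radius, medial_wall = medial_wall,
         hemisphere = hemisphere, cache = new.env(parent = emptyenv())),
    class = "cortical_mesh")
  mesh
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat("cortical_mesh: ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, hemisphere ", x$hemisphere,
      "\n  sphere radius ", x$radius, " mm; medial wall: ",
      sum(x$medial_wall), " vertices\n", sep = "")
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a \code{cortical_mesh}.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

# memoised vertex adjacency list (1-based integer vectors, sorted)
mesh_adjacency <- function(mesh) {
  if (!is.null(mesh$cache$adjacency)) return(mesh$cache$adjacency)
  tri <- mesh$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  adj <- split(e[, 2L], factor(e[, 1L], levels = seq_len(n_vertices(mesh))))
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  mesh$cache$adjacency <- adj
  adj
}

# adjacency in compressed form for the C++ flood: 0-based CSR
mesh_adjacency_csr <- function(mesh) {
  if (!is.null(mesh$cache$adj_csr)) return(mesh$cache$adj_csr)
  adj <- mesh_adjacency(mesh)
  idx <- unlist(adj, use.names = FALSE) - 1L
  ptr <- c(0L, cumsum(vapply(adj, length, integer(1))))
  csr <- list(ptr = as.integer(ptr), idx = as.integer(idx))
  mesh$cache$adj_csr <- csr
  csr
}

#' k-ring neighborhood of a vertex
#'
#' All vertices reachable from \code{vertex} by at most \code{k} mesh edges,
#' including the vertex itself. Used for watershed seeding (3-ring minima)
#' and for the patch variability map (10-ring patches).
#'
#' @param mesh a \code{cortical_mesh}.
#' @param vertex 1-based vertex index.
#' @param k nonnegative ring count.
#' @return sorted integer vector of vertex indices.
#' @export
k_ring_neighborhood <- function(mesh, vertex, k) {
  nv <- n_vertices(mesh)
  vertex <- as.integer(vertex)
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1L || vertex > nv)
    stop("vertex index out of range [1, ", nv, "]")
  k <- as.integer(k)
  if (k < 0L) stop("'k' must be >= 0")
  adj <- mesh_adjacency(mesh)
  seen <- logical(nv)
  seen[vertex] <- TRUE
  frontier <- vertex
  for (i in seq_len(k)) {
    if (length(frontier) == 0L) break
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  sort(which(seen))
}

#' Great-circle distance between points on a sphere
#'
#' @param a,b numeric length-3 vectors or n x 3 matrices of positions on the
#'   sphere of the given radius.
#' @param radius sphere radius in mm.
#' @param tol relative tolerance for the on-sphere check.
#' @return distance(s) in mm, in \code{[0, pi * radius]}.
#' @export
geodesic_sphere_distance <- function(a, b, radius = 100, tol = 1e-6) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (any(abs(sqrt(rowSums(a^2)) - radius) > tol * radius) ||
      any(abs(sqrt(rowSums(b^2)) - radius) > tol * radius))
    stop("input positions are not on the sphere of radius ", radius)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  # half-chord form: numerically stable near 0 and pi
  u <- a / radius
  v <- b / radius
  half <- sqrt(rowSums((u - v)^2)) / 2
  ang <- 2 * asin(pmin(1, half))
  d <- radius * ang
  if (length(d) == 1L) d[[1L]] else d
}

# full pairwise great-circle distance matrix between two index sets
sphere_distance_matrix <- function(mesh, idx_a, idx_b) {
  u <- mesh$sphere[idx_a, , drop = FALSE] / mesh$radius
  v <- mesh$sphere[idx_b, , drop = FALSE] / mesh$radius
  cosang <- tcrossprod(u, v)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  mesh$radius * acos(cosang)
}

#' Scalar map on a mesh
#'
#' A scalar map is a plain numeric vector with one value per vertex;
#' medial-wall (and otherwise undefined) vertices carry \code{NA}, never a
#' silent zero, so they cannot leak into averages. This helper validates the
#' length and masks the medial wall.
#'
#' @param values numeric vector of length \code{n_vertices(mesh)}.
#' @param mesh a \code{cortical_mesh}.
#' @param smoothing_sigma smoothing already applied, mm (0 = unsmoothed).
#' @return numeric vector with medial-wall entries set to \code{NA} and a
#'   \code{smoothing_sigma} attribute.
#' @export
scalar_map <- function(values, mesh, smoothing_sigma = 0) {
  values <- as.numeric(values)
  if (length(values) != n_vertices(mesh))
    stop("map length ", length(values), " != vertex count ",
         n_vertices(mesh))
  values[mesh$medial_wall] <- NA_real_
  attr(values, "smoothing_sigma") <- smoothing_sigma
  values
}

# Gaussian smoothing kernel on the sphere, memoised per (mesh, sigma).
# Great-circle distances within a 3*sigma cutoff, collected by expanding
# rings; rows and columns restricted to non-medial-wall vertices. The
# nonnegative symmetric weight matrix is balanced to be doubly stochastic
# (Sinkhorn), so constants are fixed points and the map mean over defined
# vertices is preserved.
smoothing_matrix <- function(mesh, sigma) {
  key <- paste0("smooth_", format(sigma, digits = 12))
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  nv <- n_vertices(mesh)
  defined <- !mesh$medial_wall
  adj <- mesh_adjacency(mesh)
  cutoff <- 3 * sigma
  ii <- vector("list", nv)
  jj <- vector("list", nv)
  xx <- vector("list", nv)
  for (v in which(defined)) {
    # expanding-ring BFS until a whole ring falls outside the cutoff
    seen <- v
    frontier <- v
    repeat {
      nb <- unique(unlist(adj[frontier], use.names = FALSE))
      nb <- setdiff(nb, seen)
      if (length(nb) == 0L) break
      d <- geodesic_sphere_distance(mesh$sphere[v, ],
                                    mesh$sphere[nb, , drop = FALSE],
                                    mesh$radius)
      seen <- c(seen, nb)
      frontier <- nb
      if (min(d) > cutoff) break
    }
    nbhd <- seen[defined[seen]]
    d <- geodesic_sphere_distance(mesh$sphere[v, ],
                                  mesh$sphere[nbhd, , drop = FALSE],
                                  mesh$radius)
    keep <- d <= cutoff
    nbhd <- nbhd[keep]
    w <- exp(-d[keep]^2 / (2 * sigma^2))
    ii[[v]] <- rep.int(v, length(nbhd))
    jj[[v]] <- nbhd
    xx[[v]] <- w
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nv, nv))
  W <- (W + Matrix::t(W)) / 2   # enforce exact symmetry of the raw kernel
  # Sinkhorn balancing on the defined block: the doubly stochastic kernel
  # fixes constants (row sums 1) and preserves the map mean (column sums 1)
  for (it in seq_len(500)) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
    cs <- Matrix::colSums(W)
    cs[cs == 0] <- 1
    W <- W %*% Matrix::Diagonal(x = 1 / cs)
    if (max(abs(Matrix::rowSums(W)[defined] - 1)) < 1e-13) break
  }
  rs <- Matrix::rowSums(W)
  rs[rs == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / rs) %*% W   # exact row sums
  mesh$cache[[key]] <- W
  W
}

#' Smooth a scalar map on the sphere with a Gaussian kernel
#'
#' Geodesic (great-circle) Gaussian weighted averaging within a 3-sigma
#' cutoff. Medial-wall vertices contribute no weight and remain \code{NA}.
#' The kernel is normalized so that constant maps are unchanged and the map
#' mean over defined vertices is preserved. A kernel with \code{sigma = 0}
#' is the identity.
#'
#' @param values scalar map (numeric per-vertex vector, \code{NA} =
#'   undefined).
#' @param mesh a \code{cortical_mesh}.
#' @param sigma kernel width in mm; the surface pipeline default for BOLD
#'   time courses is 2.55 mm.
#' @return smoothed scalar map with updated \code{smoothing_sigma}.
#' @export
smooth_scalar_map <- function(values, mesh, sigma) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  values <- scalar_map(values, mesh,
                       smoothing_sigma = attr(values, "smoothing_sigma") %||% 0)
  if (sigma == 0) return(values)
  W <- smoothing_matrix(mesh, sigma)
  ok <- !is.na(values)
  v0 <- ifelse(ok, values, 0)
  num <- as.numeric(W %*% v0)
  den <- as.numeric(W %*% as.numeric(ok))
  out <- ifelse(ok & den > 0, num / den, NA_real_)
  out <- scalar_map(out, mesh,
                    smoothing_sigma = sqrt((attr(values, "smoothing_sigma") %||% 0)^2 + sigma^2))
  out
}

#' Mean mesh edge length
#'
#' Average great-circle length of the mesh edges (mm on the sphere), the
#' natural resolution unit of the mesh.
#'
#' @param mesh a \code{cortical_mesh}.
#' @return mean edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  if (!is.null(mesh$cache$mean_edge)) return(mesh$cache$mean_edge)
  tri <- mesh$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  d <- geodesic_sphere_distance(mesh$sphere[e[, 1L], , drop = FALSE],
                                mesh$sphere[e[, 2L], , drop = FALSE],
                                mesh$radius)
  mesh$cache$mean_edge <- mean(d)
  mesh$cache$mean_edge
}

#' Resolution-scaled BOLD smoothing width
#'
#' The surface pipeline smooths vertex time courses with a small Gaussian
#' kernel of sigma 2.55 mm on a 32k surface whose vertices are about 2 mm
#' apart — a kernel of about 1.275 edge lengths. On meshes of a different
#' resolution the same physical width is meaningless (it can fall entirely
#' between vertices), so this helper scales the kernel to the mesh: sigma =
#' \code{sigma_mm / reference_edge_mm} times the mesh's mean edge length.
#'
#' @param mesh a \code{cortical_mesh}.
#' @param sigma_mm kernel width on the reference surface (default 2.55).
#' @param reference_edge_mm vertex spacing of the reference surface
#'   (default 2).
#' @return kernel width in mm on this mesh's sphere.
#' @export
scaled_smoothing_sigma <- function(mesh, sigma_mm = 2.55,
                                   reference_edge_mm = 2) {
  (sigma_mm / reference_edge_mm) * mean_edge_length(mesh)
}

# smooth each column of a V x n matrix with the shared kernel
smooth_columns <- function(mat, mesh, sigma) {
  if (sigma == 0) return(mat)
  W <- smoothing_matrix(mesh, sigma)
  ok <- !is.na(mat)
  num <- as.matrix(W %*% ifelse(ok, mat, 0))
  den <- as.matrix(W %*% (ok * 1))
  out <- num / den
  out[den == 0] <- NA_real_
  out[mesh$medial_wall, ] <- NA_real_
  out
}
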