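# Evaluation battery for local gradient maps and parcellations:
# split-half reproducibility of binarized gradient maps (dice), parcel
# homogeneity (percent variance explained by the first principal component
# of vertex connectivity profiles), parcel profile variance, rotation null
# parcellations preserving parcel number and size, rank-based null
# comparison, spherical Hausdorff border distance, and the patch-
# correlation variability map between two gradient maps.

#' Binarize a map to its top fraction of values
#'
#' Exactly \code{ceiling(frac * N_defined)} vertices are set to 1 (the
#' highest values; ties at the cutoff resolved by lower vertex index), all
#' other defined vertices 0, undefined vertices \code{NA}.
#'
#' @param values per-vertex map.
#' @param frac fraction in (0, 1].
#' @return binary per-vertex map.
#' @export
binarize_top <- function(values, frac) {
  if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  defined <- which(!is.na(values))
  m <- ceiling(frac * length(defined))
  out <- rep(NA_real_, length(values))
  out[defined] <- 0
  ord <- defined[order(-values[defined], defined)]
  out[ord[seq_len(m)]] <- 1
  out
}

#' Dice overlap of two binary maps
#'
#' \code{2 |A n B| / (|A| + |B|)}, in [0, 1]. Two empty sets are identical
#' emptiness and score 1 by convention.
#'
#' @param a,b binary per-vertex maps (NAs treated as 0).
#' @return dice coefficient.
#' @export
dice <- function(a, b) {
  if (length(a) != length(b)) stop("maps differ in length")
  A <- !is.na(a) & a == 1
  B <- !is.na(b) & b == 1
  if (!any(A) && !any(B)) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}

#' Split-half reproducibility of the group local gradient map
#'
#' Subjects are repeatedly split into disjoint "generating" and "repeating"
#' halves; each half's maps are averaged, binarized to the top
#' \code{frac} of values (default the highest 25\%), and compared with the
#' dice overlap. Returns the distribution over repetitions.
#'
#' @param subject_maps V x S matrix (or list) of per-subject local gradient
#'   maps.
#' @param n_rep repetitions (default 1000).
#' @param frac binarization fraction (default 0.25).
#' @param seed RNG seed.
#' @return list with \code{mean}, \code{sd} and \code{samples}.
#' @export
split_half_reproducibility <- function(subject_maps, n_rep = 1000,
                                       frac = 0.25, seed = 1L) {
  if (is.list(subject_maps)) subject_maps <- do.call(cbind, subject_maps)
  s <- ncol(subject_maps)
  if (s < 2L) stop("need at least 2 subjects")
  set.seed(seed)
  samples <- vapply(seq_len(n_rep), function(i) {
    half <- sample(s, floor(s / 2))
    g1 <- rowMeans(subject_maps[, half, drop = FALSE])
    g2 <- rowMeans(subject_maps[, -half, drop = FALSE])
    dice(binarize_top(g1, frac), binarize_top(g2, frac))
  }, numeric(1))
  list(mean = mean(samples), sd = sd(samples), samples = samples)
}

#' Parcel homogeneity: percent variance of the first principal component
#'
#' For each parcel, the vertex connectivity profiles are entered into a
#' principal component analysis (uncentered: the components decompose the
#' profiles themselves, so a parcel whose vertices share one profile is
#' rank one and maximally homogeneous); homogeneity is
#' \code{100 * lambda_1 / sum(lambda)}. Single-vertex parcels are 100 by
#' convention and flagged.
#'
#' @param parc a \code{parcellation}.
#' @param vertex_profiles V x D matrix of per-vertex connectivity profiles
#'   (e.g. subject-mean correlation profiles).
#' @return numeric vector of per-parcel homogeneity (percent), with
#'   attribute \code{flagged} marking single-vertex parcels.
#' @export
parcel_homogeneity <- function(parc, vertex_profiles) {
  n <- nrow(parc$parcel_table)
  out <- numeric(n)
  flagged <- logical(n)
  for (p in seq_len(n)) {
    verts <- which(parc$labels == p)
    x <- vertex_profiles[verts, , drop = FALSE]
    x <- x[, colSums(is.na(x)) == 0L, drop = FALSE]
    if (nrow(x) < 2L) {
      out[p] <- 100
      flagged[p] <- TRUE
      next
    }
    tot <- sum(x^2)
    if (tot == 0) {
      out[p] <- 100
      next
    }
    # dual form: eigenvalues of the (n_vert x n_vert) Gram matrix share the
    # nonzero spectrum of the profile scatter matrix
    lam1 <- eigen(tcrossprod(x), symmetric = TRUE,
                  only.values = TRUE)$values[1L]
    out[p] <- 100 * lam1 / tot
  }
  attr(out, "flagged") <- flagged
  out
}

#' Parcel profile variance
#'
#' For each parcel, form the matrix whose columns are the z-scored
#' connectivity profiles of the parcel's vertices; the parcel value is the
#' sum over profile dimensions (rows) of the standard deviation across
#' vertices (columns). The map-level value is the mean over parcels.
#' Single-vertex parcels are 0 and flagged.
#'
#' @param parc a \code{parcellation}.
#' @param z_profiles V x D matrix of per-vertex z-profiles (subject-average
#'   z-scores).
#' @return list with \code{per_parcel} (attribute \code{flagged}) and
#'   \code{map_mean}.
#' @export
parcel_variance <- function(parc, z_profiles) {
  n <- nrow(parc$parcel_table)
  out <- numeric(n)
  flagged <- logical(n)
  for (p in seq_len(n)) {
    verts <- which(parc$labels == p)
    x <- z_profiles[verts, , drop = FALSE]
    x <- x[, colSums(is.na(x)) == 0L, drop = FALSE]
    if (nrow(x) < 2L) {
      flagged[p] <- TRUE
      next
    }
    out[p] <- sum(apply(x, 2L, sd))
  }
  attr(out, "flagged") <- flagged
  list(per_parcel = out, map_mean = mean(out))
}

# rotation matrix from angles about x, y, z (applied in that fixed order)
rotation_matrix_xyz <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rotation null parcellations
#'
#' Each null applies one random rigid rotation (independent angles uniform
#' on [0, 2 pi) about x, y and z, in that order) to the whole parcellation
#' on the sphere, relocating every parcel while preserving parcel number
#' and (up to nearest-vertex resampling) parcel sizes. Null labels are
#' obtained by pulling each vertex back through the inverse rotation and
#' copying the label of the nearest original vertex. Parcels losing at
#' least half of their vertex count to the medial wall in a null are
#' flagged for that null.
#'
#' @param parc a \code{parcellation}.
#' @param mesh the spherical \code{cortical_mesh}.
#' @param n ensemble size (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @return object of class \code{null_ensemble}: rotation angles (n x 3),
#'   label matrix (n x V), medial-wall flags (n x parcels), seed.
#' @export
generate_null_parcellations <- function(parc, mesh, n = 1000, seed = 1L) {
  if (n < 1L) stop("'n' must be >= 1")
  set.seed(seed)
  nv <- n_vertices(mesh)
  np <- nrow(parc$parcel_table)
  angles <- matrix(runif(3L * n, 0, 2 * pi), n, 3L)
  labels <- matrix(0L, n, nv)
  mw_flag <- matrix(FALSE, n, np)
  orig_sizes <- parc$parcel_table$vertex_count
  for (i in seq_len(n)) {
    rot <- rotation_matrix_xyz(angles[i, 1L], angles[i, 2L], angles[i, 3L])
    back <- mesh$sphere %*% rot   # pullback: R^T p, as p %*% R
    nn <- nearest_vertex(mesh, back)
    lab <- parc$labels[nn]
    lab[mesh$medial_wall] <- 0L
    labels[i, ] <- lab
    null_sizes <- tabulate(lab[lab > 0L], nbins = np)
    mw_flag[i, ] <- null_sizes < 0.5 * orig_sizes
  }
  structure(list(rotations = angles, labels = labels, mw_flag = mw_flag,
                 n = n, seed = seed, parcel_table = parc$parcel_table),
            class = "null_ensemble")
}

#' Evaluate homogeneity/variance over a null ensemble
#'
#' Computes the chosen metric for every parcel of every null parcellation.
#' A parcel's per-null value is dropped where the parcel was rotated into
#' the medial wall (flagged); the per-parcel null reference is the average
#' over its surviving rotated versions, and each null's map-level value
#' averages its surviving parcels.
#'
#' @param ensemble a \code{null_ensemble}.
#' @param mesh the \code{cortical_mesh}.
#' @param profiles V x D vertex profile matrix (correlation profiles for
#'   homogeneity, z-profiles for variance).
#' @param metric `"homogeneity"` or `"variance"`.
#' @return list with \code{per_null} (map-level value per null) and
#'   \code{per_parcel} (average over surviving rotations).
#' @export
evaluate_nulls <- function(ensemble, mesh, profiles,
                           metric = c("homogeneity", "variance")) {
  metric <- match.arg(metric)
  np <- nrow(ensemble$parcel_table)
  vals <- matrix(NA_real_, ensemble$n, np)
  for (i in seq_len(ensemble$n)) {
    parc_i <- structure(list(labels = ensemble$labels[i, ],
                             parcel_table = ensemble$parcel_table),
                        class = "parcellation")
    v <- if (metric == "homogeneity") {
      parcel_homogeneity(parc_i, profiles)
    } else {
      parcel_variance(parc_i, profiles)$per_parcel
    }
    v[ensemble$mw_flag[i, ]] <- NA_real_
    lab_i <- ensemble$labels[i, ]
    sizes_i <- tabulate(lab_i[lab_i > 0L], nbins = np)
    v[sizes_i == 0L] <- NA_real_
    vals[i, ] <- v
  }
  list(per_null = rowMeans(vals, na.rm = TRUE),
       per_parcel = colMeans(vals, na.rm = TRUE))
}

#' Rank-based one-sided null comparison
#'
#' Permutation-style p-value with the add-one rank formula:
#' \code{p = (1 + #\{nulls at or beyond the real value\}) / (1 + n)}.
#'
#' @param real_value observed map-level value.
#' @param null_values vector of null map-level values.
#' @param direction `"greater"` if large real values are evidence (nulls at
#'   or above count), `"less"` if small ones are.
#' @return p-value.
#' @export
null_comparison <- function(real_value, null_values,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(null_values) == 0L) stop("empty null distribution")
  beyond <- if (direction == "greater") sum(null_values >= real_value)
            else sum(null_values <= real_value)
  (1 + beyond) / (1 + length(null_values))
}

#' Spherical Hausdorff distance between two border vertex sets
#'
#' Maximum over both directed Hausdorff distances, with point-to-set
#' distances measured as great-circle distances (mm) on the mesh's sphere.
#'
#' @param borders_a,borders_b nonempty vertex index sets.
#' @param mesh the spherical \code{cortical_mesh}.
#' @return Hausdorff distance in mm.
#' @export
hausdorff_spherical <- function(borders_a, borders_b, mesh) {
  if (length(borders_a) == 0L || length(borders_b) == 0L)
    stop("border sets must be nonempty")
  d <- sphere_distance_matrix(mesh, borders_a, borders_b)
  max(max(apply(d, 1L, min)), max(apply(d, 2L, min)))
}

#' Patch-correlation variability between two local gradient maps
#'
#' At each vertex v, the two maps' values over the k-ring patch around v
#' (default 10 rings) are extracted and the variability is
#' \code{0.5 * (1 - cor(pv1, pv2))}, in [0, 1]: 0 where the maps agree
#' perfectly over the patch, 1 where they are perfectly anti-correlated.
#' Vertices whose patch has fewer than 3 jointly defined values, or a
#' constant patch in either map, are \code{NA}.
#'
#' @param g1,g2 local gradient maps on \code{mesh}.
#' @param mesh a \code{cortical_mesh}.
#' @param ring patch radius in rings (default 10).
#' @return per-vertex variability map.
#' @export
variability_between <- function(g1, g2, mesh, ring = 10) {
  nv <- n_vertices(mesh)
  if (length(g1) != nv || length(g2) != nv)
    stop("maps do not match the mesh")
  out <- rep(NA_real_, nv)
  for (v in which(!mesh$medial_wall)) {
    patch <- k_ring_neighborhood(mesh, v, ring)
    p1 <- g1[patch]
    p2 <- g2[patch]
    ok <- !is.na(p1) & !is.na(p2)
    if (sum(ok) < 3L) next
    if (sd(p1[ok]) == 0 || sd(p2[ok]) == 0) next
    out[v] <- 0.5 * (1 - cor(p1[ok], p2[ok]))
  }
  pmin(pmax(out, 0), 1)
}
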