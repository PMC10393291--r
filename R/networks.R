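# Parcel-level network discovery: per-subject parcel connectivity
# binarized to the top 10% of correlations so every subject contributes
# the same number of connections, group averaging, clustering of
# connectivity profiles (spherical k-means over cosine similarity — the
# documented stand-in for the mixture-model clustering this workflow
# delegates to), split-half stability over k with an Amari-type
# clustering similarity, and bootstrap assignment reproducibility.

#' Mean time course of each parcel
#'
#' Unweighted vertex mean per parcel; border and medial-wall vertices
#' (label 0) are excluded. Parcels left empty after exclusions yield
#' \code{NA} rows and are flagged.
#'
#' @param ts scan time series (\code{scan_timeseries} or V x T matrix).
#' @param parc a \code{parcellation}.
#' @return parcels x T matrix with attribute \code{empty_parcels}.
#' @export
parcel_mean_timecourses <- function(ts, parc) {
  x <- ts_matrix(ts)
  if (nrow(x) != length(parc$labels))
    stop("time series does not match the parcellation")
  np <- nrow(parc$parcel_table)
  out <- matrix(NA_real_, np, ncol(x))
  for (p in seq_len(np)) {
    verts <- which(parc$labels == p)
    rows <- x[verts, , drop = FALSE]
    rows <- rows[rowSums(is.na(rows)) == 0L, , drop = FALSE]
    if (nrow(rows) > 0L) out[p, ] <- colMeans(rows)
  }
  attr(out, "empty_parcels") <- which(rowSums(is.na(out)) > 0L)
  out
}

# binarize a symmetric matrix keeping the top `frac` of upper-triangle
# off-diagonal entries (ties broken by pair index); NA pairs are excluded
# from the pool
binarize_top_connections <- function(r, frac) {
  n <- nrow(r)
  ut <- which(upper.tri(r))
  vals <- r[ut]
  pool <- ut[!is.na(vals)]
  m <- ceiling(frac * length(pool))
  keep <- pool[order(-r[pool], pool)][seq_len(m)]
  b <- matrix(0, n, n)
  b[keep] <- 1
  b + t(b)
}

#' Group binary parcel connectivity
#'
#' Per subject: Pearson correlation between parcel mean time courses,
#' binarized by setting the top 10\% of the (upper-triangle, off-diagonal)
#' correlations to one and the rest to zero, so each subject contributes
#' the same number of connections. The group matrix is the element-wise
#' mean of the subject binaries (values in [0, 1], zero diagonal).
#'
#' @param subject_ts list of scan time series (one per subject), or list
#'   of precomputed parcels x T matrices.
#' @param parc a \code{parcellation}.
#' @param frac fraction of connections kept per subject (default 0.10).
#' @return parcels x parcels group matrix of class
#'   \code{parcel_connectivity} with attribute \code{n_subjects}.
#' @export
group_binary_connectivity <- function(subject_ts, parc, frac = 0.10) {
  if (length(subject_ts) == 0L) stop("need at least one subject")
  mats <- lapply(subject_ts, function(ts) {
    ptc <- if (is.matrix(ts) && nrow(ts) == nrow(parc$parcel_table)) ts
           else parcel_mean_timecourses(ts, parc)
    r <- suppressWarnings(cor(t(ptc)))
    diag(r) <- NA
    binarize_top_connections(r, frac)
  })
  g <- Reduce(`+`, mats) / length(mats)
  diag(g) <- 0
  structure(g, class = c("parcel_connectivity", class(g)),
            n_subjects = length(mats))
}

# spherical k-means on L2-normalized rows by cosine similarity
skmeans_once <- function(x, k, max_iter = 100L) {
  n <- nrow(x)
  centers <- x[sample(n, k), , drop = FALSE]
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    sims <- x %*% t(centers)
    new_labels <- max.col(sims, ties.method = "first")
    # re-seed each empty cluster with the currently worst-fit point, one
    # point at a time so clusters cannot steal each other's reseed
    fit <- sims[cbind(seq_len(n), new_labels)]
    for (c in which(tabulate(new_labels, nbins = k) == 0L)) {
      movable <- which(tabulate(new_labels, nbins = k)[new_labels] > 1L)
      if (length(movable) == 0L) break
      worst <- movable[which.min(fit[movable])]
      new_labels[worst] <- c
      fit[worst] <- Inf
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (c in seq_len(k)) {
      members <- which(labels == c)
      if (length(members) == 0L) next
      m <- colMeans(x[members, , drop = FALSE])
      nm <- sqrt(sum(m^2))
      if (nm > 0) centers[c, ] <- m / nm
    }
  }
  obj <- sum(rowSums(x * centers[labels, , drop = FALSE]))
  list(labels = labels, objective = obj)
}

#' Cluster parcels by connectivity profile
#'
#' Spherical k-means: parcel connectivity profiles (rows of the group
#' matrix) are L2-normalized and clustered by cosine similarity, with
#' random restarts keeping the best objective. Deterministic under a fixed
#' seed.
#'
#' @param group_matrix parcels x parcels group connectivity matrix.
#' @param k cluster count (1 <= k <= parcels).
#' @param nstart random restarts (default 50).
#' @param seed RNG seed.
#' @return object of class \code{network_clustering}: \code{labels}
#'   (parcel -> network id), \code{k}, \code{objective}, \code{seed}.
#' @export
cluster_parcels <- function(group_matrix, k, nstart = 50, seed = 1L) {
  x <- as.matrix(group_matrix)
  n <- nrow(x)
  if (k > n) stop("'k' exceeds the parcel count")
  if (k < 1L) stop("'k' must be >= 1")
  nrm <- sqrt(rowSums(x^2))
  x <- x / ifelse(nrm > 0, nrm, 1)
  if (k == 1L)
    return(structure(list(labels = rep(1L, n), k = 1L, objective = NA_real_,
                          seed = seed), class = "network_clustering"))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nstart)) {
    fit <- skmeans_once(x, k)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  structure(list(labels = as.integer(best$labels), k = as.integer(k),
                 objective = best$objective, seed = seed),
            class = "network_clustering")
}

#' @export
print.network_clustering <- function(x, ...) {
  cat("network_clustering: k = ", x$k, ", sizes: ",
      paste(tabulate(x$labels, nbins = x$k), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Amari-type similarity between two clusterings
#'
#' From the k x k confusion matrix Q of shared parcel counts, the Amari
#' index averages the row-wise and column-wise mismatch
#' \code{(1 - max/sum)}, normalized by \code{k/(k-1)} so it spans [0, 1];
#' the similarity is one minus the index. It is invariant to label
#' permutation and equals 1 exactly for identical partitions.
#'
#' @param c1,c2 \code{network_clustering} objects (or label vectors) over
#'   the same parcel set with the same k.
#' @return similarity in [0, 1].
#' @export
amari_similarity <- function(c1, c2) {
  l1 <- if (inherits(c1, "network_clustering")) c1$labels else as.integer(c1)
  l2 <- if (inherits(c2, "network_clustering")) c2$labels else as.integer(c2)
  if (length(l1) != length(l2)) stop("clusterings cover different parcel sets")
  k <- max(l1, l2)
  if (k == 1L) return(1)
  q <- table(factor(l1, levels = seq_len(k)), factor(l2, levels = seq_len(k)))
  q <- matrix(as.numeric(q), k, k)
  row_sums <- rowSums(q)
  col_sums <- colSums(q)
  rterm <- ifelse(row_sums > 0, 1 - apply(q, 1L, max) / row_sums, 0)
  cterm <- ifelse(col_sums > 0, 1 - apply(q, 2L, max) / col_sums, 0)
  index <- (k / (k - 1)) * (sum(rterm) + sum(cterm)) / (2 * k)
  1 - min(max(index, 0), 1)
}

#' Split-half stability curve over cluster counts
#'
#' For each repetition, subjects are split into two folds, each fold's
#' group binary connectivity is clustered at every k, and the two
#' clusterings are compared with \code{\link{amari_similarity}}; the
#' per-k mean over repetitions is the stability curve.
#'
#' @param subject_ts list of per-subject time series (or parcels x T
#'   matrices).
#' @param parc a \code{parcellation}.
#' @param k_range candidate cluster counts (default 2:30).
#' @param n_rep repetitions (default 200).
#' @param nstart k-means restarts per clustering.
#' @param frac per-subject connection fraction for binarization.
#' @param seed RNG seed.
#' @return object of class \code{stability_curve}: data.frame with
#'   \code{k} and \code{stability}, plus \code{n_rep} and \code{seed}.
#' @export
stability_curve <- function(subject_ts, parc, k_range = 2:30, n_rep = 200,
                            nstart = 10, frac = 0.10, seed = 1L) {
  s <- length(subject_ts)
  if (s < 4L) stop("need at least 4 subjects for split-half stability")
  ptcs <- lapply(subject_ts, function(ts)
    if (is.matrix(ts) && nrow(ts) == nrow(parc$parcel_table)) ts
    else parcel_mean_timecourses(ts, parc))
  set.seed(seed)
  sims <- matrix(NA_real_, n_rep, length(k_range))
  for (rep_i in seq_len(n_rep)) {
    half <- sample(s, floor(s / 2))
    g1 <- group_binary_connectivity(ptcs[half], parc, frac)
    g2 <- group_binary_connectivity(ptcs[setdiff(seq_len(s), half)], parc,
                                    frac)
    for (j in seq_along(k_range)) {
      k <- k_range[j]
      c1 <- cluster_parcels(g1, k, nstart = nstart,
                            seed = derive_seed(seed, rep_i * 1000L + 2L * j))
      c2 <- cluster_parcels(g2, k, nstart = nstart,
                            seed = derive_seed(seed, rep_i * 1000L + 2L * j + 1L))
      sims[rep_i, j] <- amari_similarity(c1, c2)
    }
  }
  structure(list(curve = data.frame(k = k_range,
                                    stability = colMeans(sims)),
                 n_rep = n_rep, k_range = range(k_range), seed = seed),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  best <- x$curve$k[which.max(x$curve$stability)]
  cat("stability_curve over k in [", x$k_range[1L], ", ", x$k_range[2L],
      "], ", x$n_rep, " split-half repetitions\n  peak stability ",
      round(max(x$curve$stability), 4), " at k = ", best, "\n", sep = "")
  invisible(x)
}

# greedy maximum-overlap alignment of labels `from` onto reference labels
align_labels_greedy <- function(from, ref, k) {
  q <- table(factor(from, levels = seq_len(k)),
             factor(ref, levels = seq_len(k)))
  q <- matrix(as.numeric(q), k, k)
  perm <- integer(k)
  used <- logical(k)
  for (step in seq_len(k)) {
    best <- which(q == max(q), arr.ind = TRUE)[1L, ]
    perm[best[1L]] <- best[2L]
    q[best[1L], ] <- -1
    q[, best[2L]] <- -1
    used[best[2L]] <- TRUE
  }
  perm[from]
}

#' Bootstrap assignment reproducibility per parcel
#'
#' Subjects are resampled with replacement, the group matrix re-clustered
#' at fixed k, labels aligned to the full-sample reference clustering by
#' greedy maximum overlap, and each parcel's frequency of keeping its
#' reference assignment is reported.
#'
#' @param subject_ts list of per-subject time series or parcel matrices.
#' @param parc a \code{parcellation}.
#' @param k network count.
#' @param n_boot bootstrap repetitions (default 100).
#' @param nstart clustering restarts.
#' @param frac per-subject connection fraction for binarization.
#' @param seed RNG seed.
#' @return per-parcel frequency in [0, 1], with the reference clustering
#'   as attribute \code{reference}.
#' @export
assignment_reproducibility <- function(subject_ts, parc, k, n_boot = 100,
                                       nstart = 10, frac = 0.10, seed = 1L) {
  ptcs <- lapply(subject_ts, function(ts)
    if (is.matrix(ts) && nrow(ts) == nrow(parc$parcel_table)) ts
    else parcel_mean_timecourses(ts, parc))
  g_full <- group_binary_connectivity(ptcs, parc, frac)
  ref <- cluster_parcels(g_full, k, nstart = nstart,
                         seed = derive_seed(seed, 0L))
  set.seed(seed)
  hits <- numeric(nrow(parc$parcel_table))
  for (b in seq_len(n_boot)) {
    take <- sample(length(ptcs), replace = TRUE)
    g <- group_binary_connectivity(ptcs[take], parc, frac)
    cl <- cluster_parcels(g, k, nstart = nstart, seed = derive_seed(seed, b))
    aligned <- align_labels_greedy(cl$labels, ref$labels, k)
    hits <- hits + (aligned == ref$labels)
  }
  out <- hits / n_boot
  attr(out, "reference") <- ref
  out
}
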