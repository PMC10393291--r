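# Parcel-wise developmental metrics: node local efficiency with a
# retained-connection threshold sweep (50% down to 5% in 1% steps) and
# trapezoidal AUC, and age sliding windows (90-day width at 2 months,
# widening by 4 days per month) over which per-scan metrics are averaged
# into trajectories.

#' Node local efficiency at one threshold
#'
#' The connectivity matrix is binarized by keeping the top
#' \code{threshold_frac} of (upper-triangle, off-diagonal) connections;
#' the subgraph G_i contains the neighbors of \code{node}, and the local
#' efficiency is the mean inverse shortest path length over ordered
#' neighbor pairs within G_i:
#' \code{E_local = 1/(N (N-1)) * sum_{j != k in G_i} 1 / L_{j,k}},
#' with unreachable pairs contributing 0. Nodes with fewer than 2
#' neighbors score 0 by convention.
#'
#' @param conn symmetric parcels x parcels connectivity matrix.
#' @param node node (parcel) index.
#' @param threshold_frac fraction of connections retained, in (0, 1].
#' @return local efficiency in [0, 1].
#' @export
node_local_efficiency <- function(conn, node, threshold_frac) {
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("'threshold_frac' must be in (0, 1]")
  conn <- as.matrix(conn)
  adj <- binarize_top_connections(local({ d <- conn; diag(d) <- NA; d }),
                                  threshold_frac)
  nbrs <- which(adj[node, ] == 1)
  n <- length(nbrs)
  if (n < 2L) return(0)
  sub <- adj[nbrs, nbrs, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency AUC over the threshold sweep
#'
#' Evaluates \code{\link{node_local_efficiency}} over a grid of retained
#' connection fractions (default 50\% down to 5\% in 1\% steps, 46 points)
#' and returns the trapezoidal integral normalized by the grid span, so
#' the result is a density in [0, 1] independent of connection density.
#'
#' @param conn symmetric connectivity matrix.
#' @param node node index.
#' @param fracs decreasing threshold grid (default
#'   \code{seq(0.50, 0.05, by = -0.01)}).
#' @return AUC in [0, 1] with attribute \code{per_threshold}.
#' @export
auc_local_efficiency <- function(conn, node,
                                 fracs = seq(0.50, 0.05, by = -0.01)) {
  if (length(fracs) == 0L) stop("empty threshold grid")
  eff <- vapply(fracs, function(f) node_local_efficiency(conn, node, f),
                numeric(1))
  if (length(fracs) == 1L) return(eff)
  ord <- order(fracs)
  out <- trapz(fracs[ord], eff[ord]) / (max(fracs) - min(fracs))
  attr(out, "per_threshold") <- data.frame(frac = fracs, efficiency = eff)
  out
}

#' Age sliding windows
#'
#' Windows centered at whole months (default 2 to 24); the width at 2
#' months is 90 days and grows by 4 days per month:
#' \code{width(m) = 90 + 4 (m - 2)} days. A scan belongs to every window
#' whose closed interval contains its age; month centers are converted to
#' days with the mean month length 30.4375 days.
#'
#' @param scan_ages_days nonnegative scan ages in days.
#' @param centers_months window centers in months.
#' @return list of windows, each with \code{center_months},
#'   \code{center_days}, \code{width_days} and \code{scan_idx}.
#' @export
sliding_windows <- function(scan_ages_days, centers_months = 2:24) {
  stopifnot(all(scan_ages_days >= 0))
  lapply(centers_months, function(m) {
    width <- 90 + 4 * (m - 2)
    center <- m * 30.4375
    inside <- which(scan_ages_days >= center - width / 2 &
                      scan_ages_days <= center + width / 2)
    list(center_months = m, center_days = center, width_days = width,
         scan_idx = inside)
  })
}

#' Metric trajectory over age windows
#'
#' Averages a per-scan parcel metric over the scans of each age window
#' (unweighted mean; scans in overlapping windows contribute to each).
#' Empty windows are \code{NA} columns.
#'
#' @param per_scan_values parcels x scans matrix of a per-scan metric
#'   (e.g. from \code{\link{scan_parcel_homogeneity}} or
#'   \code{\link{scan_parcel_efficiency}}).
#' @param windows output of \code{\link{sliding_windows}} for the same
#'   scans.
#' @return parcels x windows matrix, columns named by center month.
#' @export
metric_trajectory <- function(per_scan_values, windows) {
  out <- vapply(windows, function(w) {
    if (length(w$scan_idx) == 0L)
      return(rep(NA_real_, nrow(per_scan_values)))
    rowMeans(per_scan_values[, w$scan_idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(per_scan_values)))
  out <- matrix(out, nrow = nrow(per_scan_values))
  colnames(out) <- vapply(windows, function(w) paste0(w$center_months, "M"),
                          character(1))
  out
}

#' Per-scan parcel homogeneity
#'
#' Homogeneity of every parcel for one scan, using the scan's own
#' vertex-wise connectivity profiles (first-order RSFC rows) as the
#' profile matrix.
#'
#' @param ts scan time series.
#' @param parc a \code{parcellation}.
#' @return per-parcel homogeneity (percent).
#' @export
scan_parcel_homogeneity <- function(ts, parc) {
  r <- compute_rsfc(ts)
  parcel_homogeneity(parc, r)
}

#' Per-scan parcel local efficiency (AUC)
#'
#' Parcel connectivity of one scan (Pearson between parcel mean time
#' courses), then the local-efficiency AUC of every parcel over the
#' standard threshold sweep.
#'
#' @param ts scan time series.
#' @param parc a \code{parcellation}.
#' @param fracs threshold grid (default 50\%..5\% step 1\%).
#' @return per-parcel AUC vector.
#' @export
scan_parcel_efficiency <- function(ts, parc,
                                   fracs = seq(0.50, 0.05, by = -0.01)) {
  ptc <- parcel_mean_timecourses(ts, parc)
  r <- suppressWarnings(cor(t(ptc)))
  vapply(seq_len(nrow(r)), function(p)
    as.numeric(auc_local_efficiency(r, p, fracs)), numeric(1))
}
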