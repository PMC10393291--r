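# First- and second-order resting-state functional connectivity. The
# workflow per scan: (1) vertex-wise Pearson RSFC of each hemisphere vertex
# against the whole cortex, (2) Fisher r-to-z normalization, (3) row-wise
# correlation of z-profiles within a hemisphere (RSFC-2nd, which changes
# abruptly at areal borders), (4) averaging of all RSFC-2nd matrices of the
# same visit so every subject contributes equally.

#' BOLD time series of one scan
#'
#' @param data numeric vertices x timepoints matrix; undefined vertices
#'   (medial wall) carry \code{NA} rows.
#' @param tr_seconds repetition time in seconds (the acquisition this
#'   workflow targets uses 0.8 s and 420 volumes).
#' @param phase_encoding `"AP"` or `"PA"`.
#' @param subject_id,session_id,visit_id identifiers.
#' @param age_days age at scan in days.
#' @param hemisphere hemisphere label.
#' @return an object of class \code{scan_timeseries}.
#' @export
scan_timeseries <- function(data, tr_seconds = 0.8, phase_encoding = "AP",
                            subject_id = "sub01", session_id = "ses01",
                            visit_id = "vis01", age_days = 0L,
                            hemisphere = "L") {
  data <- as.matrix(data)
  if (ncol(data) < 2L) stop("a scan needs at least 2 timepoints")
  structure(list(data = data, tr_seconds = tr_seconds,
                 phase_encoding = match.arg(phase_encoding, c("AP", "PA")),
                 subject_id = subject_id, session_id = session_id,
                 visit_id = visit_id, age_days = as.integer(age_days),
                 hemisphere = hemisphere),
            class = "scan_timeseries")
}

#' @export
print.scan_timeseries <- function(x, ...) {
  cat("scan_timeseries: ", nrow(x$data), " vertices x ", ncol(x$data),
      " timepoints (TR ", x$tr_seconds, " s, ", x$phase_encoding, ")\n",
      "  subject ", x$subject_id, ", session ", x$session_id,
      ", visit ", x$visit_id, ", age ", x$age_days, " days\n", sep = "")
  invisible(x)
}

ts_matrix <- function(x) {
  if (inherits(x, "scan_timeseries")) x$data else as.matrix(x)
}

#' First-order RSFC matrix
#'
#' Pearson correlation of every hemisphere vertex time course with every
#' cortex vertex time course; row i is the RSFC map of hemisphere vertex i.
#' Vertices with zero-variance time courses outside the medial wall are
#' flagged (attribute \code{invalid_vertices}) and propagate as \code{NA}
#' rows, never as silent zeros.
#'
#' @param ts_hemi hemisphere time series (\code{scan_timeseries} or
#'   vertices x timepoints matrix).
#' @param ts_cortex cortex time series sharing the timepoint count;
#'   defaults to \code{ts_hemi} (single-hemisphere analysis).
#' @return numeric V x W correlation matrix with attribute
#'   \code{invalid_vertices} (row indices with undefined correlations).
#' @export
compute_rsfc <- function(ts_hemi, ts_cortex = ts_hemi) {
  a <- ts_matrix(ts_hemi)
  b <- ts_matrix(ts_cortex)
  if (ncol(a) != ncol(b))
    stop("time series must share the timepoint count")
  sda <- apply(a, 1L, sd)
  sdb <- apply(b, 1L, sd)
  bad_a <- is.na(sda) | sda == 0
  bad_b <- is.na(sdb) | sdb == 0
  r <- matrix(NA_real_, nrow(a), nrow(b))
  if (any(!bad_a) && any(!bad_b))
    r[!bad_a, !bad_b] <- cor(t(a[!bad_a, , drop = FALSE]),
                             t(b[!bad_b, , drop = FALSE]))
  r[r > 1] <- 1
  r[r < -1] <- -1
  attr(r, "invalid_vertices") <- which(bad_a)
  r
}

#' Fisher r-to-z transform
#'
#' \code{z = arctanh(r)}, with correlations at |r| = 1 clipped to
#' 1 - 1e-7 first so z stays finite while preserving ordering.
#'
#' @param r correlation matrix or vector with entries in [-1, 1] (NAs
#'   pass through).
#' @return z-transformed values with the same shape and attributes.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    stop("correlations outside [-1, 1]")
  clip <- 1 - 1e-7
  out <- atanh(pmin(pmax(r, -clip), clip))
  attributes(out) <- attributes(r)
  out
}

#' Second-order connectivity (RSFC-2nd)
#'
#' Correlates the z-transformed RSFC profile (row) of each vertex with
#' every other vertex of the same hemisphere: entry (i, j) is the Pearson
#' correlation of rows i and j. The result is symmetric with unit diagonal;
#' undefined rows propagate as \code{NA} rows and columns. Computation is
#' row-blocked so large hemispheres stream through memory.
#'
#' @param z_matrix V x W matrix of z-profiles (rows = hemisphere vertices).
#' @param block_size rows per block of the streaming crossproduct.
#' @return V x V second-order connectivity matrix with attribute
#'   \code{invalid_vertices}.
#' @export
compute_second_order <- function(z_matrix, block_size = 4096L) {
  z <- as.matrix(z_matrix)
  v <- nrow(z)
  # undefined target vertices (e.g. the medial wall) leave NA columns in
  # every profile; correlations are taken over the jointly defined columns
  row_all_na <- rowSums(!is.na(z)) == 0L
  col_ok <- colSums(is.na(z[!row_all_na, , drop = FALSE])) == 0L
  z <- z[, col_ok, drop = FALSE]
  mu <- rowMeans(z)
  zc <- z - mu
  ss <- sqrt(rowSums(zc^2))
  bad <- is.na(ss) | ss == 0
  zc[!bad, ] <- zc[!bad, , drop = FALSE] / ss[!bad]
  out <- matrix(NA_real_, v, v)
  good <- which(!bad)
  for (start in seq(1L, length(good), by = block_size)) {
    rows <- good[start:min(start + block_size - 1L, length(good))]
    out[rows, good] <- zc[rows, , drop = FALSE] %*% t(zc[good, , drop = FALSE])
  }
  out[out > 1] <- 1
  out[out < -1] <- -1
  diag(out)[!bad] <- 1
  attr(out, "invalid_vertices") <- which(bad)
  attr(out, "hemisphere") <- attr(z_matrix, "hemisphere") %||% "L"
  out
}

#' Average second-order matrices of one visit
#'
#' Element-wise mean of the RSFC-2nd matrices of all scans of the same
#' visit, so subjects with different scan counts still contribute equally
#' at the visit level.
#'
#' @param matrices nonempty list of V x V second-order matrices sharing
#'   hemisphere and vertex count.
#' @param provenance optional character vector of contributing scan ids.
#' @return averaged matrix with attribute \code{provenance}.
#' @export
average_visit_rsfc2 <- function(matrices, provenance = NULL) {
  if (length(matrices) == 0L) stop("empty matrix list")
  dims <- vapply(matrices, function(m) dim(m)[1L], integer(1))
  if (length(unique(dims)) != 1L)
    stop("matrices must share the vertex count")
  hemis <- vapply(matrices, function(m) attr(m, "hemisphere") %||% "L",
                  character(1))
  if (length(unique(hemis)) != 1L)
    stop("cannot average matrices from different hemispheres")
  out <- Reduce(`+`, matrices) / length(matrices)
  attr(out, "hemisphere") <- hemis[[1L]]
  attr(out, "provenance") <- provenance %||%
    paste0("matrix", seq_along(matrices))
  out
}
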