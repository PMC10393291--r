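`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index between two label vectors (NAs dropped pairwise);
# cross-checked against mclust::adjustedRandIndex in the test suite
#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions corrected for chance; 1 for identical
#' partitions (up to relabeling), about 0 for independent ones. Entries that
#' are \code{NA} in either labeling (e.g. borders, medial wall) are dropped.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) stop("no jointly labeled elements")
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# derive a stream-specific seed (< 2^31) from a base seed
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}
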