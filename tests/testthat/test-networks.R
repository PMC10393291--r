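test_that("parcel mean time courses are unweighted vertex means", {
  mesh <- test_icosphere(1, medial_wall_frac = 0.1)
  labels <- rep(0L, 42)
  labels[1:4] <- 1L
  labels[5:6] <- 2L
  parc <- gradparc:::new_parcellation(labels, mesh, logical(42))
  x <- matrix(NA_real_, 42, 5)
  x[1:4, ] <- matrix(rep(c(1, 2, 3, 4, 5), each = 4), 4, 5)
  x[5, ] <- 1:5
  x[6, ] <- 3:7
  ptc <- parcel_mean_timecourses(x, parc)
  expect_equal(nrow(ptc), 2L)
  expect_equal(ptc[1, ], c(1, 2, 3, 4, 5))      # identical vertices
  expect_equal(ptc[2, ], (1:5 + 3:7) / 2)       # hand mean of two
  # a parcel made entirely of undefined rows is flagged
  labels2 <- labels
  labels2[which(mesh$medial_wall)[1]] <- 3L
  parc2 <- gradparc:::new_parcellation(labels2, mesh, logical(42))
  x2 <- x
  x2[mesh$medial_wall, ] <- NA
  ptc2 <- parcel_mean_timecourses(x2, parc2)
  expect_true(3L %in% attr(ptc2, "empty_parcels"))
})

test_that("subject binarization keeps the ceiling of 10% of pairs", {
  set.seed(36)
  ptc <- matrix(rnorm(10 * 50), 10, 50)
  g <- group_binary_connectivity(list(ptc), parc = fake_parc(10))
  expect_equal(sum(g[upper.tri(g)]), ceiling(0.10 * choose(10, 2)))  # 5
  expect_equal(diag(unclass(g)), rep(0, 10))
  expect_equal(unclass(g), t(unclass(g)), ignore_attr = TRUE)
})

test_that("group matrices average subject binaries and ignore subject order", {
  set.seed(37)
  ptcs <- replicate(4, matrix(rnorm(8 * 40), 8, 40), simplify = FALSE)
  g <- group_binary_connectivity(ptcs, fake_parc(8))
  g_perm <- group_binary_connectivity(ptcs[c(3, 1, 4, 2)], fake_parc(8))
  expect_equal(unclass(g), unclass(g_perm), ignore_attr = TRUE)
  expect_true(all(g >= 0 & g <= 1))
  # identical subjects give a binary group matrix
  same <- replicate(3, ptcs[[1]], simplify = FALSE)
  gs <- group_binary_connectivity(same, fake_parc(8))
  expect_true(all(gs %in% c(0, 1)))
  expect_error(group_binary_connectivity(list(), fake_parc(8)), "subject")
})

test_that("spherical k-means recovers planted connectivity blocks", {
  set.seed(38)
  n <- 16
  truth <- rep(1:2, each = 8)
  g <- outer(truth, truth, `==`) * 0.8 + matrix(runif(n * n, 0, 0.05), n, n)
  g <- (g + t(g)) / 2
  diag(g) <- 0
  cl <- cluster_parcels(g, 2, nstart = 10, seed = 1)
  expect_equal(cl$k, 2L)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  one <- cluster_parcels(g, 1, seed = 1)
  expect_true(all(one$labels == 1L))
  expect_error(cluster_parcels(g, 20), "exceeds")
  # best-of-restarts never loses to a single start
  c1 <- cluster_parcels(g, 4, nstart = 1, seed = 7)
  c50 <- cluster_parcels(g, 4, nstart = 25, seed = 7)
  expect_gte(c50$objective, c1$objective - 1e-12)
  # determinism under a fixed seed
  expect_identical(cluster_parcels(g, 3, nstart = 5, seed = 11)$labels,
                   cluster_parcels(g, 3, nstart = 5, seed = 11)$labels)
})

test_that("Amari similarity is permutation-invariant and matches hand values", {
  c1 <- c(1L, 1L, 2L, 2L)
  expect_equal(amari_similarity(c1, c1), 1)
  expect_equal(amari_similarity(c1, c(2L, 2L, 1L, 1L)), 1)
  # one parcel reassigned: Q = [[2,0],[1,1]] over k=2
  c2 <- c(1L, 1L, 2L, 1L)
  q_rows <- (1 - 2 / 2) + (1 - 1 / 2)
  q_cols <- (1 - 2 / 3) + (1 - 1 / 1)
  want <- 1 - (2 / 1) * (q_rows + q_cols) / 4
  expect_equal(amari_similarity(c1, c2), want)
  expect_equal(amari_similarity(c2, c1), amari_similarity(c1, c2))
  expect_error(amari_similarity(c1, c1[1:3]), "different parcel sets")
})

test_that("mclust agrees with the package adjusted Rand index", {
  skip_if_not_installed("mclust")
  set.seed(39)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("split-half stability peaks at the planted network count", {
  set.seed(40)
  n <- 20
  truth <- rep(1:4, each = 5)
  ptcs <- lapply(1:8, function(s) {
    latent <- matrix(rnorm(4 * 60), 4, 60)
    latent[truth, ] + matrix(rnorm(n * 60, sd = 0.35), n, 60)
  })
  sc <- stability_curve(ptcs, fake_parc(n), k_range = 2:6, n_rep = 10,
                        nstart = 5, seed = 2)
  expect_true(all(sc$curve$stability >= 0 & sc$curve$stability <= 1))
  expect_equal(sc$curve$k[which.max(sc$curve$stability)], 4L)
  expect_error(stability_curve(ptcs[1:3], fake_parc(n)), "4 subjects")
  # protocol defaults
  expect_equal(eval(formals(stability_curve)$k_range), 2:30)
  expect_equal(formals(stability_curve)$n_rep, 200)
})

test_that("bootstrap assignment reproducibility is 1 for identical subjects", {
  set.seed(41)
  truth <- rep(1:3, each = 5)
  latent <- matrix(rnorm(3 * 50), 3, 50)
  ptc <- latent[truth, ] + matrix(rnorm(15 * 50, sd = 0.2), 15, 50)
  ptcs <- replicate(6, ptc, simplify = FALSE)
  freq <- assignment_reproducibility(ptcs, fake_parc(15), k = 3,
                                     n_boot = 12, nstart = 5, frac = 0.3,
                                     seed = 3)
  expect_equal(as.numeric(freq), rep(1, 15))
  expect_true(all(freq >= 0 & freq <= 1))
})
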