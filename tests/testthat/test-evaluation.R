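test_that("top-fraction binarization keeps exactly ceil(frac * N) vertices", {
  v <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  b <- binarize_top(v, 0.25)
  expect_equal(sum(b), 3)            # ceil(2.5)
  expect_equal(which(b == 1), 1:3)
  expect_equal(sum(binarize_top(v, 1)), 10)
  expect_identical(binarize_top(v, 0.25), binarize_top(v, 0.25))
  # ties at the cutoff resolved by lower vertex index
  tied <- c(5, 3, 3, 3, 1)
  expect_equal(which(binarize_top(tied, 0.4) == 1), c(1L, 2L))
  # undefined vertices are excluded from the count
  vna <- c(NA, 4, 3, 2, 1)
  expect_equal(sum(binarize_top(vna, 0.5), na.rm = TRUE), 2)
  expect_error(binarize_top(v, 0), "frac")
  expect_error(binarize_top(v, 1.2), "frac")
})

test_that("dice follows 2|A&B| / (|A|+|B|) with the empty convention", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0)
  expect_equal(dice(a, b), 0.6)      # 2*3 / (4+6)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  expect_equal(dice(b, a), dice(a, b))
  expect_equal(dice(rep(0, 5), rep(0, 5)), 1)
  expect_error(dice(a, b[1:5]), "length")
})

test_that("split-half reproducibility is 1 for identical subjects and ~frac for noise", {
  same <- matrix(rep(runif(80), 6), 80, 6)
  r <- split_half_reproducibility(same, n_rep = 25, frac = 0.25, seed = 2)
  expect_equal(r$mean, 1)
  expect_equal(r$sd, 0)
  set.seed(29)
  noise <- matrix(rnorm(400 * 8), 400, 8)
  rn <- split_half_reproducibility(noise, n_rep = 200, frac = 0.25, seed = 3)
  # independent rank tops overlap at the binarization fraction
  expect_lt(abs(rn$mean - 0.25), 0.05)
  expect_error(split_half_reproducibility(noise[, 1, drop = FALSE]),
               "2 subjects")
  expect_equal(formals(split_half_reproducibility)$n_rep, 1000)
  expect_equal(formals(split_half_reproducibility)$frac, 0.25)
})

test_that("parcel homogeneity matches the eigen-decomposition oracle", {
  mesh <- test_icosphere(1)
  labels <- rep(0L, 42)
  labels[1:3] <- 1L
  labels[4:10] <- 2L
  parc <- gradparc:::new_parcellation(labels, mesh, logical(42))
  set.seed(30)
  profiles <- matrix(rnorm(42 * 4), 42, 4)
  h <- parcel_homogeneity(parc, profiles)
  for (p in 1:2) {
    x <- profiles[labels == p, , drop = FALSE]
    lam <- svd(x)$d^2
    expect_equal(h[p], 100 * lam[1] / sum(lam))
  }
  # identical profiles are rank one
  profiles2 <- matrix(rep(rnorm(4), each = 42), 42, 4) * runif(42, 0.5, 2)
  expect_equal(parcel_homogeneity(parc, profiles2)[1], 100)
  # isotropic noise in d dimensions approaches the equal-eigenvalue limit
  # 100/d from above (the finite-sample excess shrinks like sqrt(d/n))
  mesh2 <- test_icosphere(2)
  big <- rep(1L, 162)
  bparc <- gradparc:::new_parcellation(big, mesh2, logical(162))
  set.seed(31)
  hn <- mean(replicate(40, {
    parcel_homogeneity(bparc, matrix(rnorm(162 * 5), 162, 5))[1]
  }))
  expect_gt(hn, 100 / 5)
  expect_lt(hn, 1.5 * 100 / 5)
  # single-vertex parcels are 100 and flagged
  one <- rep(0L, 42)
  one[1] <- 1L
  h1 <- parcel_homogeneity(gradparc:::new_parcellation(one, mesh, logical(42)),
                           profiles)
  expect_equal(as.numeric(h1), 100)
  expect_true(attr(h1, "flagged"))
})

test_that("parcel homogeneity and variance ignore vertex order within parcels", {
  mesh <- test_icosphere(1)
  labels <- c(rep(1L, 20), rep(2L, 22))
  parc <- gradparc:::new_parcellation(labels, mesh, logical(42))
  set.seed(32)
  profiles <- matrix(rnorm(42 * 6), 42, 6)
  perm <- c(sample(1:20), sample(21:42))
  profiles_perm <- profiles
  profiles_perm[perm, ] <- profiles
  # permuting vertices within a parcel leaves both metrics unchanged
  expect_equal(as.numeric(parcel_homogeneity(parc, profiles_perm)),
               as.numeric(parcel_homogeneity(parc, profiles)))
  expect_equal(parcel_variance(parc, profiles_perm)$per_parcel,
               parcel_variance(parc, profiles)$per_parcel)
})

test_that("parcel variance sums row standard deviations", {
  mesh <- test_icosphere(1)
  labels <- rep(0L, 42)
  labels[1:2] <- 1L
  parc <- gradparc:::new_parcellation(labels, mesh, logical(42))
  # 2 vertices x 2 profile dims: rows of the paper's matrix are the dims
  z <- matrix(0, 42, 2)
  z[1, ] <- c(1, 5)
  z[2, ] <- c(3, 9)
  pv <- parcel_variance(parc, z)
  expect_equal(as.numeric(pv$per_parcel), sd(c(1, 3)) + sd(c(5, 9)))
  expect_equal(pv$map_mean, as.numeric(pv$per_parcel))
  # shift invariance
  expect_equal(parcel_variance(parc, z + 7)$per_parcel, pv$per_parcel)
  # identical columns -> 0; single vertex -> 0 flagged
  z2 <- z
  z2[2, ] <- z2[1, ]
  expect_equal(as.numeric(parcel_variance(parc, z2)$per_parcel), 0)
  one <- rep(0L, 42)
  one[1] <- 1L
  v1 <- parcel_variance(gradparc:::new_parcellation(one, mesh, logical(42)), z)
  expect_equal(as.numeric(v1$per_parcel), 0)
  expect_true(attr(v1$per_parcel, "flagged"))
})

test_that("rotation nulls preserve parcel count and approximate sizes", {
  mesh <- test_icosphere(2, medial_wall_frac = 0.05)
  parc <- synth_parcellation(mesh, 8, seed = 4)
  ens <- generate_null_parcellations(parc, mesh, n = 20, seed = 9)
  expect_equal(ens$n, 20L)
  for (i in 1:20) {
    lab <- ens$labels[i, ]
    expect_lte(max(lab), 8L)
    sizes <- tabulate(lab[lab > 0L], nbins = 8)
    keep <- !ens$mw_flag[i, ]
    # sizes preserved within resampling distortion away from the wall
    expect_true(all(abs(sizes[keep] - parc$parcel_table$vertex_count[keep]) <=
                      0.35 * parc$parcel_table$vertex_count[keep] + 3))
  }
  # bit-identical regeneration under the same seed
  ens2 <- generate_null_parcellations(parc, mesh, n = 20, seed = 9)
  expect_identical(ens$labels, ens2$labels)
  expect_identical(ens$rotations, ens2$rotations)
  expect_equal(formals(generate_null_parcellations)$n, 1000)
  expect_error(generate_null_parcellations(parc, mesh, n = 0), ">= 1")
})

test_that("a zero rotation maps the parcellation onto itself", {
  mesh <- test_icosphere(2)
  parc <- synth_parcellation(mesh, 6, seed = 5)
  rot <- gradparc:::rotation_matrix_xyz(0, 0, 0)
  expect_equal(rot, diag(3))
  nn <- gradparc:::nearest_vertex(mesh, mesh$sphere %*% rot)
  expect_identical(parc$labels[nn], parc$labels)
})

test_that("rank-based null comparison follows the add-one formula", {
  nulls <- seq_len(999)
  expect_equal(null_comparison(1000, nulls, "greater"), 1 / 1000)
  expect_equal(null_comparison(0, nulls, "less"), 1 / 1000)
  p_mid <- null_comparison(500, nulls, "greater")
  expect_lt(abs(p_mid - 0.5), 0.01)
  expect_equal(null_comparison(1000, nulls, "less"), 1)
  expect_error(null_comparison(1, numeric(0)), "empty")
})

test_that("spherical Hausdorff distance matches the exhaustive oracle", {
  mesh <- test_icosphere(2)
  expect_equal(hausdorff_spherical(c(1, 5, 9), c(1, 5, 9), mesh), 0)
  d12 <- geodesic_sphere_distance(mesh$sphere[3, ], mesh$sphere[40, ])
  expect_equal(hausdorff_spherical(3, 40, mesh), d12)
  set.seed(33)
  for (i in 1:10) {
    a <- sample(162, 4)
    b <- sample(162, 5)
    dmat <- outer(a, b, Vectorize(function(x, y)
      geodesic_sphere_distance(mesh$sphere[x, ], mesh$sphere[y, ])))
    want <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
    expect_equal(hausdorff_spherical(a, b, mesh), want)
    expect_equal(hausdorff_spherical(b, a, mesh),
                 hausdorff_spherical(a, b, mesh))
  }
  expect_error(hausdorff_spherical(integer(0), 1, mesh), "nonempty")
})

test_that("patch variability is 0 for identical and 1 for anti-correlated maps", {
  mesh <- test_icosphere(2, medial_wall_frac = 0.05)
  set.seed(34)
  g1 <- scalar_map(runif(162), mesh)
  v_same <- variability_between(g1, g1, mesh, ring = 3)
  expect_equal(max(v_same, na.rm = TRUE), 0)
  v_anti <- variability_between(g1, 0.8 - g1, mesh, ring = 3)
  expect_equal(min(v_anti, na.rm = TRUE), 1)
  expect_equal(max(v_anti, na.rm = TRUE), 1)
  expect_true(all(is.na(v_same[mesh$medial_wall])))
})

test_that("patch variability matches a direct Pearson computation", {
  mesh <- test_icosphere(1)
  set.seed(35)
  g1 <- scalar_map(rnorm(42), mesh)
  g2 <- scalar_map(rnorm(42), mesh)
  v <- variability_between(g1, g2, mesh, ring = 1)
  for (vert in c(1L, 17L, 42L)) {
    patch <- k_ring_neighborhood(mesh, vert, 1L)
    expect_equal(v[[vert]], 0.5 * (1 - cor(g1[patch], g2[patch])))
  }
  # constant patches are undefined
  gc <- scalar_map(rep(1, 42), mesh)
  expect_true(all(is.na(variability_between(gc, g2, mesh, ring = 1))))
})
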