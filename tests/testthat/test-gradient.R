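test_that("the gradient of a constant map is zero and shift-invariant", {
  mesh <- test_icosphere(2)
  g <- spatial_gradient(scalar_map(rep(3, 162), mesh), mesh)
  expect_equal(max(abs(g), na.rm = TRUE), 0)
  set.seed(14)
  v <- rnorm(162)
  g1 <- spatial_gradient(scalar_map(v, mesh), mesh)
  g2 <- spatial_gradient(scalar_map(v + 17.3, mesh), mesh)
  expect_equal(as.numeric(g1), as.numeric(g2))
  expect_true(all(g1 >= 0, na.rm = TRUE))
})

test_that("the gradient of a linear field matches the analytic magnitude", {
  # f = z on the sphere has tangential gradient magnitude sqrt(1-(z/R)^2)
  mesh <- test_icosphere(3)
  g <- spatial_gradient(scalar_map(mesh$sphere[, 3], mesh), mesh)
  expected <- sqrt(pmax(0, 1 - (mesh$sphere[, 3] / mesh$radius)^2))
  ok <- !is.na(g) & expected > 0.3   # away from the poles
  expect_lt(max(abs(g[ok] - expected[ok]) / expected[ok]), 0.06)
})

test_that("degenerate triangles are reported by index", {
  # regular tetrahedron on the sphere, then collapse one vertex pair
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v <- v * (100 / sqrt(3))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  v2 <- v
  v2[4, ] <- v2[3, ]
  mesh <- cortical_mesh(v2, f)
  expect_error(spatial_gradient(scalar_map(c(1, 2, 3, 4), mesh), mesh),
               "degenerate")
})

test_that("the gradient matrix maps each connectivity row to a gradient map", {
  mesh <- test_icosphere(2, medial_wall_frac = 0.05)
  nv <- 162
  # constant rows -> zero gradients
  r2 <- matrix(1, nv, nv)
  gm <- gradient_matrix(r2, mesh)
  expect_equal(dim(gm), c(nv, nv))
  expect_equal(max(abs(gm), na.rm = TRUE), 0)
  # 2-block structure: largest gradients on the block border
  upper <- mesh$sphere[, 3] > 0
  block <- outer(upper, upper, `==`) * 1
  gmb <- gradient_matrix(block, mesh)
  row1 <- gmb[which(!mesh$medial_wall & !upper)[1], ]
  peak <- which.max(row1)
  border <- which(vapply(seq_len(nv), function(v) {
    nb <- k_ring_neighborhood(mesh, v, 1L)
    any(upper[nb]) && any(!upper[nb])
  }, logical(1)))
  expect_true(peak %in% border)
  # rows equal per-row spatial_gradient
  set.seed(15)
  vals <- rnorm(nv)
  r2r <- matrix(vals, nv, nv, byrow = TRUE)[1:3, , drop = FALSE]
  gm3 <- gradient_matrix(rbind(r2r, matrix(0, nv - 3, nv)), mesh)
  expect_equal(gm3[1, ], as.numeric(spatial_gradient(scalar_map(vals, mesh), mesh)))
})

test_that("watershed agrees with the brute-force priority-flood oracle", {
  set.seed(16)
  for (mesh in list(test_icosphere(1), test_icosphere(2, medial_wall_frac = 0.05))) {
    for (i in 1:25) {
      vals <- scalar_map(runif(n_vertices(mesh)), mesh)
      got <- gradparc:::watershed_flood(vals, mesh)
      want <- oracle_flood(vals, mesh)
      expect_identical(got$labels, want$labels)
      expect_identical(got$boundary, want$boundary)
    }
  }
})

test_that("a monotone bowl yields one basin and no boundary", {
  mesh <- test_icosphere(2)
  bowl <- geodesic_sphere_distance(mesh$sphere[7, ],
                                   mesh$sphere, mesh$radius)
  b <- watershed_boundary_map(scalar_map(bowl, mesh), mesh)
  expect_equal(sum(b, na.rm = TRUE), 0)
  fl <- gradparc:::watershed_flood(scalar_map(bowl, mesh), mesh)
  expect_equal(max(fl$labels), 1L)
})

test_that("a constant map yields one region per component with empty boundary", {
  mesh <- test_icosphere(1, medial_wall_frac = 0.1)
  fl <- gradparc:::watershed_flood(scalar_map(rep(1, 42), mesh), mesh)
  expect_equal(max(fl$labels), 1L)
  expect_false(any(fl$boundary))
  expect_true(all(fl$labels[!mesh$medial_wall] == 1L))
})

test_that("two basins are separated by a boundary on the ridge", {
  mesh <- test_icosphere(2)
  d1 <- geodesic_sphere_distance(mesh$sphere[1, ], mesh$sphere, mesh$radius)
  d2 <- geodesic_sphere_distance(-mesh$sphere[1, ], mesh$sphere, mesh$radius)
  two <- pmin(d1, d2)
  fl <- gradparc:::watershed_flood(scalar_map(two, mesh), mesh)
  expect_equal(max(fl$labels), 2L)
  expect_gt(sum(fl$boundary), 0)
  # boundary vertices sit on the ridge (equidistant band)
  expect_true(all(abs(d1 - d2)[fl$boundary] < 2 * mean_edge_length(mesh)))
  want <- oracle_flood(scalar_map(two, mesh), mesh)
  expect_identical(fl$labels, want$labels)
})

test_that("local gradient maps average binary boundary maps", {
  m1 <- c(0, 1, 0, 1)
  expect_equal(local_gradient_map(list(m1, m1, m1)), m1,
               ignore_attr = TRUE)
  m2 <- c(0, 1, 0, 0)
  avg <- local_gradient_map(list(m1, m2))
  expect_equal(as.numeric(avg), c(0, 1, 0, 0.5))
  expect_error(local_gradient_map(list()), "empty")
  expect_error(local_gradient_map(list(c(0, 2, 0, 0))), "binary")
  set.seed(17)
  maps <- replicate(6, sample(c(0, 1), 10, replace = TRUE), simplify = FALSE)
  a <- local_gradient_map(maps)
  b <- local_gradient_map(maps[sample(6)])
  expect_equal(as.numeric(a), as.numeric(b))   # permutation invariance
  expect_true(all(a >= 0 & a <= 1))
})

test_that("hierarchical map averaging weights each grouped unit equally", {
  meta <- data.frame(
    session_id = c("a1", "a1", "a2", "b1"),
    visit_id = c("A", "A", "A", "B"),
    age_group = c("3M", "3M", "3M", "6M"))
  maps <- cbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  sess <- combine_maps(maps, meta, to = "session")
  expect_equal(unname(sess$maps), cbind(c(0.5, 0.5), c(1, 1), c(0, 0)))
  vis <- combine_maps(maps, meta, to = "visit")
  # session means first: visit A = mean(c(.5,.5), c(1,1)) = (.75,.75),
  # different from the pooled scan mean (2/3, 2/3)
  expect_equal(unname(vis$maps), cbind(c(0.75, 0.75), c(0, 0)))
  ai <- combine_maps(maps, meta, to = "age_independent")
  expect_equal(unname(ai$maps), cbind(c(0.375, 0.375)))
  expect_error(combine_maps(maps, meta[, -1, drop = FALSE], to = "session"),
               "session_id")
  one <- combine_maps(maps[, 4, drop = FALSE], meta[4, ], to = "age_group")
  expect_equal(unname(one$maps), maps[, 4, drop = FALSE])
})

test_that("overlap consistency counts per-group top-fraction hits", {
  set.seed(18)
  base <- runif(40)
  six <- matrix(base, 40, 6)
  oc <- overlap_consistency(six, 0.5)
  expect_true(all(oc %in% c(0, 6)))
  expect_equal(sum(oc == 6), ceiling(0.5 * 40))
  # disjoint top halves -> only 0/1 values
  two <- cbind(c(rep(1, 20), rep(0, 20)), c(rep(0, 20), rep(1, 20)))
  oc2 <- overlap_consistency(two, 0.5)
  expect_true(all(oc2 %in% c(0, 1)))
  expect_error(overlap_consistency(list(), 0.5), "empty")
})
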