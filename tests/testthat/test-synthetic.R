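test_that("icospheres have 10 * 4^s + 2 consistently oriented faces", {
  expect_equal(n_vertices(icosphere(0)), 12L)
  expect_equal(n_vertices(test_icosphere(2)), 162L)
  expect_equal(n_vertices(test_icosphere(3)), 642L)
  mesh <- test_icosphere(2)
  tri <- mesh$triangles
  a <- mesh$sphere[tri[, 1], ]
  b <- mesh$sphere[tri[, 2], ]
  c3 <- mesh$sphere[tri[, 3], ]
  vol <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  expect_true(all(sign(vol) == sign(vol[1])))
  mw <- icosphere(2, medial_wall_frac = 0.05)
  expect_equal(sum(mw$medial_wall), round(0.05 * 162))
  expect_error(icosphere(-1), ">= 0")
})

test_that("synthetic parcellations partition defined vertices into connected parcels", {
  mesh <- test_icosphere(3, medial_wall_frac = 0.05)
  one <- synth_parcellation(mesh, 1, seed = 1)
  expect_true(all(one$labels[!mesh$medial_wall] == 1L))
  parc <- synth_parcellation(mesh, 20, seed = 1)
  expect_equal(nrow(parc$parcel_table), 20L)
  expect_true(all(parc$parcel_table$vertex_count > 0))
  expect_true(all(parc$labels[!mesh$medial_wall] > 0L))
  expect_true(all(parc$labels[mesh$medial_wall] == 0L))
  adj <- gradparc:::mesh_adjacency(mesh)
  for (p in sample(20, 5)) {
    verts <- which(parc$labels == p)
    seen <- verts[1]
    repeat {
      nxt <- intersect(unique(unlist(adj[seen])), verts)
      if (length(setdiff(nxt, seen)) == 0) break
      seen <- union(seen, nxt)
    }
    expect_setequal(seen, verts)
  }
  expect_identical(synth_parcellation(mesh, 20, seed = 1)$labels, parc$labels)
  expect_error(synth_parcellation(mesh, 10000, seed = 1), "exceeds")
})

test_that("the noiseless limit gives unit within-parcel correlation", {
  mesh <- test_icosphere(2, medial_wall_frac = 0.05)
  parc <- synth_parcellation(mesh, 6, seed = 2)
  nets <- synth_networks(6, 2, seed = 2)
  ts <- synth_timeseries(mesh, parc, nets, timepoints = 80, snr = 1e9,
                         coherence = 1, seed = 3)
  p1 <- which(parc$labels == 1L)[1:3]
  r <- cor(t(ts$data[p1, ]))
  expect_equal(r, matrix(1, 3, 3), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("cross-network vertex correlations stay within the null bound", {
  mesh <- test_icosphere(2, medial_wall_frac = 0.05)
  parc <- synth_parcellation(mesh, 6, seed = 2)
  nets <- synth_networks(6, 3, seed = 2)
  tt <- 400
  ts <- synth_timeseries(mesh, parc, nets, timepoints = tt, snr = 5,
                         network_weight = 1, coherence = 1, seed = 4)
  # with full network weight, parcels of different networks share no latent
  pn <- nets[parc$labels[!mesh$medial_wall]]
  v1 <- which(!mesh$medial_wall & nets[pmax(parc$labels, 1)] == 1 &
                parc$labels > 0)[1]
  v2 <- which(!mesh$medial_wall & nets[pmax(parc$labels, 1)] == 2 &
                parc$labels > 0)[1]
  r <- cor(ts$data[v1, ], ts$data[v2, ])
  expect_lt(abs(r), 3 / sqrt(tt) + 0.05)
})

test_that("second-order structure reflects the planted parcellation", {
  mesh <- test_icosphere(2, medial_wall_frac = 0.05)
  parc <- synth_parcellation(mesh, 6, seed = 5)
  nets <- synth_networks(6, 2, seed = 5)
  ts <- synth_timeseries(mesh, parc, nets, timepoints = 250, snr = 10,
                         seed = 6)
  r2 <- compute_second_order(fisher_z(compute_rsfc(ts)))
  def <- !is.na(r2)
  same_parcel <- outer(parc$labels, parc$labels, `==`)
  labeled <- outer(parc$labels > 0, parc$labels > 0, `&`)
  off_diag <- !diag(TRUE, 162)
  within <- mean(r2[same_parcel & labeled & def & off_diag])
  between <- mean(r2[!same_parcel & labeled & def])
  expect_gt(within, between)
})

test_that("cohorts are pure functions of the seed with full metadata", {
  spec <- synth_cohort_spec(subdivisions = 2, n_parcels = 8, n_networks = 2,
                            n_subjects = 6, timepoints = 40, seed = 7)
  co1 <- synth_cohort(spec)
  co2 <- synth_cohort(spec)
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$scans[[3]]$data, co2$scans[[3]]$data)
  expect_identical(co1$ground_truth$parcellation$labels,
                   co2$ground_truth$parcellation$labels)
  expect_equal(length(co1$scans), 6 * 2)        # AP + PA per subject
  expect_setequal(names(co1$metadata),
                  c("subject_id", "visit_id", "session_id", "phase_encoding",
                    "age_days", "age_group", "scan_id"))
  expect_equal(length(unique(co1$metadata$age_group)), 6L)
  expect_true(all(co1$metadata$phase_encoding %in% c("AP", "PA")))
})

test_that("misalignment warps are smooth, on-sphere and capped", {
  mesh <- test_icosphere(2)
  expect_identical(random_smooth_warp(mesh, 0, seed = 1), mesh$sphere)
  wp <- random_smooth_warp(mesh, 5, seed = 1)
  expect_equal(sqrt(rowSums(wp^2)), rep(100, 162), tolerance = 1e-9)
  ang <- acos(pmin(1, rowSums(wp * mesh$sphere) / 100^2)) * 180 / pi
  expect_lte(max(ang), 5 + 1e-6)
  expect_gt(max(ang), 4)      # the cap is attained up to rounding
  # smoothness: neighboring displacements are similar
  adj <- gradparc:::mesh_adjacency(mesh)
  d <- wp - mesh$sphere
  rough <- mean(vapply(seq_len(162), function(v)
    mean(sqrt(rowSums((d[adj[[v]], , drop = FALSE] -
                         matrix(d[v, ], length(adj[[v]]), 3, byrow = TRUE))^2))),
    numeric(1)))
  expect_lt(rough, mean(sqrt(rowSums(d^2))))
})

test_that("planted-structure recovery degrades as SNR falls", {
  mesh <- test_icosphere(2, medial_wall_frac = 0.05)
  parc <- synth_parcellation(mesh, 8, seed = 8)
  nets <- synth_networks(8, 2, seed = 8)
  sg <- scaled_smoothing_sigma(mesh)
  ari_at <- function(snr) {
    maps <- vapply(1:4, function(i) {
      ts <- synth_timeseries(mesh, parc, nets, timepoints = 150, snr = snr,
                             seed = 100 + i)
      as.numeric(scan_gradient_map(ts, mesh, smooth_sigma = sg))
    }, numeric(162))
    wp <- watershed_parcellate(scalar_map(rowMeans(maps), mesh), mesh)
    adjusted_rand_index(drop_zero(wp$labels), drop_zero(parc$labels))
  }
  ari <- vapply(c(10, 5, 2, 0.5), ari_at, numeric(1))
  expect_gt(ari[1], ari[4])                  # extremes clearly ordered
  expect_gt(cor(c(10, 5, 2, 0.5), ari, method = "spearman"), 0)
})
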