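# Synthetic spherical-cortex cohort generator. Every pipeline stage is
# validated on data from this module: an icosphere mesh with a polar-cap
# medial wall, a geodesic-Voronoi ground-truth parcellation, network-
# structured AR(1) parcel time courses with vertex noise at a controlled
# SNR, and smooth random spherical misalignments per subject. All
# generators are pure functions of (parameters, seed).

#' Subdivided icosahedron projected to a sphere
#'
#' @param subdivisions nonnegative subdivision count; the vertex count is
#'   \code{10 * 4^subdivisions + 2}.
#' @param radius sphere radius in mm (default 100).
#' @param medial_wall_frac fraction of vertices marked as a polar
#'   medial-wall cap (the vertices with the largest z), 0 for none.
#' @param hemisphere hemisphere label for the resulting mesh.
#' @return a \code{cortical_mesh}.
#' @export
icosphere <- function(subdivisions, radius = 100, medial_wall_frac = 0,
                      hemisphere = "L") {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L) stop("'subdivisions' must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_mid <- new.env(parent = emptyenv())
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- (v[a, ] + v[b, ]) / 2
      newv[[length(newv) + 1L]] <<- p
      m <- nv + length(newv)
      edge_mid[[key]] <- m
      m
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- v * (radius / sqrt(rowSums(v^2)))
  medial_wall <- rep(FALSE, nrow(v))
  if (medial_wall_frac > 0) {
    n_mw <- round(medial_wall_frac * nrow(v))
    if (n_mw > 0)
      medial_wall[order(v[, 3L], decreasing = TRUE)[seq_len(n_mw)]] <- TRUE
  }
  cortical_mesh(v, f, sphere = v, radius = radius,
                medial_wall = medial_wall, hemisphere = hemisphere)
}

#' Ground-truth parcellation from geodesic Voronoi regions
#'
#' Seeds are drawn uniformly among non-medial-wall vertices and every
#' defined vertex is assigned to the seed with the smallest graph-geodesic
#' distance (edge lengths = great-circle distances), which yields connected,
#' nonempty parcels partitioning the defined vertices.
#'
#' @param mesh a \code{cortical_mesh}.
#' @param n_parcels number of parcels; must not exceed the defined vertex
#'   count.
#' @param seed RNG seed (the generator is a pure function of it).
#' @param lloyd_iterations rounds of centroidal relaxation (seed moves to
#'   its parcel's geodesic medoid, then regions are recomputed). A few
#'   rounds even out parcel sizes so planted parcels sit at a scale
#'   comparable to real cortical areas at the mesh resolution, rather than
#'   leaving sub-resolution slivers no boundary method could resolve.
#' @return a \code{parcellation} with no border vertices (label 0 only on
#'   the medial wall).
#' @export
synth_parcellation <- function(mesh, n_parcels, seed = 1L,
                               lloyd_iterations = 5L) {
  defined <- which(!mesh$medial_wall)
  if (n_parcels > length(defined))
    stop("n_parcels exceeds the defined vertex count")
  set.seed(seed)
  seeds <- sort(sample(defined, n_parcels))
  g <- mesh_igraph(mesh)
  assign_regions <- function(seeds) {
    d <- igraph::distances(g, v = seeds, to = defined)
    apply(d, 2L, which.min)
  }
  region <- assign_regions(seeds)
  for (it in seq_len(lloyd_iterations)) {
    new_seeds <- vapply(seq_len(n_parcels), function(p) {
      members <- defined[region == p]
      if (length(members) == 0L) return(seeds[p])
      dm <- igraph::distances(g, v = members, to = members)
      members[which.min(rowSums(dm))]   # geodesic medoid
    }, integer(1))
    new_seeds <- sort(new_seeds)
    if (identical(new_seeds, seeds)) break
    seeds <- new_seeds
    region <- assign_regions(seeds)
  }
  labels <- integer(n_vertices(mesh))
  labels[defined] <- region
  new_parcellation(labels, mesh, boundary = logical(n_vertices(mesh)),
                   provenance = sprintf("synthetic voronoi seed=%d", seed))
}

# igraph of the mesh with great-circle edge lengths, medial wall removed
mesh_igraph <- function(mesh) {
  if (!is.null(mesh$cache$igraph)) return(mesh$cache$igraph)
  tri <- mesh$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  keep <- !mesh$medial_wall[e[, 1L]] & !mesh$medial_wall[e[, 2L]]
  e <- e[keep, , drop = FALSE]
  w <- geodesic_sphere_distance(mesh$sphere[e[, 1L], , drop = FALSE],
                                mesh$sphere[e[, 2L], , drop = FALSE],
                                mesh$radius)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < n_vertices(mesh))
    g <- igraph::add_vertices(g, n_vertices(mesh) - igraph::vcount(g))
  igraph::E(g)$weight <- w
  mesh$cache$igraph <- g
  g
}

#' Balanced random assignment of parcels to networks
#'
#' @param n_parcels parcel count.
#' @param n_networks number of planted networks (k*).
#' @param seed RNG seed.
#' @return integer vector of network ids per parcel, sizes balanced to
#'   within one parcel.
#' @export
synth_networks <- function(n_parcels, n_networks, seed = 1L) {
  set.seed(seed)
  sample(rep_len(seq_len(n_networks), n_parcels))
}

# unit-variance AR(1) series (rho = 0.3 by default): realistic serial
# correlation so sample correlations have plausible variance
ar1_series <- function(n, t, rho = 0.3) {
  x <- matrix(rnorm(n * t), n, t)
  if (rho != 0) {
    s <- sqrt(1 - rho^2)
    for (j in 2:t) x[, j] <- rho * x[, j - 1L] + s * x[, j]
  }
  x
}

#' Smooth random spherical misalignment warp
#'
#' A band-limited random tangent displacement field: i.i.d. Gaussian 3D
#' vectors per vertex are smoothed on the sphere with a wide kernel,
#' projected to the tangent plane, and rescaled so the largest angular
#' displacement equals \code{max_degrees}. Emulates inter-subject residual
#' functional misalignment after folding-based registration.
#'
#' @param mesh a \code{cortical_mesh}.
#' @param max_degrees maximum angular displacement in degrees.
#' @param smooth_sigma smoothing width of the random field in mm.
#' @param seed RNG seed.
#' @return V x 3 matrix of displaced on-sphere positions (the identity when
#'   \code{max_degrees = 0}).
#' @export
random_smooth_warp <- function(mesh, max_degrees, smooth_sigma = 30,
                               seed = 1L) {
  pos <- mesh$sphere
  if (max_degrees == 0) return(pos)
  set.seed(seed)
  nv <- n_vertices(mesh)
  field <- matrix(rnorm(nv * 3L), nv, 3L)
  W <- smoothing_matrix(mesh, smooth_sigma)
  field <- as.matrix(W %*% field)
  # rows of W are zero on the medial wall; keep those displacements at zero
  normals <- pos / mesh$radius
  field <- field - normals * rowSums(field * normals)  # tangent projection
  mag <- sqrt(rowSums(field^2))
  scale <- (max_degrees * pi / 180) / max(mag, 1e-300)
  theta <- mag * scale                     # per-vertex rotation angle (rad)
  dir <- field / ifelse(mag > 0, mag, 1)
  out <- cos(theta) * pos + sin(theta) * (dir * mesh$radius)
  out * (mesh$radius / sqrt(rowSums(out^2)))
}

#' Synthetic BOLD-like scan on a parcellated sphere
#'
#' Generative model: each network has a latent unit-variance AR(1) signal;
#' each parcel mixes its network signal (weight \code{network_weight}) with
#' a parcel-specific signal; each vertex mixes its parcel signal (weight
#' \code{coherence}) with a vertex-private signal, and adds i.i.d. Gaussian
#' noise with standard deviation \code{1/snr} (so \code{snr} is the ratio of
#' parcel-signal sd to vertex-noise sd). An optional misalignment warp
#' displaces which parcel each vertex samples from, emulating imperfect
#' inter-subject registration.
#'
#' @param mesh a \code{cortical_mesh}.
#' @param parc ground-truth \code{parcellation}.
#' @param network_labels per-parcel network ids.
#' @param timepoints number of volumes T.
#' @param snr parcel-signal sd / vertex-noise sd.
#' @param coherence share of vertex signal variance carried by the parcel
#'   signal, in (0, 1].
#' @param network_weight share of parcel signal variance carried by the
#'   network latent, in [0, 1].
#' @param ar_rho lag-1 autocorrelation of all latent signals.
#' @param warp_positions optional V x 3 matrix of displaced sphere positions
#'   (see \code{\link{random_smooth_warp}}).
#' @param seed RNG seed.
#' @param ... scan metadata passed to \code{\link{scan_timeseries}}
#'   (subject_id, session_id, visit_id, age_days, phase_encoding, ...).
#' @return a \code{scan_timeseries} (medial-wall rows are \code{NA}).
#' @export
synth_timeseries <- function(mesh, parc, network_labels, timepoints = 300,
                             snr = 5, coherence = 0.9, network_weight = 0.5,
                             ar_rho = 0.3, warp_positions = NULL, seed = 1L,
                             ...) {
  stopifnot(snr > 0, coherence > 0, coherence <= 1,
            network_weight >= 0, network_weight <= 1)
  set.seed(seed)
  labels <- parc$labels
  if (!is.null(warp_positions)) {
    # vertex v samples the parcel planted at its displaced position
    nn <- nearest_vertex(mesh, warp_positions)
    labels <- parc$labels[nn]
    # displaced points landing on the medial wall keep their own parcel
    fix <- labels == 0L & parc$labels > 0L
    labels[fix] <- parc$labels[fix]
  }
  np <- max(parc$labels)
  nk <- max(network_labels)
  tt <- timepoints
  net_sig <- ar1_series(nk, tt, ar_rho)
  parc_sig <- ar1_series(np, tt, ar_rho)
  s <- sqrt(network_weight) * net_sig[network_labels, , drop = FALSE] +
    sqrt(1 - network_weight) * parc_sig
  nv <- n_vertices(mesh)
  x <- matrix(NA_real_, nv, tt)
  on_cortex <- which(labels > 0L & !mesh$medial_wall)
  priv <- ar1_series(length(on_cortex), tt, ar_rho)
  x[on_cortex, ] <- sqrt(coherence) * s[labels[on_cortex], , drop = FALSE] +
    sqrt(1 - coherence) * priv +
    matrix(rnorm(length(on_cortex) * tt, sd = 1 / snr),
           length(on_cortex), tt)
  scan_timeseries(x, ...)
}

# nearest mesh vertex for each row of an n x 3 matrix of sphere positions
nearest_vertex <- function(mesh, points) {
  sims <- points %*% t(mesh$sphere)
  max.col(sims, ties.method = "first")
}

#' Specification of a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator. Defaults are the
#' desk-scale validation conditions used throughout the package: an
#' icosphere with 642 vertices and a 5\% polar medial wall, 20 planted
#' parcels in 4 networks, 12 subjects with one visit of one AP/PA scan pair,
#' 300 volumes per scan at SNR 5.
#'
#' @param subdivisions icosphere subdivision level.
#' @param n_parcels planted parcel count.
#' @param n_networks planted network count (k*).
#' @param n_subjects subject count.
#' @param n_visits visits per subject.
#' @param sessions_per_visit sessions per visit.
#' @param phase_encodings scan phase-encoding directions per session.
#' @param timepoints volumes per scan.
#' @param snr parcel-signal sd / vertex-noise sd.
#' @param coherence within-parcel vertex coherence.
#' @param network_weight within-network parcel signal share.
#' @param ar_rho latent AR(1) coefficient.
#' @param misalign_degrees maximum subject misalignment angle (degrees);
#'   0 disables misalignment.
#' @param medial_wall_frac polar-cap medial-wall fraction.
#' @param age_groups age-group centers in months.
#' @param radius sphere radius in mm.
#' @param seed RNG seed recorded in every output's provenance.
#' @return a list of class \code{synth_cohort_spec}.
#' @export
synth_cohort_spec <- function(subdivisions = 3, n_parcels = 20,
                              n_networks = 4, n_subjects = 12, n_visits = 1,
                              sessions_per_visit = 1,
                              phase_encodings = c("AP", "PA"),
                              timepoints = 300, snr = 5, coherence = 0.9,
                              network_weight = 0.5, ar_rho = 0.3,
                              misalign_degrees = 0, medial_wall_frac = 0.05,
                              age_groups = c(3, 6, 9, 12, 18, 24),
                              radius = 100, seed = 1L) {
  spec <- as.list(environment())
  stopifnot(spec$n_parcels > 0, spec$n_networks > 0, spec$n_subjects > 0,
            spec$timepoints >= 2, spec$snr > 0)
  class(spec) <- "synth_cohort_spec"
  spec
}

#' Generate a full synthetic cohort
#'
#' Builds the mesh, ground-truth parcellation, network labels and
#' subject-specific misalignment warps, then simulates every scan of every
#' subject (subjects are spread round-robin over the age groups; scan ages
#' are jittered around the group month). The result mirrors the pipeline's
#' expected inputs: a scan list plus a metadata table with subject, session,
#' visit, age and phase-encoding columns.
#'
#' @param spec a \code{\link{synth_cohort_spec}}.
#' @return list with \code{mesh}, \code{scans} (list of
#'   \code{scan_timeseries}), \code{metadata} (data.frame), and
#'   \code{ground_truth} (parcellation, network labels, per-subject warp
#'   positions, spec).
#' @export
synth_cohort <- function(spec = synth_cohort_spec()) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  mesh <- icosphere(spec$subdivisions, radius = spec$radius,
                    medial_wall_frac = spec$medial_wall_frac)
  parc <- synth_parcellation(mesh, spec$n_parcels,
                             seed = derive_seed(spec$seed, 1L))
  networks <- synth_networks(spec$n_parcels, spec$n_networks,
                             seed = derive_seed(spec$seed, 2L))
  groups <- rep_len(spec$age_groups, spec$n_subjects)
  warps <- vector("list", spec$n_subjects)
  scans <- list()
  meta <- list()
  scan_no <- 0L
  for (s in seq_len(spec$n_subjects)) {
    warps[[s]] <- random_smooth_warp(mesh, spec$misalign_degrees,
                                     seed = derive_seed(spec$seed, 100L + s))
    set.seed(derive_seed(spec$seed, 200L + s))
    age0 <- round(groups[s] * 30.4375 + runif(1, -15, 15))
    for (v in seq_len(spec$n_visits)) {
      for (ses in seq_len(spec$sessions_per_visit)) {
        for (pe in spec$phase_encodings) {
          scan_no <- scan_no + 1L
          ids <- list(subject_id = sprintf("sub%02d", s),
                      visit_id = sprintf("sub%02d_v%d", s, v),
                      session_id = sprintf("sub%02d_v%d_s%d", s, v, ses),
                      phase_encoding = pe,
                      age_days = age0 + (v - 1L) * 90L,
                      age_group = paste0(groups[s], "M"))
          scans[[scan_no]] <- synth_timeseries(
            mesh, parc, networks, timepoints = spec$timepoints,
            snr = spec$snr, coherence = spec$coherence,
            network_weight = spec$network_weight, ar_rho = spec$ar_rho,
            warp_positions = if (spec$misalign_degrees > 0) warps[[s]],
            seed = derive_seed(spec$seed, 1000L + scan_no),
            subject_id = ids$subject_id, session_id = ids$session_id,
            visit_id = ids$visit_id, age_days = ids$age_days,
            phase_encoding = ids$phase_encoding)
          meta[[scan_no]] <- as.data.frame(ids, stringsAsFactors = FALSE)
        }
      }
    }
  }
  metadata <- do.call(rbind, meta)
  metadata$scan_id <- seq_len(nrow(metadata))
  list(mesh = mesh, scans = scans, metadata = metadata,
       ground_truth = list(parcellation = parc, networks = networks,
                           warps = warps, spec = spec))
}
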