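# Demons-style spherical registration driven by feature maps (local
# gradient maps, optionally folding maps), and the iterative group-template
# procedure: register every map to the current population mean, resample,
# re-average, repeat. The update rule is a classic normalized demons force
# along the template's tangent gradient, with fluid (update-field) and
# diffusion (total-displacement) Gaussian smoothing on the sphere, a
# coarse-to-fine feature-smoothing pyramid, fold prevention by step
# halving, and a monotone line search so the feature MSE never increases.

#' Registration parameters
#'
#' @param fluid_sigma Gaussian width (mm) for smoothing each iteration's
#'   update field.
#' @param diffusion_sigma Gaussian width (mm) for smoothing the accumulated
#'   displacement field.
#' @param n_iter inner iterations per pyramid level.
#' @param level_sigmas feature smoothing widths (mm) of the coarse-to-fine
#'   pyramid levels.
#' @param step_size maximum displacement per iteration (mm).
#' @param channel_weights weights of the feature channels (e.g. folding and
#'   local gradient); recycled to the channel count.
#' @param max_halvings line-search/fold-repair step halvings before giving
#'   up an iteration.
#' @return list of class \code{register_params}.
#' @export
register_params <- function(fluid_sigma = 6, diffusion_sigma = 4,
                            n_iter = 30, level_sigmas = c(12, 6, 3),
                            step_size = 4, channel_weights = 1,
                            max_halvings = 8) {
  p <- as.list(environment())
  class(p) <- "register_params"
  p
}

#' Identity spherical warp
#'
#' @param mesh a \code{cortical_mesh}.
#' @return a \code{spherical_warp} whose target positions are the mesh's
#'   own sphere coordinates (represented exactly).
#' @export
identity_warp <- function(mesh) {
  structure(list(target_positions = mesh$sphere, n_iterations_run = 0L,
                 feature_weights = 1, radius = mesh$radius),
            class = "spherical_warp")
}

#' @export
print.spherical_warp <- function(x, ...) {
  cat("spherical_warp: ", nrow(x$target_positions), " vertices, ",
      x$n_iterations_run, " iterations run\n", sep = "")
  invisible(x)
}

# Barycentric interpolation of per-vertex values at arbitrary on-sphere
# points (central-projection barycentrics). For each point the incident
# triangle fan of its nearest vertex is searched (vectorized over points,
# slot by slot, with per-triangle inverse matrices precomputed once per
# mesh); the triangle with the largest minimum barycentric weight wins,
# which also covers points on edges and vertices. Points whose fan search
# fails badly fall back to an exhaustive 2-ring search.
sphere_interp_weights <- function(mesh, points) {
  tri <- mesh$triangles
  nt <- nrow(tri)
  if (is.null(mesh$cache$interp_geom)) {
    v2t <- split(rep(seq_len(nt), 3L), c(tri[, 1L], tri[, 2L], tri[, 3L]))
    v2t <- lapply(seq_len(n_vertices(mesh)), function(v) {
      tt <- v2t[[as.character(v)]]
      if (is.null(tt)) integer(0) else as.integer(tt)
    })
    max_fan <- max(vapply(v2t, length, integer(1)))
    fan <- matrix(0L, n_vertices(mesh), max_fan)
    for (v in seq_len(n_vertices(mesh)))
      fan[v, seq_along(v2t[[v]])] <- v2t[[v]]
    minv <- matrix(0, nt, 9L)   # row-major 3x3 inverse of [a b c] columns
    for (t in seq_len(nt)) {
      m <- t(mesh$sphere[tri[t, ], , drop = FALSE])
      minv[t, ] <- as.numeric(t(solve(m)))
    }
    adj <- mesh_adjacency(mesh)
    mesh$cache$interp_geom <- list(v2t = v2t, fan = fan, minv = minv,
                                   adj = adj)
  }
  geom <- mesh$cache$interp_geom
  n <- nrow(points)
  nn <- nearest_vertex(mesh, points)
  best_min <- rep(-Inf, n)
  best_tri <- integer(n)
  best_w <- matrix(0, n, 3L)
  px <- points[, 1L]; py <- points[, 2L]; pz <- points[, 3L]
  for (slot in seq_len(ncol(geom$fan))) {
    tid <- geom$fan[nn, slot]
    act <- which(tid > 0L)
    if (length(act) == 0L) next
    m <- geom$minv[tid[act], , drop = FALSE]
    w1 <- m[, 1L] * px[act] + m[, 2L] * py[act] + m[, 3L] * pz[act]
    w2 <- m[, 4L] * px[act] + m[, 5L] * py[act] + m[, 6L] * pz[act]
    w3 <- m[, 7L] * px[act] + m[, 8L] * py[act] + m[, 9L] * pz[act]
    s <- w1 + w2 + w3
    ok <- s != 0
    w1 <- w1 / s; w2 <- w2 / s; w3 <- w3 / s
    mn <- pmin(w1, w2, w3)
    upd <- act[ok & mn > best_min[act]]
    if (length(upd) > 0L) {
      sel <- match(upd, act)
      best_min[upd] <- mn[sel]
      best_tri[upd] <- tid[upd]
      best_w[upd, ] <- cbind(w1[sel], w2[sel], w3[sel])
    }
  }
  # fallback: 2-ring exhaustive search for poorly matched points
  for (i in which(best_min < -1e-6)) {
    ring <- unique(c(nn[i], geom$adj[[nn[i]]],
                     unlist(geom$adj[geom$adj[[nn[i]]]], use.names = FALSE)))
    cand <- unique(unlist(geom$v2t[ring], use.names = FALSE))
    for (t in cand) {
      m <- matrix(geom$minv[t, ], 3L, 3L, byrow = TRUE)
      w <- as.numeric(m %*% points[i, ])
      s <- sum(w)
      if (s == 0) next
      w <- w / s
      if (min(w) > best_min[i]) {
        best_min[i] <- min(w)
        best_tri[i] <- t
        best_w[i, ] <- w
      }
    }
  }
  if (any(best_min < -0.05))
    stop("no containing triangle found for warped point(s) ",
         paste(head(which(best_min < -0.05), 3L), collapse = ", "))
  best_w <- pmax(best_w, 0)
  best_w <- best_w / rowSums(best_w)
  list(triangle = best_tri, weights = best_w,
       corners = tri[best_tri, , drop = FALSE])
}

sphere_interp <- function(mesh, values, points,
                          na_action = c("propagate", "zero")) {
  na_action <- match.arg(na_action)
  iw <- sphere_interp_weights(mesh, points)
  vals <- as.numeric(values)
  vmat <- matrix(vals[iw$corners], nrow(points), 3L)
  if (na_action == "zero") {
    vmat[is.na(vmat)] <- 0
    return(rowSums(iw$weights * vmat))
  }
  na_weight <- rowSums(iw$weights * is.na(vmat))
  vmat[is.na(vmat)] <- 0
  out <- rowSums(iw$weights * vmat)
  out[na_weight > 1e-6] <- NA_real_
  out
}

#' Resample a scalar map through a spherical warp
#'
#' Barycentric interpolation of the map at the warp's target positions:
#' vertex v of the result takes the map's value at
#' \code{warp$target_positions[v, ]}. The identity warp reproduces the map;
#' constant maps are invariant; outputs are bounded by the input range.
#'
#' @param values scalar map on \code{mesh}.
#' @param warp a \code{spherical_warp} on the same mesh.
#' @param mesh a \code{cortical_mesh}.
#' @return resampled scalar map (\code{NA} where the source is undefined).
#' @export
resample_map <- function(values, warp, mesh) {
  out <- sphere_interp(mesh, values, warp$target_positions)
  scalar_map(out, mesh)
}

# per-vertex tangent-plane gradient vectors (V x 3) of a map
vertex_gradient_vectors <- function(values, mesh) {
  op <- mesh_gradient_operator(mesh)
  v0 <- ifelse(is.na(values), 0, values)
  g <- cbind(as.numeric(op$avg %*% (op$gx %*% v0)),
             as.numeric(op$avg %*% (op$gy %*% v0)),
             as.numeric(op$avg %*% (op$gz %*% v0)))
  normals <- mesh$sphere / mesh$radius
  g <- g - normals * rowSums(g * normals)
  g[!op$vertex_ok, ] <- 0
  g
}

# weighted feature MSE over defined vertices
feature_mse <- function(warped, template, weights) {
  tot <- 0
  for (c in seq_along(template)) {
    d <- (warped[[c]] - template[[c]])^2
    tot <- tot + weights[c] * mean(d, na.rm = TRUE)
  }
  tot / sum(weights)
}

# smooth a V x 3 tangent field on the sphere and re-project to tangent
smooth_tangent_field <- function(field, mesh, sigma) {
  if (sigma <= 0) return(field)
  W <- smoothing_matrix(mesh, sigma)
  f <- as.matrix(W %*% field)
  normals <- mesh$sphere / mesh$radius
  f - normals * rowSums(f * normals)
}

# TRUE if no spherical triangle inverts orientation under positions `pos`
no_folds <- function(mesh, pos) {
  tri <- mesh$triangles
  sgn <- function(p) {
    a <- p[tri[, 1L], , drop = FALSE]
    b <- p[tri[, 2L], , drop = FALSE]
    c <- p[tri[, 3L], , drop = FALSE]
    # signed volume of (a, b, c): orientation of the spherical triangle
    a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
      a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
  }
  all(sign(sgn(pos)) == sign(sgn(mesh$sphere)))
}

project_sphere <- function(pos, radius) {
  pos * (radius / sqrt(rowSums(pos^2)))
}

#' Register feature maps onto a template
#'
#' Demons-like spherical registration: at each iteration the residual
#' (template minus warped individual) drives a displacement along the
#' template's tangent gradient (normalized demons force), the update field
#' is fluid-smoothed, the accumulated displacement diffusion-smoothed, and
#' the step is halved until no spherical triangle folds and the weighted
#' feature MSE does not increase (monotone objective). Matching runs over a
#' coarse-to-fine feature-smoothing pyramid.
#'
#' @param individual_features list of scalar maps (channels) of the moving
#'   scan.
#' @param template_features list of template scalar maps, channel-aligned.
#' @param mesh a \code{cortical_mesh}.
#' @param params a \code{\link{register_params}}.
#' @return a \code{spherical_warp} with fields \code{target_positions}
#'   (where each vertex samples the individual from),
#'   \code{n_iterations_run}, \code{feature_weights}, \code{mse_before} and
#'   \code{mse_after}.
#' @export
register_to_template <- function(individual_features, template_features,
                                 mesh, params = register_params()) {
  if (!is.list(individual_features)) individual_features <- list(individual_features)
  if (!is.list(template_features)) template_features <- list(template_features)
  nc <- length(template_features)
  if (length(individual_features) != nc)
    stop("feature channel counts differ")
  weights <- rep_len(params$channel_weights, nc)
  pos <- mesh$sphere
  n_run <- 0L
  mse0 <- feature_mse(individual_features, template_features, weights)
  for (sigma_l in params$level_sigmas) {
    ind_l <- lapply(individual_features, smooth_scalar_map, mesh = mesh,
                    sigma = sigma_l)
    tem_l <- lapply(template_features, smooth_scalar_map, mesh = mesh,
                    sigma = sigma_l)
    tgrad <- lapply(tem_l, vertex_gradient_vectors, mesh = mesh)
    warp_now <- structure(list(target_positions = pos), class = "spherical_warp")
    warped <- lapply(ind_l, function(f) sphere_interp(mesh, f, pos))
    warped <- lapply(warped, scalar_map, mesh = mesh)
    mse <- feature_mse(warped, tem_l, weights)
    for (it in seq_len(params$n_iter)) {
      force <- matrix(0, n_vertices(mesh), 3L)
      for (c in seq_len(nc)) {
        r <- tem_l[[c]] - warped[[c]]
        r[is.na(r)] <- 0
        g <- tgrad[[c]]
        g2 <- rowSums(g^2)
        denom <- g2 + r^2 + 1e-12
        force <- force + weights[c] * (r / denom) * g
      }
      force <- smooth_tangent_field(force, mesh, params$fluid_sigma)
      fmag <- sqrt(rowSums(force^2))
      mx <- max(fmag)
      if (mx == 0) break
      force <- force * (params$step_size / mx)
      step <- 1
      accepted <- FALSE
      for (h in seq_len(params$max_halvings)) {
        cand <- project_sphere(pos + step * force, mesh$radius)
        disp <- smooth_tangent_field(cand - mesh$sphere, mesh,
                                     params$diffusion_sigma)
        cand <- project_sphere(mesh$sphere + disp, mesh$radius)
        if (no_folds(mesh, cand)) {
          warped_c <- lapply(ind_l, function(f) sphere_interp(mesh, f, cand))
          warped_c <- lapply(warped_c, scalar_map, mesh = mesh)
          mse_c <- feature_mse(warped_c, tem_l, weights)
          if (mse_c <= mse) {
            pos <- cand
            warped <- warped_c
            mse <- mse_c
            accepted <- TRUE
            break
          }
        }
        step <- step / 2
      }
      n_run <- n_run + 1L
      if (!accepted) break
    }
  }
  warped_raw <- lapply(individual_features,
                       function(f) scalar_map(sphere_interp(mesh, f, pos), mesh))
  mse1 <- feature_mse(warped_raw, template_features, weights)
  if (mse1 > mse0) {
    # contract: never worse than the identity warp on the raw features
    pos <- mesh$sphere
    mse1 <- mse0
  }
  structure(list(target_positions = pos, n_iterations_run = n_run,
                 feature_weights = weights, radius = mesh$radius,
                 mse_before = mse0, mse_after = mse1),
            class = "spherical_warp")
}

#' Iterative group template from local gradient maps
#'
#' Builds the population-mean local gradient map by alternating
#' registration and re-averaging: (1) average all maps into the current
#' template, (2) register each map to it, (3) resample the warped maps and
#' re-average. The loop runs \code{n_outer} times (default 4) and stops
#' early when the template's maximum absolute change falls below
#' \code{tol}.
#'
#' @param maps list (or V x n matrix) of local gradient maps.
#' @param mesh a \code{cortical_mesh}.
#' @param n_outer outer iterations (default 4).
#' @param params a \code{\link{register_params}}.
#' @param tol early-stop tolerance on the template change.
#' @return list with \code{template} (the final mean map), \code{warps}
#'   (one \code{spherical_warp} per input map), \code{naive_mean} (the
#'   unregistered mean), and \code{n_outer_run}.
#' @export
build_group_template <- function(maps, mesh, n_outer = 4,
                                 params = register_params(), tol = 1e-4) {
  if (is.matrix(maps)) maps <- lapply(seq_len(ncol(maps)), function(i) maps[, i])
  if (length(maps) == 0L) stop("empty map list")
  maps <- lapply(maps, scalar_map, mesh = mesh)
  naive <- scalar_map(rowMeans(do.call(cbind, maps)), mesh)
  template <- naive
  warps <- lapply(maps, function(m) identity_warp(mesh))
  n_run <- 0L
  for (outer in seq_len(n_outer)) {
    warps <- lapply(maps, register_to_template,
                    template_features = list(template), mesh = mesh,
                    params = params)
    warped <- lapply(seq_along(maps), function(i)
      resample_map(maps[[i]], warps[[i]], mesh))
    new_template <- scalar_map(rowMeans(do.call(cbind, warped)), mesh)
    delta <- max(abs(new_template - template), na.rm = TRUE)
    template <- new_template
    n_run <- outer
    if (delta < tol) break
  }
  list(template = template, warps = warps, naive_mean = naive,
       n_outer_run = n_run)
}
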