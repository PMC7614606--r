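#' Parameters for a synthetic contact-site scene
#'
#' Bundles the ground-truth parameters from which a synthetic
#' ER-mitochondria contact site (MCS) is generated: a pair of membrane
#' patches separated by an intermembrane gap, and bridge dipoles placed on
#' the ER patch with configurable length, tilt and spatial-clustering
#' distributions. Defaults mirror the architecture measured in situ:
#' a 24.2 nm gap, bridge lengths 24.2 +/- 4.76 nm (truncated to the
#' observed 9.4-52 nm range), an expected 24 bridges per contact site, and
#' a 200 nm patch, which puts the bridge density near one per 1400-1700
#' nm^2 of ER membrane.
#'
#' @param seed integer seed; recorded in all outputs.
#' @param membrane_shape \code{"flat"}, \code{"spherical_cap"} or
#'   \code{"saddle"}.
#' @param curvature 1/nm; radius of the spherical cap or saddle scale.
#' @param patch_extent nm; side of the square patch (flat, saddle) or
#'   diameter of the cap base disc.
#' @param intermembrane_gap nm between the two membranes along normals.
#' @param n_bridges expected number of bridges (Poisson mean under CSR);
#'   ignored when \code{density} is given.
#' @param density bridges per nm^2 of ER membrane (overrides
#'   \code{n_bridges}).
#' @param length_mean,length_sd,length_min,length_max truncated-normal
#'   bridge-length distribution, nm.
#' @param tilt_scale degrees; scale of the folded-normal tilt distribution
#'   (tilt = |N(0, tilt_scale)|, so the true median tilt is about
#'   0.674 x \code{tilt_scale}).
#' @param placement \code{"csr"} (homogeneous Poisson on the surface) or
#'   \code{"thomas"} (Poisson parents with Gaussian offspring).
#' @param parent_intensity parents per nm^2 (Thomas process).
#' @param cluster_sd nm; Gaussian offspring displacement (Thomas).
#' @param mean_offspring expected offspring per parent (Thomas).
#' @param grid_n mesh resolution (grid cells per side / rings).
#' @param tomogram_id identifier stamped on the generated table.
#' @return A list of class \code{"scene_params"}.
#' @export
scene_params <- function(seed = 1L,
                         membrane_shape = c("flat", "spherical_cap", "saddle"),
                         curvature = 1 / 150,
                         patch_extent = 200,
                         intermembrane_gap = 24.2,
                         n_bridges = 24,
                         density = NULL,
                         length_mean = 24.2, length_sd = 4.76,
                         length_min = 9.4, length_max = 52,
                         tilt_scale = 16,
                         placement = c("csr", "thomas"),
                         parent_intensity = NULL,
                         cluster_sd = 10,
                         mean_offspring = 6,
                         grid_n = 40,
                         tomogram_id = "synthetic-1") {
  membrane_shape <- match.arg(membrane_shape)
  placement <- match.arg(placement)
  if (patch_extent <= 0) {
    stop_mcsarch("patch_extent must be positive", "configuration_error")
  }
  if (intermembrane_gap <= 0) {
    stop_mcsarch("intermembrane_gap must be positive", "configuration_error")
  }
  if (!(length_min < length_mean && length_mean < length_max)) {
    stop_mcsarch("need length_min < length_mean < length_max",
                 "configuration_error")
  }
  if (is.null(density) && n_bridges <= 0) {
    stop_mcsarch("n_bridges (or density) must be positive",
                 "configuration_error")
  }
  structure(list(seed = as.integer(seed), membrane_shape = membrane_shape,
                 curvature = curvature, patch_extent = patch_extent,
                 intermembrane_gap = intermembrane_gap,
                 n_bridges = n_bridges, density = density,
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = length_min, length_max = length_max,
                 tilt_scale = tilt_scale, placement = placement,
                 parent_intensity = parent_intensity,
                 cluster_sd = cluster_sd, mean_offspring = mean_offspring,
                 grid_n = grid_n, tomogram_id = tomogram_id),
            class = "scene_params")
}

# Base surface + analytic unit normals (pointing from OMM towards ER).
# The OMM is the base surface; the ER is offset by the gap along normals.
base_surface <- function(p) {
  n <- p$grid_n
  if (p$membrane_shape == "spherical_cap") {
    a <- p$patch_extent / 2
    R <- 1 / p$curvature
    if (a >= R) {
      stop_mcsarch("cap base radius must be below 1/curvature",
                   "configuration_error")
    }
    # polar mesh of a cap, rim at z = 0, sphere centre below the patch
    n_sec <- max(3L, 2L * n)
    rings <- seq(0, a, length.out = n + 1)
    centre_z <- -sqrt(R^2 - a^2)
    verts <- matrix(c(0, 0, R + centre_z), ncol = 3)
    for (r in rings[-1]) {
      th <- seq(0, 2 * pi, length.out = n_sec + 1)[-(n_sec + 1)]
      verts <- rbind(verts, cbind(r * cos(th), r * sin(th),
                                  sqrt(R^2 - r^2) + centre_z))
    }
    faces <- NULL
    # fan around the apex
    first <- 2
    faces <- cbind(1, first + seq_len(n_sec) - 1,
                   first + (seq_len(n_sec) %% n_sec))
    for (i in seq_len(n - 1)) {
      a0 <- 2 + (i - 1) * n_sec
      b0 <- 2 + i * n_sec
      j <- seq_len(n_sec) - 1
      jn <- seq_len(n_sec) %% n_sec
      faces <- rbind(faces,
                     cbind(a0 + j, b0 + j, b0 + jn),
                     cbind(a0 + j, b0 + jn, a0 + jn))
    }
    normals <- sweep(verts, 2, c(0, 0, centre_z))
    normals <- normals / sqrt(rowSums(normals^2))
    shape_info <- list(kind = "spherical_cap", R = R,
                       centre = c(0, 0, centre_z), base_radius = a)
  } else {
    g <- seq(0, p$patch_extent, length.out = n + 1)
    xy <- as.matrix(expand.grid(x = g, y = g))
    h <- p$patch_extent / 2
    if (p$membrane_shape == "flat") {
      z <- rep(0, nrow(xy))
      grad <- matrix(0, nrow(xy), 2)
    } else { # saddle z = c/2 * (x'^2 - y'^2)
      xc <- xy[, 1] - h; yc <- xy[, 2] - h
      z <- p$curvature / 2 * (xc^2 - yc^2)
      grad <- cbind(p$curvature * xc, -p$curvature * yc)
    }
    verts <- cbind(xy, z)
    normals <- cbind(-grad, 1)
    normals <- normals / sqrt(rowSums(normals^2))
    idx <- function(i, j) (j - 1) * (n + 1) + i
    i <- rep(seq_len(n), n)
    j <- rep(seq_len(n), each = n)
    faces <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    shape_info <- list(kind = p$membrane_shape, extent = p$patch_extent,
                       curvature = p$curvature)
  }
  list(vertices = verts, faces = faces, normals = normals,
       shape_info = shape_info)
}

#' Generate a paired ER/OMM membrane patch
#'
#' Builds the OMM patch from the requested shape and offsets every vertex
#' by the intermembrane gap along the local surface normal to obtain the
#' ER patch, so that the ER-to-OMM distance along normals equals the gap
#' by construction.
#'
#' @param p a \code{\link{scene_params}}.
#' @return List with \code{er} and \code{omm} (\code{membrane_patch}
#'   objects); vertex normals and analytic shape info are attached as
#'   attributes for downstream sampling.
#' @export
generate_membrane_pair <- function(p) {
  s <- base_surface(p)
  omm <- membrane_patch(s$vertices, s$faces, membrane = "omm")
  er <- membrane_patch(s$vertices + p$intermembrane_gap * s$normals,
                       s$faces, membrane = "er")
  attr(omm, "vertex_normals") <- s$normals
  attr(er, "vertex_normals") <- s$normals
  attr(omm, "shape_info") <- s$shape_info
  attr(er, "shape_info") <- s$shape_info
  list(er = er, omm = omm)
}

# Uniform sampling on a mesh: area-weighted triangle choice + uniform
# barycentric coordinates. Returns points and the face index of each.
sample_on_mesh <- function(mesh, n) {
  if (n == 0) {
    return(list(points = matrix(numeric(0), 0, 3), face = integer(0)))
  }
  ar <- triangle_areas(mesh)
  tri <- sample.int(length(ar), n, replace = TRUE, prob = ar)
  v <- mesh$vertices
  f <- mesh$faces[tri, , drop = FALSE]
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  pts <- w1 * v[f[, 1], , drop = FALSE] + w2 * v[f[, 2], , drop = FALSE] +
    w3 * v[f[, 3], , drop = FALSE]
  list(points = pts, face = tri)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm / sqrt(rowSums(nrm^2))
}

# Project points onto the mesh: orthogonal projection onto the plane of a
# nearby triangle, accepted only if the projection falls inside that
# triangle (barycentric test). Points whose projection lies on no nearby
# triangle are off the patch and dropped — the boundary behaviour expected
# of a point process on a finite membrane patch.
project_to_mesh <- function(mesh, pts, n_candidates = 8L) {
  if (nrow(pts) == 0) {
    return(list(points = pts, face = integer(0)))
  }
  ctr <- triangle_centroids(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  keep <- logical(nrow(pts))
  out <- matrix(NA_real_, nrow(pts), 3)
  face <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(ctr) - pts[i, ])^2)
    cand <- order(d2)[seq_len(min(n_candidates, length(d2)))]
    for (j in cand) {
      a <- v[f[j, 1], ]; b <- v[f[j, 2], ]; cc <- v[f[j, 3], ]
      e1 <- b - a; e2 <- cc - a
      nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
               e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      proj <- pts[i, ] - sum((pts[i, ] - a) * nrm) * nrm
      # barycentric coordinates of proj in triangle (a, b, cc)
      d00 <- sum(e1 * e1); d01 <- sum(e1 * e2); d11 <- sum(e2 * e2)
      w <- proj - a
      d20 <- sum(w * e1); d21 <- sum(w * e2)
      den <- d00 * d11 - d01 * d01
      if (den <= 0) next
      bv <- (d11 * d20 - d01 * d21) / den
      bw <- (d00 * d21 - d01 * d20) / den
      if (bv >= -1e-9 && bw >= -1e-9 && bv + bw <= 1 + 1e-9) {
        keep[i] <- TRUE
        out[i, ] <- proj
        face[i] <- j
        break
      }
    }
  }
  list(points = out[keep, , drop = FALSE], face = face[keep])
}

#' Sample bridge anchor positions on a membrane surface
#'
#' Places ER-anchor points on the mesh under either complete spatial
#' randomness (CSR; homogeneous Poisson with the scene intensity, so the
#' count is Poisson with mean intensity x area) or a Thomas cluster
#' process (Poisson parents on the surface, Poisson-many Gaussian
#' offspring displaced in the parent's tangent plane and projected back to
#' the surface).
#'
#' @param p a \code{\link{scene_params}}.
#' @param surface a \code{membrane_patch} (normally the ER patch).
#' @return List with \code{points} (n x 3 matrix), \code{face} (triangle
#'   index per point) and \code{lambda} (intensity used, per nm^2).
#' @export
sample_bridge_positions <- function(p, surface) {
  area <- sum(triangle_areas(surface))
  lambda <- if (!is.null(p$density)) p$density else p$n_bridges / area
  if (lambda <= 0) stop_mcsarch("intensity must be positive",
                                "configuration_error")
  if (lambda * area > 1e5) {
    stop_mcsarch("runaway scene: expected count above 1e5",
                 "configuration_error")
  }
  if (p$placement == "csr") {
    n <- stats::rpois(1, lambda * area)
    s <- sample_on_mesh(surface, n)
    return(list(points = s$points, face = s$face, lambda = lambda))
  }
  # Thomas: parent intensity defaults to lambda / mean_offspring so the
  # realized intensity matches the CSR intensity.
  kappa <- p$parent_intensity %||% (lambda / p$mean_offspring)
  n_par <- stats::rpois(1, kappa * area)
  parents <- sample_on_mesh(surface, n_par)
  nrm <- face_normals(surface)
  pts <- matrix(numeric(0), 0, 3)
  if (n_par > 0) {
    n_off <- stats::rpois(n_par, p$mean_offspring)
    for (i in seq_len(n_par)) {
      if (n_off[i] == 0) next
      n0 <- nrm[parents$face[i], ]
      u <- if (abs(n0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- u - sum(u * n0) * n0; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(n0[2] * e1[3] - n0[3] * e1[2],
              n0[3] * e1[1] - n0[1] * e1[3],
              n0[1] * e1[2] - n0[2] * e1[1])
      off <- matrix(stats::rnorm(2 * n_off[i], 0, p$cluster_sd), ncol = 2)
      disp <- off[, 1, drop = FALSE] %*% rbind(e1) +
        off[, 2, drop = FALSE] %*% rbind(e2)
      pts <- rbind(pts, sweep(disp, 2, parents$points[i, ], "+"))
    }
  }
  proj <- project_to_mesh(surface, pts)
  list(points = proj$points, face = proj$face, lambda = lambda)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
    guard <- guard + 1
    if (guard > 1000) {
      stop_mcsarch("truncated-normal rejection failed to converge",
                   "configuration_error")
    }
  }
  out[seq_len(n)]
}

# direction at `tilt` degrees from unit vector n, azimuth uniform over the
# tangent plane
tilted_direction <- function(n, tilt_deg, azimuth_deg) {
  u <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- u - sum(u * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  t <- tilt_deg * pi / 180; a <- azimuth_deg * pi / 180
  cos(t) * n + sin(t) * (cos(a) * e1 + sin(a) * e2)
}

#' Generate a ground-truthed synthetic contact-site scene
#'
#' Builds the membrane pair, samples ER anchors from the requested point
#' process, then draws for each bridge a length (truncated normal) and a
#' tilt (folded normal, azimuth uniform) and places the OMM anchor at the
#' drawn length along the tilted direction from the ER anchor towards the
#' OMM. Identical \code{(params, seed)} give identical output.
#'
#' @param p a \code{\link{scene_params}}.
#' @return List with \code{particles} (a \code{particle_table} of
#'   dipoles), \code{er}/\code{omm} membrane patches, and \code{truth}
#'   (data.frame of the realized per-bridge ground truth: anchors, length,
#'   tilt, azimuth) plus the parameters under \code{params}.
#' @export
generate_scene <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  set.seed(p$seed)
  mp <- generate_membrane_pair(p)
  pos <- sample_bridge_positions(p, mp$er)
  n <- nrow(pos$points)
  nrm <- face_normals(mp$er)
  truth <- data.frame(bridge_id = seq_len(n),
                      er_x = numeric(n), er_y = numeric(n), er_z = numeric(n),
                      omm_x = numeric(n), omm_y = numeric(n),
                      omm_z = numeric(n),
                      length = numeric(n), tilt = numeric(n),
                      azimuth = numeric(n))
  ext <- sum(triangle_areas(mp$er))
  bb_lo <- apply(mp$omm$vertices, 2, min) - p$intermembrane_gap
  bb_hi <- apply(mp$omm$vertices, 2, max) + p$intermembrane_gap
  for (i in seq_len(n)) {
    er_a <- pos$points[i, ]
    gapward <- -nrm[pos$face[i], ]   # ER normal pointing into the gap
    ok <- FALSE
    for (try in seq_len(100)) {
      len <- rtrunc_norm(1, p$length_mean, p$length_sd,
                         p$length_min, p$length_max)
      tilt <- abs(stats::rnorm(1, 0, p$tilt_scale)) %% 180
      if (tilt >= 90) next
      az <- stats::runif(1, -180, 180)
      d <- tilted_direction(gapward, tilt, az)
      omm_a <- er_a + len * d
      # reject draws that leave the scene bounding box sideways
      if (all(omm_a[1:2] >= bb_lo[1:2]) && all(omm_a[1:2] <= bb_hi[1:2])) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_mcsarch("failed to place OMM anchor after 100 redraws",
                   "degenerate_geometry_error")
    }
    truth[i, 2:10] <- c(er_a, omm_a, len, tilt, az)
  }
  particles <- particle_table(
    data.frame(tomogram_id = p$tomogram_id, bridge_id = truth$bridge_id,
               er_x = truth$er_x, er_y = truth$er_y, er_z = truth$er_z,
               omm_x = truth$omm_x, omm_y = truth$omm_y,
               omm_z = truth$omm_z),
    provenance = list(list(step = "generate_scene", seed = p$seed,
                           n = n, lambda = pos$lambda,
                           placement = p$placement)))
  list(particles = particles, er = mp$er, omm = mp$omm, truth = truth,
       params = p, lambda = pos$lambda, er_area = ext)
}
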