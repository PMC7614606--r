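#' Parameters for synthetic fluorescence z-stacks
#'
#' Ground-truth parameters for rendering diffraction-limited puncta: each
#' punctum carries a lognormally distributed number of fluorophore
#' molecules, is rendered as a 3-D Gaussian point-spread function (PSF)
#' scaled by molecules x counts-per-molecule, and the photon image is
#' corrupted by Poisson noise and a camera gain/offset. Two-channel mode
#' draws per-punctum molecule counts with a configurable inter-channel
#' correlation on the log scale.
#'
#' @param seed integer seed.
#' @param dim stack dimensions \code{c(ny, nx, nz)} in voxels.
#' @param voxel_xy,voxel_z voxel size, micrometres.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas, micrometres.
#' @param per_molecule_intensity camera counts contributed by one molecule
#'   (integrated over the PSF).
#' @param molecules_median,molecules_sdlog lognormal molecules-per-punctum
#'   distribution (median on the natural scale, sd on the log scale).
#' @param n_puncta puncta per stack.
#' @param cell_background photons per voxel of diffuse background.
#' @param camera_offset,gain camera model: counts = offset + gain x photons.
#' @param channels 1 or 2.
#' @param rho inter-channel correlation of log molecule counts, in [-1,1].
#' @param noise logical; \code{FALSE} renders the noise-free expectation.
#' @param min_separation minimum pairwise xy distance between puncta, in
#'   voxels (\code{NULL}: positions fully uniform). Use about 3 PSF sigmas
#'   to generate stacks where every punctum is individually resolvable.
#' @return A list of class \code{"image_params"}.
#' @export
image_params <- function(seed = 1L,
                         dim = c(64, 64, 16),
                         voxel_xy = 0.065, voxel_z = 0.2,
                         psf_sigma_xy = 0.11, psf_sigma_z = 0.35,
                         per_molecule_intensity = 200,
                         molecules_median = 26, molecules_sdlog = 0.4,
                         n_puncta = 10,
                         cell_background = 20,
                         camera_offset = 100, gain = 1,
                         channels = 1, rho = 0,
                         noise = TRUE, min_separation = NULL) {
  if (psf_sigma_xy <= 0 || psf_sigma_z <= 0) {
    stop_mcsarch("PSF sigmas must be positive", "configuration_error")
  }
  if (abs(rho) > 1) stop_mcsarch("rho must lie in [-1,1]",
                                 "configuration_error")
  if (per_molecule_intensity < 0 || cell_background < 0) {
    stop_mcsarch("intensities must be non-negative", "configuration_error")
  }
  if (!channels %in% c(1, 2)) {
    stop_mcsarch("channels must be 1 or 2", "configuration_error")
  }
  structure(list(seed = as.integer(seed), dim = dim,
                 voxel_xy = voxel_xy, voxel_z = voxel_z,
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 per_molecule_intensity = per_molecule_intensity,
                 molecules_median = molecules_median,
                 molecules_sdlog = molecules_sdlog,
                 n_puncta = n_puncta, cell_background = cell_background,
                 camera_offset = camera_offset, gain = gain,
                 channels = channels, rho = rho, noise = noise,
                 min_separation = min_separation),
            class = "image_params")
}

# Add one Gaussian punctum (total photon signal = amplitude) to a stack.
# Positions are continuous 1-based voxel coordinates; sigmas in voxels.
render_punctum <- function(stack, y, x, z, amplitude, sxy, sz) {
  d <- dim(stack)
  ry <- max(1, floor(y - 4 * sxy)):min(d[1], ceiling(y + 4 * sxy))
  rx <- max(1, floor(x - 4 * sxy)):min(d[2], ceiling(x + 4 * sxy))
  rz <- max(1, floor(z - 4 * sz)):min(d[3], ceiling(z + 4 * sz))
  gy <- exp(-(ry - y)^2 / (2 * sxy^2))
  gx <- exp(-(rx - x)^2 / (2 * sxy^2))
  gz <- exp(-(rz - z)^2 / (2 * sz^2))
  norm <- (2 * pi)^(3 / 2) * sxy^2 * sz
  block <- (amplitude / norm) * (gy %o% gx %o% gz)
  stack[ry, rx, rz] <- stack[ry, rx, rz] + block
  stack
}

apply_camera <- function(photons, p) {
  if (p$noise) {
    counts <- p$camera_offset +
      p$gain * stats::rpois(length(photons), pmax(photons, 0))
  } else {
    counts <- p$camera_offset + p$gain * photons
  }
  array(counts, dim = dim(photons))
}

#' Generate a synthetic punctum z-stack with ground truth
#'
#' Renders \code{n_puncta} 3-D Gaussian puncta at uniform sub-voxel
#' positions (kept 4 PSF sigmas inside the border), adds the diffuse cell
#' background, and applies the Poisson/gain/offset camera model. Pairs of
#' puncta closer than 2 PSF sigmas in xy are flagged unresolvable in the
#' truth table.
#'
#' @param p an \code{\link{image_params}}.
#' @return List with \code{stacks} (list of \code{[ny, nx, nz]} arrays,
#'   one per channel) and \code{truth} (data.frame: punctum id, continuous
#'   voxel position, true molecules per channel, \code{unresolvable}
#'   flag), plus \code{params}.
#' @export
generate_fm_stack <- function(p) {
  stopifnot(inherits(p, "image_params"))
  set.seed(p$seed)
  d <- p$dim
  sxy <- p$psf_sigma_xy / p$voxel_xy
  sz <- p$psf_sigma_z / p$voxel_z
  n <- p$n_puncta
  # border margins, clamped so thin stacks still leave a valid interior
  my <- min(4 * sxy + 1, (d[1] - 1) / 2)
  mx <- min(4 * sxy + 1, (d[2] - 1) / 2)
  mz <- min(4 * sz + 1, (d[3] - 1) / 2)
  pos <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("y", "x", "z")))
  for (i in seq_len(n)) {
    for (try in seq_len(500)) {
      cand <- c(stats::runif(1, my, d[1] - my),
                stats::runif(1, mx, d[2] - mx),
                stats::runif(1, mz, d[3] - mz))
      if (is.null(p$min_separation) || i == 1 ||
          min(sqrt((pos[seq_len(i - 1), 1] - cand[1])^2 +
                     (pos[seq_len(i - 1), 2] - cand[2])^2)) >=
            p$min_separation) {
        pos[i, ] <- cand
        break
      }
    }
    if (anyNA(pos[i, ])) {
      stop_mcsarch("could not place puncta at the requested separation",
                   "configuration_error")
    }
  }
  # correlated lognormal molecule counts across channels
  z1 <- stats::rnorm(n)
  mol <- matrix(NA_real_, n, p$channels)
  mol[, 1] <- p$molecules_median * exp(p$molecules_sdlog * z1)
  if (p$channels == 2) {
    z2 <- p$rho * z1 + sqrt(1 - p$rho^2) * stats::rnorm(n)
    mol[, 2] <- p$molecules_median * exp(p$molecules_sdlog * z2)
  }
  stacks <- vector("list", p$channels)
  for (ch in seq_len(p$channels)) {
    photons <- array(p$cell_background, dim = d)
    for (i in seq_len(n)) {
      photons <- render_punctum(photons, pos[i, 1], pos[i, 2], pos[i, 3],
                                mol[i, ch] * p$per_molecule_intensity,
                                sxy, sz)
    }
    stacks[[ch]] <- apply_camera(photons, p)
  }
  unres <- rep(FALSE, n)
  if (n >= 2) {
    dxy <- as.matrix(stats::dist(pos[, 1:2]))
    diag(dxy) <- Inf
    unres <- apply(dxy, 1, min) < 2 * sxy
  }
  truth <- data.frame(punctum_id = seq_len(n), y = pos[, 1], x = pos[, 2],
                      z = pos[, 3], molecules = mol[, 1],
                      unresolvable = unres)
  if (p$channels == 2) truth$molecules_ch2 <- mol[, 2]
  list(stacks = stacks, truth = truth, params = p)
}

#' Generate a synthetic two-channel mitochondrial cell
#'
#' Emulates a yeast cell whose mitochondrial network is marked in a red
#' channel and carries a green-labelled protein of interest: a random-walk
#' tube inside a circular cell region defines the true mitochondrial mask;
#' the red channel renders the mask (lightly blurred in xy), and the green
#' channel holds a fixed per-voxel density inside the mask plus cytosolic
#' background inside the cell. The truth records the exact mask and the
#' total mitochondrial green signal.
#'
#' @param p an \code{\link{image_params}}; \code{per_molecule_intensity}
#'   is reused as the green per-voxel mitochondrial density and
#'   \code{cell_background} as the cytosolic green background.
#' @param tube_radius tube radius, voxels.
#' @param n_steps random-walk steps.
#' @param red_density red photons per mitochondrial voxel.
#' @return List with \code{red}, \code{green} stacks, \code{mask} (logical
#'   truth array), \code{cell_roi} (\code{c(cx, cy, r)} in pixels),
#'   \code{true_total} (total mitochondrial green photons), and
#'   \code{params}.
#' @export
generate_mito_cell <- function(p, tube_radius = 1.5, n_steps = 200,
                               red_density = 200) {
  stopifnot(inherits(p, "image_params"))
  set.seed(p$seed)
  d <- p$dim
  cx <- d[2] / 2; cy <- d[1] / 2
  r_cell <- min(d[1], d[2]) / 2 - 2
  # random-walk tube centreline, biased to stay inside the cell
  pos <- c(cy, cx, d[3] / 2)
  path <- matrix(NA_real_, n_steps, 3)
  for (i in seq_len(n_steps)) {
    step <- stats::rnorm(3, 0, c(1.2, 1.2, 0.4))
    cand <- pos + step
    rad <- sqrt((cand[1] - cy)^2 + (cand[2] - cx)^2)
    if (rad > r_cell - tube_radius - 1 ||
        cand[3] < 2 || cand[3] > d[3] - 1) {
      cand <- pos + c(0.3 * (cy - pos[1]) / max(1, abs(cy - pos[1])),
                      0.3 * (cx - pos[2]) / max(1, abs(cx - pos[2])),
                      0.2 * (d[3] / 2 - pos[3]) / max(1, abs(d[3] / 2 - pos[3])))
    }
    pos <- cand
    path[i, ] <- pos
  }
  mask <- array(FALSE, dim = d)
  iy <- slice.index(mask, 1); ix <- slice.index(mask, 2)
  iz <- slice.index(mask, 3)
  for (i in seq_len(n_steps)) {
    near <- (iy - path[i, 1])^2 + (ix - path[i, 2])^2 +
      ((iz - path[i, 3]) * 2)^2 <= tube_radius^2 * 4
    mask <- mask | near
  }
  incell <- (iy - cy)^2 + (ix - cx)^2 <= r_cell^2
  mask <- mask & incell
  red_photons <- array(0, dim = d)
  red_photons[mask] <- red_density
  for (k in seq_len(d[3])) {
    red_photons[, , k] <- as.matrix(EBImage::gblur(
      EBImage::Image(red_photons[, , k]), sigma = 1))
  }
  green_photons <- array(0, dim = d)
  green_photons[incell] <- p$cell_background
  green_photons[mask] <- green_photons[mask] + p$per_molecule_intensity
  true_total <- p$per_molecule_intensity * sum(mask)
  list(red = apply_camera(red_photons, p),
       green = apply_camera(green_photons, p),
       mask = mask, cell_roi = c(cx = cx, cy = cy, r = r_cell),
       true_total = true_total, params = p)
}

#' Read and write z-stacks as multi-page TIFF
#'
#' Stacks are stored as 16-bit multi-page TIFF scaled by a fixed factor of
#' 65535, i.e. camera counts are assumed below 65535 (the range of the
#' 16-bit cameras being emulated). One file per channel.
#'
#' @param stack \code{[ny, nx, nz]} numeric array of counts.
#' @param path file path.
#' @return \code{write_stack}: the path, invisibly; \code{read_stack}: the
#'   array of counts.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(k)
    pmin(pmax(stack[, , k] / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                          length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65535
  arr
}
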