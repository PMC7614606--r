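# Fixtures are built in code; no binary data ships with the package.

# A dipole table mimicking the bookkeeping of a full picking session:
# `n_clean` good bridges over `n_tomo` tomograms (the first tomogram holds
# exactly 1 bridge and the second exactly 2, so nearest-neighbour
# eligibility drops 3 bridges from 2 tomograms), plus `n_misaligned` and
# `n_peroxisome` flagged picks.
make_picking_table <- function(n_clean = 1098, n_tomo = 51,
                               n_misaligned = 25, n_peroxisome = 10,
                               seed = 1) {
  set.seed(seed)
  stopifnot(n_clean >= n_tomo + 2)
  tomo <- c("tomo-01", "tomo-02", "tomo-02",
            sprintf("tomo-%02d", sample(3:n_tomo, n_clean - 3,
                                        replace = TRUE)))
  n_flag <- n_misaligned + n_peroxisome
  flags <- c(rep("", n_clean), rep("misaligned", n_misaligned),
             rep("peroxisome_mcs", n_peroxisome))
  tomo <- c(tomo, sprintf("tomo-%02d", sample(3:n_tomo, n_flag,
                                              replace = TRUE)))
  n <- n_clean + n_flag
  er <- matrix(runif(3 * n, 0, 800), ncol = 3)
  len <- pmin(pmax(rnorm(n, 24.2, 4.76), 9.4), 52)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  omm <- er + len * u
  df <- data.frame(tomogram_id = tomo, bridge_id = NA, er_x = er[, 1],
                   er_y = er[, 2], er_z = er[, 3], omm_x = omm[, 1],
                   omm_y = omm[, 2], omm_z = omm[, 3], flags = flags)
  df$bridge_id <- stats::ave(seq_len(n), df$tomogram_id,
                             FUN = seq_along)
  particle_table(df)
}

# O(n^2) brute-force nearest-neighbour oracle: explicit double loop,
# independent of the dist()-based implementation.
brute_force_nn <- function(pts) {
  n <- nrow(pts)
  d <- rep(Inf, n)
  id <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (dij < d[i]) {
        d[i] <- dij
        id[i] <- j
      }
    }
  }
  list(distance = d, neighbour = id)
}

# closed-form Pearson chi-square for a 2x2 table
chisq_closed_form <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  n <- a + b + cc + dd
  n * (a * dd - b * cc)^2 /
    ((a + b) * (cc + dd) * (a + cc) * (b + dd))
}

# random rigid transform (rotation + translation)
random_rigid <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, 0, 100))
}

# full triangulated sphere of radius r (lat/long grid)
sphere_mesh <- function(r = 1, n_th = 60, n_ph = 120) {
  th <- seq(0, pi, length.out = n_th + 1)
  verts <- do.call(rbind, lapply(th, function(a)
    cbind(r * sin(a) * cos(seq(0, 2 * pi,
                               length.out = n_ph + 1)[-(n_ph + 1)]),
          r * sin(a) * sin(seq(0, 2 * pi,
                               length.out = n_ph + 1)[-(n_ph + 1)]),
          r * cos(a))))
  idx <- function(i, j) (i - 1) * n_ph + ((j - 1) %% n_ph) + 1
  faces <- do.call(rbind, lapply(seq_len(n_th), function(i)
    do.call(rbind, lapply(seq_len(n_ph), function(j)
      rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
            c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))))))
  membrane_patch(verts, faces)
}

# simulated calibrated-imaging session: reference puncta at a known copy
# number and target puncta at a known median, on a shared intensity scale
simulate_session <- function(n_ref = 200, n_target = 200,
                             target_median = 26, reference_count = 80,
                             per_molecule = 50, sdlog = 0.4,
                             noise_sd = 100) {
  ref_mol <- reference_count * exp(rnorm(n_ref, 0, sdlog))
  tgt_mol <- target_median * exp(rnorm(n_target, 0, sdlog))
  list(ref = data.frame(integrated_intensity =
                          ref_mol * per_molecule + rnorm(n_ref, 0, noise_sd)),
       target = data.frame(integrated_intensity =
                             tgt_mol * per_molecule +
                               rnorm(n_target, 0, noise_sd)))
}
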