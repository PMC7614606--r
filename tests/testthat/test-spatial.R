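collinear_table <- function(pos, tomo = "t") {
  n <- length(pos)
  dipole_to_particle(particle_table(data.frame(
    tomogram_id = tomo, bridge_id = seq_len(n),
    er_x = pos, er_y = 0, er_z = 0,
    omm_x = pos, omm_y = 0, omm_z = 24)))
}

test_that("nearest-neighbour distances match hand computation", {
  t <- collinear_table(c(0, 5, 9))
  rec <- nn_distances(t, "er_anchor")
  expect_equal(rec$nn_distance[order(rec$bridge_id)], c(5, 4, 4))
  expect_equal(rec$nn_bridge_id[order(rec$bridge_id)], c(2, 3, 2))
})

test_that("nearest-neighbour search equals the O(n^2) brute-force oracle", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(3:60, 1)
    pts <- matrix(rnorm(3 * n, 0, 50), ncol = 3)
    t <- dipole_to_particle(particle_table(data.frame(
      tomogram_id = "t", bridge_id = seq_len(n),
      er_x = pts[, 1], er_y = pts[, 2], er_z = pts[, 3],
      omm_x = pts[, 1], omm_y = pts[, 2], omm_z = pts[, 3] + 24)))
    rec <- nn_distances(t, "er_anchor")
    oracle <- brute_force_nn(pts)
    expect_equal(rec$nn_distance, oracle$distance, tolerance = 1e-12)
    expect_equal(rec$nn_bridge_id, oracle$neighbour)
    # every NN distance bounds all other same-kind distances from below
    expect_true(all(rec$nn_distance <=
                      apply(as.matrix(dist(pts)) +
                              diag(Inf, n), 1, min) + 1e-12))
  }
})

test_that("tomograms under the minimum bridge count are excluded", {
  t <- make_picking_table(seed = 5)
  t <- filter_particles(t, c("misaligned", "peroxisome_mcs"))
  t <- dipole_to_particle(t)
  rec <- nn_distances(t, "centre", min_per_tomogram = 3)
  expect_equal(nrow(rec), 1095)
  expect_equal(attr(rec, "n_tomograms_used"), 49)
  expect_setequal(attr(rec, "excluded_tomograms"), c("tomo-01", "tomo-02"))
  expect_equal(attr(rec, "n_excluded_bridges"), 3)
  # same eligibility rule for all three point kinds
  for (kind in c("er_anchor", "omm_anchor")) {
    expect_equal(nrow(nn_distances(t, kind)), 1095)
  }
  only_small <- collinear_table(c(0, 5))
  expect_error(nn_distances(only_small, "centre"),
               class = "insufficient_data_error")
})

test_that("nn_summary uses unscaled median/MAD", {
  rec <- data.frame(nn_distance = c(3, 3, 7), tomogram_id = "t")
  s <- nn_summary(rec)
  expect_equal(s$median, 3)
  expect_equal(s$mad, 0)
  expect_equal(s$n, 3)
})

test_that("pooled CSR nearest-neighbour median matches the Poisson closed form", {
  lam <- 1 / 1407
  nn <- c()
  for (s in 1:80) {
    sc <- generate_scene(scene_params(seed = s, density = lam,
                                      patch_extent = 500,
                                      tilt_scale = 0.01, grid_n = 15))
    if (nrow(sc$particles) < 3) next
    nn <- c(nn, nn_distances(dipole_to_particle(sc$particles),
                             "er_anchor")$nn_distance)
  }
  expect_equal(median(nn), sqrt(log(2) / (pi * lam)), tolerance = 0.05)
})

test_that("class contingency reproduces the closed form and hand values", {
  # balanced table: no association
  rec0 <- data.frame(focal_class = rep(c("short", "long"), each = 20),
                     nn_class = rep(c("short", "long"), 20))
  c0 <- class_contingency(rec0)
  expect_equal(c0$chi_square, 0)
  expect_equal(c0$p_value, 1)

  rec1 <- data.frame(
    focal_class = rep(c("short", "long"), c(40, 40)),
    nn_class = c(rep("short", 30), rep("long", 10),
                 rep("short", 10), rep("long", 30)))
  c1 <- class_contingency(rec1)
  expect_equal(c1$chi_square, 20.0)
  expect_equal(c1$df, 1)
  expect_equal(c1$row_percent[1, 1], 75)

  set.seed(14)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    rec <- data.frame(
      focal_class = rep(rep(c("short", "long"), each = 2), as.vector(t(tab))),
      nn_class = rep(rep(c("short", "long"), 2), as.vector(t(tab))))
    expect_equal(class_contingency(rec)$chi_square,
                 chisq_closed_form(tab), tolerance = 1e-9)
  }

  degen <- data.frame(focal_class = rep("short", 5),
                      nn_class = rep("short", 5))
  expect_error(class_contingency(degen), class = "degenerate_table_error")
})

test_that("label permutation exposes the known anti-conservativeness of the NN chi-square", {
  # Nearest-neighbour contingency tables duplicate information through
  # reciprocal NN pairs, so the Pearson statistic runs above its nominal
  # chi-square(1) reference under label permutation. The rejection rate is
  # reproducibly inflated (roughly 2-3x nominal) but bounded; practical
  # conclusions should rest on effect sizes far from the 5% boundary.
  set.seed(15)
  sc <- generate_scene(scene_params(seed = 15, density = 1 / 1407,
                                    patch_extent = 700, grid_n = 15))
  t <- classify_by_length(dipole_to_particle(sc$particles))
  rec <- nn_distances(t, "centre")
  nb <- match(rec$nn_bridge_id, rec$bridge_id)
  expect_gt(mean(nb[nb] == seq_along(nb)), 0.5)  # many reciprocal pairs
  n_sim <- 400
  hits <- replicate(n_sim, {
    lab <- sample(rec$focal_class)
    perm <- data.frame(focal_class = lab, nn_class = lab[nb])
    class_contingency(perm)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.05)
  expect_lt(mean(hits), 0.30)
})

test_that("surface area sums contact triangles against closed forms", {
  sq <- membrane_patch(rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0),
                             c(0, 100, 0)),
                       rbind(c(1, 2, 3), c(1, 3, 4)), "er")
  expect_equal(as.numeric(surface_area(sq)), 10000)

  # full sphere mesh vs 4 pi r^2
  sph <- sphere_mesh(r = 1, n_th = 60, n_ph = 120)
  expect_gt(nrow(sph$faces), 5000)
  ar <- as.numeric(surface_area(sph))
  expect_equal(ar, 4 * pi, tolerance = 0.01)
  expect_gt(attr(surface_area(sph), "n_degenerate"), 0)  # polar slivers

  # contact filter against a finely meshed opposing membrane 24 nm away
  mp <- generate_membrane_pair(scene_params(patch_extent = 100,
                                            grid_n = 10,
                                            intermembrane_gap = 24))
  omm <- mp$er  # dense plane at z = 24
  expect_equal(as.numeric(surface_area(sq, omm, d_contact = 0)), 0)
  expect_equal(as.numeric(surface_area(sq, omm, d_contact = 40)), 10000)
})

test_that("area per bridge and densities follow the definitions", {
  mcs <- data.frame(mcs_id = "m1", er_contact_area = 10000, n_bridges = 5)
  apb <- area_per_bridge(mcs)
  expect_equal(apb$mcs$area_per_bridge, 2000)
  expect_equal(apb$mcs$density_per_1e4nm2, 5)
  expect_equal(apb$median, 2000)
  expect_equal(apb$mad, 0)  # single MCS

  mcs2 <- rbind(mcs, data.frame(mcs_id = "m2", er_contact_area = 8000,
                                n_bridges = 0))
  apb2 <- area_per_bridge(mcs2)
  expect_equal(apb2$n_excluded, 1)
  expect_equal(nrow(apb2$mcs), 1)
})

test_that("pooled area per bridge is consistent with the generating density", {
  lam <- 1 / 1407
  vals <- c()
  for (s in 1:60) {
    sc <- generate_scene(scene_params(seed = s + 300, density = lam,
                                      patch_extent = 500,
                                      tilt_scale = 0.01, grid_n = 10))
    n <- nrow(sc$particles)
    if (n == 0) next
    vals <- c(vals, sc$er_area / n)
  }
  expect_equal(median(vals), 1 / lam, tolerance = 0.1)
})

test_that("uniform spacing follows the hexagonal-lattice closed form", {
  expect_equal(round(uniform_spacing(1407)), 40)
  expect_equal(uniform_spacing(sqrt(3) / 2), 1.0)
  expect_equal(uniform_spacing(100), sqrt(200 / sqrt(3)), tolerance = 1e-12)
  expect_equal(uniform_spacing(100), 10.7457, tolerance = 1e-4)
  expect_error(uniform_spacing(0), class = "invalid_input_error")
})

test_that("bridge counts track contact area", {
  mcs <- data.frame(mcs_id = 1:5, er_contact_area = c(1, 2, 3, 4, 5) * 1e4,
                    n_bridges = c(5, 10, 15, 20, 25))
  bv <- bridges_vs_area(mcs)
  expect_equal(bv$r, 1)
  expect_equal(bv$max_density, 5)

  set.seed(16)
  areas <- runif(100, 1e4, 2e5)
  counts <- rpois(100, areas / 1407)
  bv2 <- bridges_vs_area(data.frame(mcs_id = 1:100,
                                    er_contact_area = areas,
                                    n_bridges = counts))
  expect_gt(bv2$r, 0.5)
  # shuffled pairing destroys the correlation
  bv3 <- bridges_vs_area(data.frame(mcs_id = 1:100,
                                    er_contact_area = areas,
                                    n_bridges = sample(counts)))
  expect_lt(abs(bv3$r), 0.3)
  expect_error(bridges_vs_area(mcs[1:2, ]),
               class = "insufficient_data_error")
})
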