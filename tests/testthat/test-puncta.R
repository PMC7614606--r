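sigma_vox <- function(p) c(xy = p$psf_sigma_xy / p$voxel_xy,
                           z = p$psf_sigma_z / p$voxel_z)

test_that("well-separated puncta are detected at their true positions", {
  # noise-free rendering isolates the detector geometry from shot noise
  p <- image_params(seed = 1, n_puncta = 10, noise = FALSE,
                    min_separation = 3 * 0.11 / 0.065)
  fm <- generate_fm_stack(p)
  s <- sigma_vox(p)
  det <- detect_puncta(fm$stacks[[1]], sigma_xy = s["xy"], sigma_z = s["z"])
  expect_equal(nrow(det), 10)
  for (i in seq_len(nrow(det))) {
    d <- sqrt((fm$truth$y - det$y[i])^2 + (fm$truth$x - det$x[i])^2 +
                (fm$truth$z - det$z[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("blank stacks yield zero detections", {
  p <- image_params(seed = 2, n_puncta = 0)
  fm <- generate_fm_stack(p)
  det <- detect_puncta(fm$stacks[[1]], sigma_xy = 1.7, sigma_z = 1.75)
  expect_equal(nrow(det), 0)
})

test_that("a sub-resolution pair is detected as one punctum", {
  p <- image_params(seed = 3, n_puncta = 0, noise = FALSE,
                    camera_offset = 100, cell_background = 20)
  fm <- generate_fm_stack(p)
  s <- sigma_vox(p)
  # render two puncta half a PSF sigma apart onto the background stack
  st <- fm$stacks[[1]]
  mid <- dim(st) / 2
  st <- mcsarch:::render_punctum(st, mid[1], mid[2], mid[3],
                                 26 * 200, s["xy"], s["z"])
  st <- mcsarch:::render_punctum(st, mid[1] + 0.5 * s["xy"], mid[2],
                                 mid[3], 26 * 200, s["xy"], s["z"])
  det <- detect_puncta(st, sigma_xy = s["xy"], sigma_z = s["z"])
  expect_equal(nrow(det), 1)
})

test_that("detection recall and precision reach 0.95 on resolvable puncta", {
  tp <- n_det <- n_true <- 0
  for (seed in 1:6) {
    p <- image_params(seed = seed, n_puncta = 10,
                      min_separation = 3 * 0.11 / 0.065)
    fm <- generate_fm_stack(p)
    s <- sigma_vox(p)
    det <- detect_puncta(fm$stacks[[1]], sigma_xy = s["xy"],
                         sigma_z = s["z"])
    n_det <- n_det + nrow(det)
    n_true <- n_true + nrow(fm$truth)
    for (i in seq_len(nrow(det))) {
      d <- sqrt((fm$truth$y - det$y[i])^2 + (fm$truth$x - det$x[i])^2 +
                  (fm$truth$z - det$z[i])^2)
      if (min(d) < 2) tp <- tp + 1
    }
  }
  expect_gte(tp / n_true, 0.95)
  expect_gte(tp / n_det, 0.95)
})

test_that("calibration maps the reference median to the reference count", {
  set.seed(4)
  ref <- data.frame(integrated_intensity = rlnorm(50, log(1000), 0.3))
  ref_med <- median(ref$integrated_intensity)
  puncta <- data.frame(integrated_intensity = c(ref_med, 0, 325))
  cal <- calibrate_counts(puncta, ref, reference_count = 80)
  expect_equal(cal$molecules[1], 80)
  expect_equal(cal$molecules[2], 0)
  # hand formula with a fixed reference median of 1000
  ref2 <- data.frame(integrated_intensity = rep(1000, 11))
  cal2 <- calibrate_counts(data.frame(integrated_intensity = 325), ref2)
  expect_equal(cal2$molecules, 26.0)

  expect_error(calibrate_counts(puncta, ref[1:5, , drop = FALSE]),
               class = "insufficient_data_error")
  bad_ref <- data.frame(integrated_intensity = rep(-5, 12))
  expect_error(calibrate_counts(puncta, bad_ref),
               class = "calibration_error")
})

test_that("calibration is invariant to a common intensity scale", {
  set.seed(5)
  ref <- data.frame(integrated_intensity = rlnorm(30, log(800), 0.4))
  tgt <- data.frame(integrated_intensity = rlnorm(40, log(260), 0.4))
  m1 <- calibrate_counts(tgt, ref)$molecules
  ref2 <- ref; tgt2 <- tgt
  ref2$integrated_intensity <- ref$integrated_intensity * 7.3
  tgt2$integrated_intensity <- tgt$integrated_intensity * 7.3
  m2 <- calibrate_counts(tgt2, ref2)$molecules
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("strain summaries match brute-force median/MAD recomputation", {
  s <- summarize_strain(list(c(10, 20, 30)))
  expect_equal(s$median_molecules, 20)
  expect_equal(s$mad_molecules, 10)

  s3 <- summarize_strain(list(c(24, 25, 26), c(26, 26, 26), c(27, 27, 28)))
  expect_equal(s3$per_repeat$median, c(25, 26, 27))
  expect_equal(s3$mean_of_medians, 26)
  expect_equal(s3$sd_of_medians, 1.0)

  set.seed(6)
  reps <- lapply(1:3, function(i) rlnorm(80, log(26), 0.4))
  s <- summarize_strain(reps)
  pooled <- unlist(reps)
  expect_equal(s$median_molecules, median(pooled))
  expect_equal(s$mad_molecules, median(abs(pooled - median(pooled))))
  expect_equal(s$n_puncta, 240)
})

test_that("ratio of medians recovers a known stoichiometry", {
  set.seed(7)
  # three repeats of a session, as in a standard imaging experiment
  tgt_mol <- ref_mol <- list()
  for (i in 1:3) {
    sess <- simulate_session(target_median = 3.6 * 80)
    ref_mol[[i]] <- calibrate_counts(sess$ref, sess$ref)$molecules
    tgt_mol[[i]] <- calibrate_counts(sess$target, sess$ref)$molecules
  }
  ratio <- ratio_of_medians(summarize_strain(tgt_mol),
                            summarize_strain(ref_mol))
  expect_equal(ratio, 3.6, tolerance = 0.1)
  # identical strains give 1
  same <- summarize_strain(ref_mol)
  expect_equal(ratio_of_medians(same, same), 1.0)
  zero <- summarize_strain(list(rep(0, 5)))
  expect_error(ratio_of_medians(same, zero), class = "calibration_error")
})

test_that("intensity correlation is exact for proportional channels", {
  set.seed(8)
  pa <- data.frame(y = runif(20, 5, 50), x = runif(20, 5, 50),
                   z = runif(20, 3, 10),
                   integrated_intensity = rlnorm(20, 7, 0.5))
  pb <- pa
  pb$integrated_intensity <- 2 * pa$integrated_intensity
  r <- intensity_correlation(pa, pb)
  expect_equal(r$r, 1.0)
  expect_equal(r$n, 20)
  expect_error(intensity_correlation(pa[1:2, ], pb[1:2, ]),
               class = "insufficient_data_error")
})

test_that("correlation estimate is unbiased near the generating rho", {
  set.seed(9)
  rs <- replicate(300, {
    n <- 128
    z1 <- rnorm(n); z2 <- 0.55 * z1 + sqrt(1 - 0.55^2) * rnorm(n)
    pos <- data.frame(y = seq_len(n) * 5, x = 1, z = 1)
    a <- cbind(pos, integrated_intensity = z1)
    b <- cbind(pos, integrated_intensity = z2)
    intensity_correlation(a, b)$r
  })
  expect_lt(abs(mean(rs) - 0.55), 0.05)
})

test_that("null channels exceed the 5% critical r at the nominal rate", {
  set.seed(10)
  crit <- qt(0.975, 98) / sqrt(98 + qt(0.975, 98)^2)  # r cutoff, n = 100
  expect_equal(crit, 0.196, tolerance = 0.01)
  hits <- replicate(500, {
    n <- 100
    pos <- data.frame(y = seq_len(n) * 5, x = 1, z = 1)
    a <- cbind(pos, integrated_intensity = rnorm(n))
    b <- cbind(pos, integrated_intensity = rnorm(n))
    abs(intensity_correlation(a, b)$r) > crit
  })
  expect_gt(mean(hits), 0.05 - 3 * sqrt(0.05 * 0.95 / 500))
  expect_lt(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("corrected total fluorescence follows the slice formula", {
  # one synthetic slice with known integrated density, area and background
  d <- c(40, 40, 1)
  red <- array(0, d); green <- array(2, d)  # uniform background 2
  red[15:24, 15:24, 1] <- 100               # 100-px mito block
  green[15:24, 15:24, 1] <- 12              # 10 counts over background
  m <- total_mito_fluorescence(red, green, cell_roi = c(20, 20, 18))
  expect_equal(m$slices$area, 100)
  expect_equal(m$slices$int_den, 1200)
  expect_equal(m$slices$mean_bg, 2)
  expect_equal(m$total, 1200 - 100 * 2)

  # green identically zero -> total 0
  m0 <- total_mito_fluorescence(red, array(0, d), cell_roi = c(20, 20, 18))
  expect_equal(m0$total, 0)
})

test_that("corrected total is exactly offset-invariant in noise-free mode", {
  p <- image_params(seed = 11, dim = c(40, 40, 6), noise = FALSE)
  mc <- generate_mito_cell(p)
  m1 <- total_mito_fluorescence(mc$red, mc$green, mc$cell_roi)
  m2 <- total_mito_fluorescence(mc$red, mc$green + 57.3, mc$cell_roi)
  expect_equal(m1$total, m2$total, tolerance = 1e-9)
})

test_that("total fluorescence recovers generator truth under noise", {
  errs <- vapply(1:5, function(s) {
    p <- image_params(seed = s, dim = c(48, 48, 10))
    mc <- generate_mito_cell(p)
    m <- suppressWarnings(
      total_mito_fluorescence(mc$red, mc$green, mc$cell_roi))
    abs(m$total - mc$true_total) / mc$true_total
  }, numeric(1))
  expect_lt(max(errs), 0.15)
})
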