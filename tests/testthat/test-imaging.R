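test_that("autocorrelation is 1 at zero shift and flat for white noise", {
  set.seed(10)
  patch <- matrix(runif(96 * 96), 96)
  acf <- pearson_autocorrelation(patch, 8)
  expect_equal(acf$r[1], 1)
  # independence: |r| < 3/sqrt(N) at non-zero shifts
  expect_true(all(abs(acf$r[-1]) < 3 / sqrt(96 * 95)))
  expect_error(pearson_autocorrelation(matrix(5, 10, 10), 3), "constant")
})

test_that("ACF of an analytic Gaussian is Gaussian with sqrt(2) larger width", {
  for (sigma in c(2, 4, 8)) {
    # patch much larger than the blob, so the Pearson mean-subtraction does
    # not depress the tails
    half <- 16 * sigma
    xs <- (-half):half
    g <- exp(-outer(xs^2, xs^2, `+`) / (2 * sigma^2))
    acf <- pearson_autocorrelation(g, round(4 * sigma))
    fit <- fwhm_from_acf(acf, pixel_pitch_um = 1)
    expect_lt(abs(fit$sigma_acf_nm / 1000 - sqrt(2) * sigma),
              0.02 * sqrt(2) * sigma)
  }
})

test_that("noiseless fit identity and the sqrt(2) relation hold exactly", {
  # exact samples of exp(-x^2 / (2 sigma^2)): the fit must return sigma to
  # machine-level accuracy, and the reported object FWHM must equal the
  # directly-known object FWHM through the sqrt(2) relation
  sigma_obj <- 5
  sigma_acf <- sqrt(2) * sigma_obj
  acf <- data.frame(shift = 0:15, r = exp(-(0:15)^2 / (2 * sigma_acf^2)))
  fit <- fwhm_from_acf(acf, pixel_pitch_um = 0.04)
  expect_equal(fit$fwhm_nm, 2 * sqrt(log(2)) * sigma_acf * 40,
               tolerance = 1e-6)
  expect_equal(fit$fwhm_nm, 2 * sqrt(2 * log(2)) * sigma_obj * 40,
               tolerance = 1e-6)
  expect_equal(fit$fwhm_acf_nm / fit$fwhm_nm, sqrt(2), tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-6)
  expect_true(fit$converged)
  # malformed inputs
  expect_error(fwhm_from_acf(acf[1:4, ]), "5")
  expect_error(fwhm_from_acf(data.frame(shift = 0:9, r = seq(0, 1, length.out = 10))),
               "decreasing")
})

test_that("rendered 140 nm and 600 nm foci are sized within tolerance", {
  cfg140 <- foci_render_config(lateral_fwhm = 0.14, axial_fwhm = 0.20,
                               peak_intensity = 1000, background = 0)
  st <- render_foci_stack(matrix(c(1.28, 1.28, 1.28), 1), cfg140,
                          dim = c(64, 64, 16))
  sm <- measure_focus_size(st, c(1.28, 1.28, 1.28), patch_halfwidth = 24,
                           max_shift = 12)
  expect_lt(abs(sm$fwhm_nm - 140), 15)

  cfg600 <- foci_render_config(lateral_fwhm = 0.60, axial_fwhm = 0.70,
                               peak_intensity = 1000, background = 0)
  st6 <- render_foci_stack(matrix(c(3.84, 3.84, 1.28), 1), cfg600,
                           dim = c(192, 192, 16))
  sm6 <- measure_focus_size(st6, c(3.84, 3.84, 1.28), patch_halfwidth = 80,
                            max_shift = 15)
  expect_lt(abs(sm6$fwhm_nm - 600), 40)
})

test_that("3D detection resolves separated foci and merges coincident ones", {
  cfg <- foci_render_config(peak_intensity = 1000, background = 5)
  # two foci 3x FWHM apart
  cen <- rbind(c(1.0, 1.0, 1.2), c(1.42, 1.0, 1.2))
  st <- render_foci_stack(cen, cfg, dim = c(64, 64, 16))
  foci <- count_foci_3d(st, min_peak = 300)
  expect_identical(nrow(foci), 2L)
  got <- as.matrix(foci[order(foci$x_um), c("x_um", "y_um", "z_um")])
  expect_lt(max(abs(got - cen)), 0.17)  # about one voxel (z pitch 0.16)

  # coincident centers: one detection
  st1 <- render_foci_stack(rbind(c(1.0, 1.0, 1.2), c(1.0, 1.0, 1.2)), cfg,
                           dim = c(64, 64, 16))
  expect_identical(nrow(count_foci_3d(st1, min_peak = 300)), 1L)

  # empty stack: no detections
  st0 <- render_foci_stack(NULL, cfg, dim = c(32, 32, 8))
  expect_identical(nrow(count_foci_3d(st0, min_peak = 300)), 0L)
})

test_that("detection recovers a 20-focus high-SNR stack without spurious hits", {
  set.seed(7)
  dims <- c(128, 128, 24)
  cfg <- foci_render_config(peak_intensity = 1000, background = 10,
                            poisson_noise = TRUE, seed = 99)
  ext <- dims * cfg$voxel_pitch
  cen <- separated_centers(20, ext, margin = c(0.4, 0.4, 0.6),
                           min_sep = 2 * 0.14)
  st <- render_foci_stack(cen, cfg, dim = dims)
  foci <- count_foci_3d(st, min_peak = 300, min_separation = 0.14)
  dmat <- matrix(NA_real_, 20, nrow(foci))
  for (i in 1:20)
    dmat[i, ] <- sqrt(colSums((t(as.matrix(foci[, 1:3])) - cen[i, ])^2))
  recall <- sum(apply(dmat, 1, min) < 0.17)
  spurious <- sum(apply(dmat, 2, min) >= 0.17)
  expect_gte(recall, 19)
  expect_identical(spurious, 0L)
})

test_that("detection is translation-equivariant over whole voxels", {
  cfg <- foci_render_config(peak_intensity = 800, background = 3)
  cen <- rbind(c(0.8, 0.9, 0.8), c(1.6, 1.5, 1.6))
  st <- render_foci_stack(cen, cfg, dim = c(64, 64, 16))
  shift_vox <- c(5, -3, 2)
  st2 <- render_foci_stack(sweep(cen, 2, shift_vox * cfg$voxel_pitch, `+`),
                           cfg, dim = c(64, 64, 16))
  f1 <- count_foci_3d(st, 300)
  f2 <- count_foci_3d(st2, 300)
  expect_identical(nrow(f1), nrow(f2))
  m1 <- unname(as.matrix(f1[order(f1$x_um), 1:3]))
  m2 <- unname(as.matrix(f2[order(f2$x_um), 1:3]))
  expect_equal(m2, sweep(m1, 2, shift_vox * cfg$voxel_pitch, `+`),
               tolerance = 1e-6)
})

test_that("colocalization gate keeps only double-positive foci", {
  a <- data.frame(x_um = c(1, 5, 9), y_um = 1, z_um = 1)
  b <- data.frame(x_um = c(1.1, 8.0), y_um = 1, z_um = 1)
  kept <- colocalization_filter(a, b, radius = 0.3)
  expect_identical(kept$x_um, 1)          # 0.1 um away: kept
  expect_false(5 %in% kept$x_um)          # 1+ um away: dropped
  # subset property and idempotence
  expect_true(all(kept$x_um %in% a$x_um))
  expect_identical(colocalization_filter(kept, b, 0.3), kept)
  # empty partner channel: nothing passes
  expect_identical(nrow(colocalization_filter(a, a[0, ], 0.3)), 0L)
})

test_that("track statistics use projected span with single-focus fallback", {
  foci <- data.frame(x_um = seq(0, 4, length.out = 8), y_um = 0, z_um = 0)
  st <- track_irif_stats(foci, axis = c(1, 0, 0))
  expect_equal(st$track_length_um, 4)
  expect_equal(st$lid, 2.0)

  single <- track_irif_stats(foci[1, ], axis = c(1, 0, 0))
  expect_equal(single$track_length_um, 7.6)
  expect_error(track_irif_stats(foci[0, ]), "no foci")

  # projection ignores off-axis scatter
  foci$y_um <- rnorm(8, 0, 0.05)
  expect_equal(track_irif_stats(foci, c(1, 0, 0))$track_length_um, 4)

  # optional tilt correction lengthens the track
  tilted <- track_irif_stats(foci, c(1, 0, 0), tilt_correction = TRUE)
  expect_equal(tilted$track_length_um, 4 / cos(9 * pi / 180))
})

test_that("per-volume densities and the reference gamma table agree", {
  expect_equal(irif_density_per_volume(30, 1000), 0.03)
  expect_error(irif_density_per_volume(30, 0), "volume")
  expect_equal(nuclear_box_volume(12, 10, 6), 720)

  tab <- gamma_reference_densities()
  expect_true(all(c("dose_gy", "time_min", "marker", "irif_per_um3")
                  %in% names(tab)))
  # early-time averages: 0.048 /um^3 at 1.9 Gy and 0.067 /um^3 at 3.0 Gy
  expect_equal(average_early_density(tab, 1.9), 0.048, tolerance = 5e-3)
  expect_equal(average_early_density(tab, 3.0), 0.067, tolerance = 5e-3)
  # per-cell densities are averaged, not re-ratioed
  expect_equal(average_early_density(tab, 1.9),
               mean(c(0.043, 0.052, 0.0486)))
})
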