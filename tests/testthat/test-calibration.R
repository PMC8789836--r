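# Shared fixture: one default-condition calibration reused across blocks.
calib_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tracks <- simulate_tracks(default_let_grid(), 500, seed = 21)
      dens <- density_table(tracks, 0.14)
      cache <<- list(tracks = tracks, dens = dens,
                     curve = build_calibration(dens, 0.14, seed = 21))
    }
    cache
  }
})

test_that("calibration build rejects degenerate ensembles", {
  tracks <- simulate_tracks(50, 60, seed = 1)
  dens <- density_table(tracks, 0.14)
  expect_error(build_calibration(dens, 0.14), "4 distinct LET")
  small <- density_table(simulate_tracks(c(10, 20, 40, 80), 10, seed = 2),
                         0.14)
  expect_error(build_calibration(small, 0.14), "tracks")
  expect_error(build_calibration(dens[, -7], 0.14), "lcd")
})

test_that("central curve interpolates the isotonized knot means", {
  cv <- calib_fixture()$curve
  expect_equal(predict(cv, cv$let_grid), cv$mean_lcd)
  expect_true(all(diff(cv$mean_lcd) >= 0))
  expect_true(all(cv$band_low <= cv$mean_lcd + 1e-9))
  expect_true(all(cv$mean_lcd <= cv$band_high + 1e-9))
  # held at boundary values outside the grid
  expect_equal(predict(cv, 1), cv$mean_lcd[1])
  expect_equal(predict(cv, 1000), cv$mean_lcd[length(cv$mean_lcd)])
  # monotone between knots too
  probe <- seq(min(cv$let_grid), max(cv$let_grid), length.out = 500)
  expect_true(all(diff(predict(cv, probe)) >= -1e-12))
})

test_that("zero-scatter central curve matches the 1D closed form", {
  # collinear DSBs on long straight chords, where the cluster rate converges
  # to lambda * exp(-lambda * d); a 1% systematic allowance covers the
  # O(1/L) boundary terms that remain at L = 500 um
  set.seed(303)
  d <- 0.14
  cfg <- sim_config(radial_sigma = 0)
  geom <- track_geometry(c(0, 0, 0), c(1, 0, 0), chord_length = 500)
  lets <- c(20, 50, 100, 180)
  dens <- do.call(rbind, lapply(lets, function(let) {
    rows <- lapply(1:400, function(i) {
      tr <- simulate_dsb_positions(geom, let, cfg)
      track_densities(tr, d)
    })
    do.call(rbind, rows)
  }))
  cv <- build_calibration(dens, d)
  for (i in seq_along(lets)) {
    lam <- cfg$dsb_yield_coeff * lets[i]
    oracle <- lam * exp(-lam * d)
    g <- dens[dens$let == lets[i], ]
    el <- ensemble_lcd(g)
    expect_lt(abs(cv$mean_lcd_raw[i] - oracle), 3 * el$se + 0.01 * oracle)
  }
})

test_that("detection limit sits where the curve crosses the threshold", {
  expect_equal(lcd_detection_threshold(), 0.3)  # 3 clusters per 10 um
  expect_equal(lcd_detection_threshold(4, 8), 0.5)

  cv <- calib_fixture()$curve
  dl <- detection_limit(cv)
  # the closed form k*LET*exp(-k*LET*d) = 0.3 gives ~8.4 keV/um; short-track
  # edge effects shift the simulated curve slightly, within +/- 1.5
  expect_lt(abs(dl - 8), 1.5)
  expect_equal(cv$let_min_detect, dl)

  # a tenfold brighter curve detects at lower LET
  dens10 <- calib_fixture()$dens
  dens10$n_clusters <- dens10$n_clusters * 10
  dens10$lcd <- dens10$lcd * 10
  cv10 <- build_calibration(dens10, 0.14)
  expect_lt(detection_limit(cv10), dl)

  # a curve that never reaches the threshold errors
  low <- calib_fixture()$dens
  low$n_clusters <- 0L
  low$lcd <- 0
  cvlow <- suppressWarnings(build_calibration(low, 0.14))
  expect_error(detection_limit(cvlow), "never reaches")
})

test_that("saturation limit respects slope geometry", {
  cv <- calib_fixture()$curve
  expect_equal(saturation_limit(cv, 0), max(cv$let_grid))
  # the 1D density maximum sits at lambda = 1/d, i.e. LET ~ 1/(k d) ~ 190:
  # the rated range must end at or before it
  expect_lte(saturation_limit(cv, 0.1), 1 / (0.0375 * 0.14))
  expect_equal(cv$let_max_invertible, saturation_limit(cv, 0.1))

  # larger clusters saturate earlier under identical track ensembles
  dens600 <- density_table(calib_fixture()$tracks, 0.6)
  cv600 <- build_calibration(dens600, 0.6)
  expect_lt(saturation_limit(cv600, 0.1), saturation_limit(cv, 0.1))
})

test_that("LET round trip through the inverse is exact to tolerance", {
  cv <- calib_fixture()$curve
  # the identity holds over the rated (invertible) LET range
  for (L in seq(10, cv$let_max_invertible, length.out = 15)) {
    est <- estimate_let(cv, predict(cv, L))
    expect_equal(est$status, "ok")
    expect_lt(abs(est$let - L), 0.5)
    expect_gte(est$delta_let, 0)
  }
})

test_that("estimate_let flags the invalid regimes", {
  cv <- calib_fixture()$curve
  expect_identical(estimate_let(cv, 0.1)$status, "below_detection")
  expect_identical(estimate_let(cv, max(cv$mean_lcd) + 0.5)$status,
                   "saturated")
  # a lid exactly at the plateau resolves to the smallest LET attaining it
  at_plateau <- estimate_let(cv, max(cv$mean_lcd))
  expect_identical(at_plateau$status, "ok")
  expect_equal(predict(cv, at_plateau$let), max(cv$mean_lcd),
               tolerance = 1e-6)
  expect_lte(at_plateau$let,
             min(cv$let_grid[cv$mean_lcd >= max(cv$mean_lcd)]) + 0.01)
  expect_error(estimate_let(cv, -1), "lid")
  expect_error(estimate_let(cv, 1, -0.1), "delta_lid")
  # wider measurement box -> wider LET interval
  e1 <- estimate_let(cv, 1.5, 0.05)
  e2 <- estimate_let(cv, 1.5, 0.2)
  expect_gte(e2$delta_let, e1$delta_let)
})

test_that("band contains about 68% of per-track densities in the rated range", {
  fx <- calib_fixture()
  cv <- fx$curve
  use <- cv$let_grid >= cv$let_min_detect & cv$let_grid <= cv$let_max_invertible
  inside <- total <- 0
  for (i in which(use)) {
    g <- fx$dens[fx$dens$let == cv$let_grid[i], ]
    inside <- inside + sum(g$lcd >= cv$band_low[i] & g$lcd <= cv$band_high[i])
    total <- total + nrow(g)
  }
  cover <- inside / total
  expect_gte(cover, 0.64)
  expect_lte(cover, 0.72)
})

test_that("identical ensembles and seed give a bit-identical serialized curve", {
  t1 <- simulate_tracks(c(10, 30, 80, 150), 80, seed = 5)
  t2 <- simulate_tracks(c(10, 30, 80, 150), 80, seed = 5)
  c1 <- build_calibration(density_table(t1, 0.14), 0.14, seed = 5)
  c2 <- build_calibration(density_table(t2, 0.14), 0.14, seed = 5)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_calibration(c1, f1)
  write_calibration(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
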