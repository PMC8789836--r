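# LCD(LET) calibration: central monotone curve through per-LET ensemble
# densities, a 68% band from per-track scatter, validity limits, and the
# inverse prediction LET(LCD) with a box-band uncertainty.

#' Track-recognition threshold on linear cluster density
#'
#' A traversal is recognisable as a particle track when it produces at least
#' `n_clusters` separable foci within one nucleus, i.e. a linear density of
#' `n_clusters / diameter`. The conventional choice, three clusters in a
#' 10 um nucleus, gives 0.3/um.
#'
#' @param n_clusters Minimum number of foci per nucleus.
#' @param nucleus_diameter Nucleus diameter, um.
#' @return Threshold linear density, um^-1.
#' @export
#' @examples
#' lcd_detection_threshold()  # 0.3
lcd_detection_threshold <- function(n_clusters = 3, nucleus_diameter = 10) {
  .check_number(n_clusters, "n_clusters", 0, strict = TRUE)
  .check_number(nucleus_diameter, "nucleus_diameter", 0, strict = TRUE)
  n_clusters / nucleus_diameter
}

#' Build a LCD-versus-LET calibration curve
#'
#' At each LET knot the central linear cluster density is the pooled ratio
#' `sum(n_clusters) / sum(eff_len_um)` over the knot's tracks (clusters per
#' um of effective track length); the 68% band is the pointwise 16th/84th
#' percentile of the per-track LCD values. Knot means are made non-decreasing
#' by isotonic regression and joined by a monotone shape-preserving piecewise
#' cubic (Fritsch-Carlson), so the central curve interpolates the isotonized
#' means, never overshoots, and can be inverted.
#'
#' @param densities data.frame from [density_table()]: columns `let`,
#'   `n_clusters`, `eff_len_um`, `lcd` (plus any others).
#' @param d Cluster size the densities were computed at, um.
#' @param min_tracks Minimum tracks per LET knot.
#' @param detection_threshold Linear density required for track recognition,
#'   um^-1; see [lcd_detection_threshold()].
#' @param rel_slope_tol Relative-slope tolerance handed to
#'   [saturation_limit()].
#' @param seed Optional seed recorded as provenance (the build itself is
#'   deterministic given `densities`).
#' @return An object of class `calibration_curve` with fields `d`,
#'   `let_grid`, `mean_lcd` (isotonized knot values), `mean_lcd_raw`,
#'   `band_low`, `band_high`, `let_min_detect`, `let_max_invertible`,
#'   `provenance`.
#' @export
build_calibration <- function(densities, d, min_tracks = 50,
                              detection_threshold = lcd_detection_threshold(),
                              rel_slope_tol = 0.1, seed = NULL) {
  need <- c("let", "n_clusters", "eff_len_um", "lcd")
  miss <- setdiff(need, names(densities))
  if (length(miss))
    .stopf("densities is missing column(s): %s", paste(miss, collapse = ", "))
  .check_number(d, "d", 0)
  grid <- sort(unique(densities$let))
  if (length(grid) < 4L)
    .stopf("degenerate calibration: need >= 4 distinct LET values, got %d",
           length(grid))
  by_let <- split(densities, factor(densities$let, levels = grid))
  n_tracks <- vapply(by_let, nrow, integer(1))
  if (any(n_tracks < min_tracks))
    .stopf("each LET knot needs >= %d tracks (worst knot has %d)",
           min_tracks, min(n_tracks))
  pooled <- vapply(by_let, function(g) ensemble_lcd(g)$lcd, numeric(1))
  band <- vapply(by_let,
                 function(g) quantile(g$lcd, c(0.16, 0.84), names = FALSE),
                 numeric(2))
  iso <- isoreg(grid, pooled)$yf

  curve <- structure(list(
    d = d,
    let_grid = grid,
    mean_lcd = iso,
    mean_lcd_raw = unname(pooled),
    band_low = unname(band[1, ]),
    band_high = unname(band[2, ]),
    detection_threshold = detection_threshold,
    let_min_detect = NA_real_,
    let_max_invertible = NA_real_,
    provenance = list(seed = seed, d = d,
                      n_tracks = unname(n_tracks),
                      package_version = as.character(
                        utils::packageVersion("irifdose")))
  ), class = "calibration_curve")

  curve$let_min_detect <- tryCatch(
    detection_limit(curve, detection_threshold),
    error = function(e) NA_real_)
  curve$let_max_invertible <- tryCatch(
    saturation_limit(curve, rel_slope_tol),
    error = function(e) NA_real_)
  curve
}

.curve_central <- function(curve) {
  splinefun(curve$let_grid, curve$mean_lcd, method = "monoH.FC")
}

#' Evaluate the central calibration curve
#'
#' Monotone interpolation of the isotonized knot means; outside the knot
#' range the curve is held at the boundary values (no extrapolation).
#'
#' @param object A `calibration_curve`.
#' @param let LET values to evaluate at, keV/um.
#' @param ... Unused.
#' @return Central LCD values, um^-1.
#' @export
predict.calibration_curve <- function(object, let, ...) {
  f <- .curve_central(object)
  let <- pmin(pmax(let, object$let_grid[1]),
              object$let_grid[length(object$let_grid)])
  f(let)
}

#' LET detection limit of a calibration curve
#'
#' Smallest LET at which the central curve reaches the track-recognition
#' threshold, by linear interpolation between knots.
#'
#' @param curve A `calibration_curve`.
#' @param threshold Linear density threshold, um^-1.
#' @return LET in keV/um.
#' @export
detection_limit <- function(curve, threshold = lcd_detection_threshold()) {
  stopifnot(inherits(curve, "calibration_curve"))
  .check_number(threshold, "threshold", 0)
  y <- curve$mean_lcd
  x <- curve$let_grid
  if (max(y) < threshold)
    .stopf("central curve never reaches %.3g/um: no detection limit",
           threshold)
  i <- which(y >= threshold)[1]
  if (i == 1L) return(x[1])
  # linear interpolation on the segment that crosses the threshold
  x[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
}

#' Saturation limit of a calibration curve
#'
#' The inverse prediction degrades where the curve flattens. The limit is the
#' largest grid LET up to which the knot-to-knot slope of the central curve
#' is at least `rel_slope_tol` times the initial (low-LET) slope.
#'
#' @param curve A `calibration_curve`.
#' @param rel_slope_tol Fraction of the initial slope below which the curve
#'   counts as flat; 0 returns the upper grid bound.
#' @return LET in keV/um.
#' @export
saturation_limit <- function(curve, rel_slope_tol = 0.1) {
  stopifnot(inherits(curve, "calibration_curve"))
  .check_number(rel_slope_tol, "rel_slope_tol", 0)
  x <- curve$let_grid
  y <- curve$mean_lcd
  s <- diff(y) / diff(x)
  if (s[1] <= 0)
    .stopf("central curve has non-positive initial slope; cannot rate saturation")
  ok <- which(s >= rel_slope_tol * s[1])
  if (!length(ok)) return(x[1])
  x[max(ok) + 1L]
}

#' Estimate LET from a measured linear IRIF density
#'
#' Inverts the central curve by monotone bisection (leftmost crossing,
#' tolerance 1e-3 keV/um). The LET uncertainty is read off the band: the
#' measurement box `[lid - delta_lid, lid + delta_lid]` is intersected with
#' the band envelope and `delta_let` is the half-width of the LET interval
#' where they overlap (clipped to the calibration grid). Status flags:
#' `"below_detection"` when `lid` is under the track-recognition threshold,
#' `"saturated"` when `lid` reaches the curve plateau, otherwise `"ok"`.
#'
#' @param curve A `calibration_curve`.
#' @param lid Measured linear IRIF density, um^-1.
#' @param delta_lid Its uncertainty, um^-1.
#' @param tol Bisection tolerance, keV/um.
#' @return An object of class `let_estimate`: `let`, `delta_let`, `status`.
#' @export
estimate_let <- function(curve, lid, delta_lid = 0, tol = 1e-3) {
  stopifnot(inherits(curve, "calibration_curve"))
  .check_number(lid, "lid", 0)
  .check_number(delta_lid, "delta_lid", 0)
  out <- structure(list(let = NA_real_, delta_let = NA_real_, status = "ok",
                        lid = lid, delta_lid = delta_lid),
                   class = "let_estimate")
  if (lid < curve$detection_threshold) {
    out$status <- "below_detection"
    return(out)
  }
  # lids above the plateau cannot be inverted; a lid exactly at the plateau
  # resolves to the smallest LET attaining it
  plateau <- max(curve$mean_lcd)
  if (lid > plateau) {
    out$status <- "saturated"
    return(out)
  }
  f <- .curve_central(curve)
  lo <- curve$let_grid[1]
  hi <- curve$let_grid[length(curve$let_grid)]
  if (f(lo) >= lid) {
    out$let <- lo
  } else {
    # leftmost L with f(L) >= lid on a non-decreasing curve
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) >= lid) hi <- mid else lo <- mid
    }
    out$let <- hi
  }
  # box-band intersection on a fine grid
  grid <- seq(curve$let_grid[1], curve$let_grid[length(curve$let_grid)],
              length.out = 4001L)
  blo <- approx(curve$let_grid, curve$band_low, grid)$y
  bhi <- approx(curve$let_grid, curve$band_high, grid)$y
  hit <- bhi >= (lid - delta_lid) & blo <= (lid + delta_lid)
  if (any(hit)) {
    rng <- range(grid[hit])
    out$delta_let <- (rng[2] - rng[1]) / 2
  } else {
    out$delta_let <- 0
  }
  out
}

#' @export
print.let_estimate <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<let_estimate> LET = %.4g +/- %.3g keV/um (ok)\n",
                x$let, x$delta_let))
  else
    cat(sprintf("<let_estimate> status: %s (lid = %.3g/um)\n",
                x$status, x$lid))
  invisible(x)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_curve> d = %.3g um, %d knots on LET ",
           "[%.3g, %.3g] keV/um\n  detection limit %.3g, ",
           "saturation limit %.3g keV/um\n"),
    x$d, length(x$let_grid), x$let_grid[1], x$let_grid[length(x$let_grid)],
    x$let_min_detect, x$let_max_invertible))
  invisible(x)
}

#' Simulate ensembles and build a calibration curve in one step
#'
#' Convenience wrapper: [simulate_tracks()] at the given LET knots,
#' [density_table()] at cluster size `d`, then [build_calibration()].
#'
#' @param lets LET knots, keV/um.
#' @param d Cluster size, um.
#' @param n_per_let Tracks per knot.
#' @param nucleus A [nucleus_model()].
#' @param config A [sim_config()].
#' @param seed Integer seed (recorded as provenance).
#' @param ... Passed to [build_calibration()].
#' @return A `calibration_curve`.
#' @export
calibrate_from_simulation <- function(lets, d, n_per_let = NULL,
                                      nucleus = nucleus_model(),
                                      config = sim_config(), seed = NULL,
                                      ...) {
  tracks <- simulate_tracks(lets, n_per_let, nucleus, config, seed)
  dens <- density_table(tracks, d, config$fallback_track_length)
  build_calibration(dens, d, seed = seed, ...)
}

#' Default LET knots for calibration builds
#'
#' Fifteen knots from 2 to 240 keV/um, denser at low LET where the curve
#' rises steeply and the detection limit sits.
#'
#' @return Numeric vector of LET values.
#' @export
default_let_grid <- function() {
  c(2, 4, 6, 8, 12, 16, 24, 36, 50, 70, 95, 125, 160, 200, 240)
}
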