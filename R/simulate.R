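# Track-structure toy simulator: straight ion chords through a spherical
# nucleus, homogeneous Poisson DSB induction along the chord with an
# LET-proportional linear rate, and a small isotropic radial scatter.

#' Nucleus model
#'
#' Geometry of the model cell nucleus and of the circular beam source that
#' illuminates it. The defaults describe a lymphocyte-like spherical nucleus
#' of 10 um diameter containing 6.6 Gbp of DNA, irradiated by a parallel beam
#' started from an 80 um^2 circular source tangential to the nucleus.
#'
#' @param diameter Nucleus diameter in um.
#' @param dna_content DNA content in Gbp (bookkeeping only; the toy generator
#'   does not model chromatin).
#' @param source_area Area of the circular beam source in um^2. Impact points
#'   are uniform on this disc, so a source larger than the nucleus cross
#'   section produces a proportion of tracks that miss the nucleus.
#' @return An object of class `nucleus_model`.
#' @export
#' @examples
#' nucleus_model()
nucleus_model <- function(diameter = 10, dna_content = 6.6, source_area = 80) {
  .check_number(diameter, "diameter", 0, strict = TRUE)
  .check_number(dna_content, "dna_content", 0, strict = TRUE)
  .check_number(source_area, "source_area", 0, strict = TRUE)
  structure(list(diameter = diameter, dna_content = dna_content,
                 source_area = source_area),
            class = "nucleus_model")
}

#' Simulation configuration
#'
#' Parameters of the DSB induction model. The linear DSB density along a track
#' is `lambda(LET) = dsb_yield_coeff * LET` (DSB per um); the default yield
#' coefficient 0.0375 um^-1 per (keV/um) is fixed by the track-recognition
#' convention that a linear density of 0.3/um corresponds to a LET of
#' 8 keV/um. Each DSB is displaced perpendicular to the track axis by an
#' isotropic Gaussian offset of scale `radial_sigma`.
#'
#' @param dsb_yield_coeff DSB yield per um track length per unit LET
#'   (um^-1 / (keV um^-1)).
#' @param radial_sigma Scale (sd per perpendicular component) of the radial
#'   scatter of DSB positions, um.
#' @param fallback_track_length Effective track length assumed for tracks with
#'   at most one DSB, um.
#' @param n_tracks_per_let Default ensemble size per LET value when building
#'   calibration ensembles.
#' @param seed Optional integer seed recorded with simulation output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dsb_yield_coeff = 0.0375, radial_sigma = 0.02,
                       fallback_track_length = 7.6, n_tracks_per_let = 500,
                       seed = NULL) {
  .check_number(dsb_yield_coeff, "dsb_yield_coeff", 0)
  .check_number(radial_sigma, "radial_sigma", 0)
  .check_number(fallback_track_length, "fallback_track_length", 0,
                strict = TRUE)
  .check_number(n_tracks_per_let, "n_tracks_per_let", 1)
  structure(list(dsb_yield_coeff = dsb_yield_coeff,
                 radial_sigma = radial_sigma,
                 fallback_track_length = fallback_track_length,
                 n_tracks_per_let = as.integer(n_tracks_per_let),
                 seed = seed),
            class = "sim_config")
}

#' Track geometry
#'
#' A straight chord through the nucleus: entry point, unit direction and chord
#' length. The beam runs along +x by default; the nucleus center is the
#' coordinate origin.
#'
#' @param entry_point Numeric length-3, um.
#' @param direction Numeric length-3; normalised internally.
#' @param chord_length Chord length in um (0 for tracks that miss the
#'   nucleus).
#' @return An object of class `track_geometry`.
#' @export
track_geometry <- function(entry_point, direction = c(1, 0, 0),
                           chord_length) {
  if (length(entry_point) != 3L || length(direction) != 3L)
    .stopf("entry_point and direction must have length 3")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) .stopf("direction must be non-zero")
  .check_number(chord_length, "chord_length", 0)
  structure(list(entry_point = as.numeric(entry_point),
                 direction = as.numeric(direction) / nrm,
                 chord_length = chord_length),
            class = "track_geometry")
}

#' Sample the entry geometry of one ion
#'
#' Draws an impact point uniformly on the circular source disc (perpendicular
#' to the beam, tangential to the nucleus) and intersects the parallel ray
#' with the spherical nucleus. For impact parameter `b` and nucleus radius
#' `R` the chord length is `2 * sqrt(R^2 - b^2)` when `b < R` and 0 otherwise.
#'
#' @param nucleus A [nucleus_model()].
#' @return A [track_geometry()] with the beam along +x.
#' @export
sample_entry_geometry <- function(nucleus = nucleus_model()) {
  stopifnot(inherits(nucleus, "nucleus_model"))
  r_src <- sqrt(nucleus$source_area / pi)
  # uniform point on the source disc
  u <- runif(1)
  phi <- runif(1, 0, 2 * pi)
  b_y <- r_src * sqrt(u) * cos(phi)
  b_z <- r_src * sqrt(u) * sin(phi)
  chord_from_impact(b_y, b_z, nucleus)
}

#' Chord geometry for a given impact point
#'
#' Deterministic companion of [sample_entry_geometry()]: the chord produced by
#' a parallel ray along +x that passes through `(y, z) = (b_y, b_z)`.
#'
#' @param b_y,b_z Impact coordinates perpendicular to the beam, um.
#' @param nucleus A [nucleus_model()].
#' @return A [track_geometry()].
#' @export
#' @examples
#' chord_from_impact(0, 0)$chord_length   # 10: full diameter
#' chord_from_impact(3, 0)$chord_length   # 8 = 2 * sqrt(25 - 9)
#' chord_from_impact(5, 0)$chord_length   # 0: tangent ray
chord_from_impact <- function(b_y, b_z, nucleus = nucleus_model()) {
  stopifnot(inherits(nucleus, "nucleus_model"))
  R <- nucleus$diameter / 2
  b2 <- b_y^2 + b_z^2
  half <- if (b2 < R^2) sqrt(R^2 - b2) else 0
  track_geometry(entry_point = c(-half, b_y, b_z),
                 direction = c(1, 0, 0),
                 chord_length = 2 * half)
}

#' Simulate DSB positions along one track
#'
#' The DSB count is Poisson with mean `lambda * chord_length`, where
#' `lambda = dsb_yield_coeff * LET`; axial positions are uniform on the chord
#' and each DSB is displaced perpendicular to the track axis by an isotropic
#' Gaussian offset of scale `config$radial_sigma`. Draws come from the
#' current RNG state, so results are reproducible under `set.seed()`.
#'
#' @param geometry A [track_geometry()].
#' @param let LET in keV/um; must be non-negative.
#' @param config A [sim_config()].
#' @param track_id Identifier stored with the record.
#' @return An object of class `ion_track` with fields `track_id`, `let`,
#'   `geometry` and `dsb_coords` (n x 3 matrix, um).
#' @export
simulate_dsb_positions <- function(geometry, let, config = sim_config(),
                                   track_id = 1L) {
  stopifnot(inherits(geometry, "track_geometry"),
            inherits(config, "sim_config"))
  .check_number(let, "let", 0)
  lambda <- config$dsb_yield_coeff * let
  n <- rpois(1L, lambda * geometry$chord_length)
  if (n > 0L) {
    t_ax <- runif(n, 0, geometry$chord_length)
    # orthonormal frame around the track axis
    e1 <- geometry$direction
    ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- ref - sum(ref * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    off2 <- if (config$radial_sigma > 0) rnorm(n, 0, config$radial_sigma)
            else numeric(n)
    off3 <- if (config$radial_sigma > 0) rnorm(n, 0, config$radial_sigma)
            else numeric(n)
    coords <- matrix(geometry$entry_point, nrow = n, ncol = 3L,
                     byrow = TRUE) +
      outer(t_ax, e1) + outer(off2, e2) + outer(off3, e3)
    colnames(coords) <- c("x", "y", "z")
  } else {
    coords <- .as_coord_matrix(NULL)
  }
  structure(list(track_id = track_id, let = let, geometry = geometry,
                 dsb_coords = coords),
            class = "ion_track")
}

#' Simulate an ensemble of ion tracks
#'
#' For each LET value, `n_per_let` tracks are drawn: entry geometry from the
#' source disc, then DSB positions along the chord. One `set.seed()` call at
#' the start makes the whole ensemble reproducible; track draws then consume
#' the RNG stream in a fixed order.
#'
#' @param lets Numeric vector of LET values, keV/um.
#' @param n_per_let Tracks per LET value (default from `config`).
#' @param nucleus A [nucleus_model()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of `ion_track` objects with attribute `seed`.
#' @export
simulate_tracks <- function(lets, n_per_let = NULL,
                            nucleus = nucleus_model(),
                            config = sim_config(), seed = NULL) {
  if (!is.numeric(lets) || length(lets) < 1L || any(lets < 0))
    .stopf("'lets' must be non-negative LET values (keV/um)")
  if (is.null(n_per_let)) n_per_let <- config$n_tracks_per_let
  if (!is.null(seed)) set.seed(seed)
  tracks <- vector("list", length(lets) * n_per_let)
  id <- 0L
  for (let in lets) {
    for (k in seq_len(n_per_let)) {
      id <- id + 1L
      geom <- sample_entry_geometry(nucleus)
      tracks[[id]] <- simulate_dsb_positions(geom, let, config, track_id = id)
    }
  }
  attr(tracks, "seed") <- seed
  attr(tracks, "config") <- config
  tracks
}

#' @export
print.ion_track <- function(x, ...) {
  cat(sprintf("<ion_track #%s> LET %.4g keV/um, chord %.3g um, %d DSB\n",
              x$track_id, x$let, x$geometry$chord_length,
              nrow(x$dsb_coords)))
  invisible(x)
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf(
    "<nucleus_model> diameter %.3g um, %.3g Gbp, source %.3g um^2\n",
    x$diameter, x$dna_content, x$source_area))
  invisible(x)
}
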