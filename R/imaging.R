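# Image-analysis operations of the focus-counting assay: Pearson
# autocorrelation sizing, simplified 3D foci detection, double-positive
# colocalization gating, and the per-track / per-volume IRIF statistics.

#' Pearson autocorrelation of an image patch
#'
#' Shifts a duplicate of the patch over itself by whole pixels and computes
#' the Pearson correlation coefficient of the overlapping regions at each
#' shift. Shifts along the two image axes are averaged (foci are round). By
#' construction `r(0) = 1`.
#'
#' @param patch 2D numeric matrix.
#' @param max_shift Largest pixel shift evaluated.
#' @return data.frame with columns `shift` (pixels) and `r`.
#' @export
pearson_autocorrelation <- function(patch, max_shift) {
  if (!is.matrix(patch) || !is.numeric(patch))
    .stopf("'patch' must be a numeric matrix")
  max_shift <- as.integer(max_shift)
  if (max_shift < 1L || max_shift >= min(dim(patch)))
    .stopf("'max_shift' must be in [1, min(dim(patch)) - 1]")
  if (sd(patch) == 0)
    .stopf("constant patch: autocorrelation is undefined")
  r <- numeric(max_shift + 1L)
  r[1] <- 1
  nr <- nrow(patch)
  nc <- ncol(patch)
  for (s in seq_len(max_shift)) {
    a1 <- patch[seq_len(nr - s), , drop = FALSE]
    b1 <- patch[s + seq_len(nr - s), , drop = FALSE]
    a2 <- patch[, seq_len(nc - s), drop = FALSE]
    b2 <- patch[, s + seq_len(nc - s), drop = FALSE]
    for (m in list(a1, b1, a2, b2))
      if (sd(m) == 0)
        .stopf("constant overlap at shift %d: correlation undefined", s)
    r[s + 1L] <- (cor(as.vector(a1), as.vector(b1)) +
                    cor(as.vector(a2), as.vector(b2))) / 2
  }
  data.frame(shift = 0:max_shift, r = r)
}

#' Focus size from an autocorrelation function
#'
#' Fits `f(x) = exp(-x^2 / (2 sigma^2))` to the ACF samples by least squares.
#' Because the ACF of a Gaussian object is itself Gaussian with a sqrt(2)
#' larger width, the object FWHM is `FWHM_ACF / sqrt(2) = 2 sqrt(ln 2) *
#' sigma_fit`.
#'
#' @param acf data.frame from [pearson_autocorrelation()] (columns `shift`,
#'   `r`), at least 5 samples with an overall decreasing trend.
#' @param pixel_pitch_um Pixel size, um.
#' @return Object of class `size_measurement`: `fwhm_nm` (object size),
#'   `sigma_acf_nm`, `fwhm_acf_nm`, `residual_norm`, `converged`.
#' @export
fwhm_from_acf <- function(acf, pixel_pitch_um = 0.04) {
  if (!all(c("shift", "r") %in% names(acf)))
    .stopf("'acf' needs columns 'shift' and 'r'")
  if (nrow(acf) < 5L) .stopf("need at least 5 ACF samples")
  .check_number(pixel_pitch_um, "pixel_pitch_um", 0, strict = TRUE)
  if (cor(acf$shift, acf$r) >= 0)
    .stopf("ACF has no overall decreasing trend; cannot size the object")
  sse <- function(sigma) sum((exp(-acf$shift^2 / (2 * sigma^2)) - acf$r)^2)
  hi <- 10 * max(acf$shift)
  opt <- optimize(sse, interval = c(1e-3, hi), tol = 1e-10)
  sigma_px <- opt$minimum
  converged <- sigma_px > 2e-3 && sigma_px < hi * 0.99
  if (!converged)
    warning("Gaussian ACF fit did not converge to an interior optimum")
  sigma_nm <- sigma_px * pixel_pitch_um * 1000
  structure(list(fwhm_nm = 2 * sqrt(log(2)) * sigma_nm,
                 sigma_acf_nm = sigma_nm,
                 fwhm_acf_nm = 2 * sqrt(2 * log(2)) * sigma_nm,
                 residual_norm = sqrt(opt$objective),
                 converged = converged),
            class = "size_measurement")
}

#' @export
print.size_measurement <- function(x, ...) {
  cat(sprintf("<size_measurement> object FWHM %.3g nm (ACF sigma %.3g nm)\n",
              x$fwhm_nm, x$sigma_acf_nm))
  invisible(x)
}

#' Measure a focus size in a stack
#'
#' Extracts a maximum-intensity projection over a few z-slices around the
#' focus, computes the radial ACF of the 2D patch and fits it; sizes are
#' measured in 2D sections, as in the assay.
#'
#' @param stack An [image_stack()].
#' @param center_um Focus position (x, y, z), um.
#' @param patch_halfwidth Patch half-width in pixels.
#' @param z_halfwidth Half-depth of the z-projection window, slices.
#' @param max_shift Largest ACF shift, pixels (default `patch_halfwidth`).
#' @return A `size_measurement` (see [fwhm_from_acf()]).
#' @export
measure_focus_size <- function(stack, center_um, patch_halfwidth = 24,
                               z_halfwidth = 2, max_shift = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  center_um <- as.numeric(center_um)
  if (length(center_um) != 3L) .stopf("'center_um' must be length 3")
  d <- dim(stack$data)
  vi <- pmin(pmax(ceiling(center_um / stack$voxel_pitch), 1L), d)
  xr <- max(1L, vi[1] - patch_halfwidth):min(d[1], vi[1] + patch_halfwidth)
  yr <- max(1L, vi[2] - patch_halfwidth):min(d[2], vi[2] + patch_halfwidth)
  zr <- max(1L, vi[3] - z_halfwidth):min(d[3], vi[3] + z_halfwidth)
  mip <- apply(stack$data[xr, yr, zr, drop = FALSE], c(1, 2), max)
  if (is.null(max_shift)) max_shift <- min(patch_halfwidth,
                                           min(dim(mip)) - 1L)
  acf <- pearson_autocorrelation(mip, max_shift)
  fwhm_from_acf(acf, pixel_pitch_um = stack$voxel_pitch[1])
}

# 26-connected neighbour offsets
.neighbour_offsets <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
}

#' Detect foci in a 3D stack
#'
#' Simplified intensity-based spot detection: seeds are 3D local maxima (26
#' neighbourhood) with intensity at least `min_peak` and pairwise physical
#' distance at least `min_separation` (the higher peak wins ties); each focus
#' is then the set of voxels connected to its seed with intensity at least
#' `rel_floor` times the seed intensity, split between competing seeds by
#' nearer-seed assignment. Centroids are intensity-weighted.
#'
#' @param stack An [image_stack()].
#' @param min_peak Minimum seed intensity.
#' @param min_separation Minimum seed separation, um (default 0.14, one PSF
#'   FWHM).
#' @param rel_floor Fraction of the seed intensity down to which voxels are
#'   grown into the focus.
#' @return data.frame with one row per focus: `x_um`, `y_um`, `z_um`,
#'   `peak`, `voxels`. May be empty.
#' @export
count_foci_3d <- function(stack, min_peak, min_separation = 0.14,
                          rel_floor = 0.5) {
  stopifnot(inherits(stack, "image_stack"))
  .check_number(min_peak, "min_peak", 0, strict = TRUE)
  .check_number(min_separation, "min_separation", 0)
  .check_number(rel_floor, "rel_floor", 0, strict = TRUE)
  A <- stack$data
  d <- dim(A)
  pitch <- stack$voxel_pitch
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), peak = numeric(0),
                      voxels = integer(0))

  # local maxima: pad with -Inf so borders compare correctly
  pad <- array(-Inf, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- A
  ismax <- A >= min_peak
  offs <- .neighbour_offsets()
  for (o in seq_len(26)) {
    off <- offs[o, ]
    nb <- pad[2:(d[1] + 1L) + off[1], 2:(d[2] + 1L) + off[2],
              2:(d[3] + 1L) + off[3], drop = FALSE]
    dim(nb) <- d
    ismax <- ismax & (A >= nb)
    if (!any(ismax)) return(empty)
  }
  idx <- which(ismax)
  ij <- arrayInd(idx, d)
  peaks <- A[idx]
  ord <- order(peaks, decreasing = TRUE)
  pos <- (ij - 0.5) * matrix(pitch, nrow(ij), 3, byrow = TRUE)

  # greedy non-maximum suppression at min_separation
  keep <- integer(0)
  for (i in ord) {
    if (length(keep)) {
      dd <- sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2))
      if (any(dd < min_separation)) next
    }
    keep <- c(keep, i)
  }
  seeds <- ij[keep, , drop = FALSE]
  seed_pos <- pos[keep, , drop = FALSE]
  seed_peak <- peaks[keep]
  ns <- length(keep)

  # candidate voxels: above the lowest floor of any seed
  floors <- rel_floor * seed_peak
  cand <- which(A >= min(floors))
  cij <- arrayInd(cand, d)
  cpos <- (cij - 0.5) * matrix(pitch, nrow(cij), 3, byrow = TRUE)
  # nearest seed per candidate voxel
  nearest <- integer(length(cand))
  bestd <- rep(Inf, length(cand))
  for (s in seq_len(ns)) {
    ds <- (cpos[, 1] - seed_pos[s, 1])^2 + (cpos[, 2] - seed_pos[s, 2])^2 +
      (cpos[, 3] - seed_pos[s, 3])^2
    upd <- ds < bestd
    bestd[upd] <- ds[upd]
    nearest[upd] <- s
  }
  zone <- array(0L, dim = d)
  zone[cand] <- nearest

  res <- vector("list", ns)
  for (s in seq_len(ns)) {
    # BFS from the seed through its zone, down to its own floor
    member <- matrix(seeds[s, ], ncol = 3)
    visited <- new.env(hash = TRUE, parent = emptyenv())
    assign(paste(seeds[s, ], collapse = ","), TRUE, envir = visited)
    frontier <- member
    while (nrow(frontier)) {
      nxt <- list()
      for (f in seq_len(nrow(frontier))) {
        nb <- sweep(offs, 2, frontier[f, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        for (q in seq_len(nrow(nb))) {
          key <- paste(nb[q, ], collapse = ",")
          if (exists(key, envir = visited, inherits = FALSE)) next
          assign(key, TRUE, envir = visited)
          if (zone[nb[q, 1], nb[q, 2], nb[q, 3]] == s &&
              A[nb[q, 1], nb[q, 2], nb[q, 3]] >= floors[s])
            nxt[[length(nxt) + 1L]] <- nb[q, ]
        }
      }
      frontier <- if (length(nxt)) do.call(rbind, nxt)
                  else matrix(numeric(0), ncol = 3)
      if (nrow(frontier)) member <- rbind(member, frontier)
    }
    w <- A[member]
    cen <- colSums((member - 0.5) * matrix(pitch, nrow(member), 3,
                                           byrow = TRUE) * w) / sum(w)
    res[[s]] <- data.frame(x_um = cen[1], y_um = cen[2], z_um = cen[3],
                           peak = seed_peak[s], voxels = nrow(member))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Double-positive colocalization gate
#'
#' Keeps the detections in `foci_a` whose centroid lies within `radius` of
#' some detection in `foci_b` (counting only foci in the double-positive
#' region). The default radius, 0.3 um, is half the large-marker focus size.
#'
#' @param foci_a,foci_b data.frames with columns `x_um`, `y_um`, `z_um`.
#' @param radius Gating radius, um.
#' @return The gated subset of `foci_a`.
#' @export
colocalization_filter <- function(foci_a, foci_b, radius = 0.3) {
  .check_number(radius, "radius", 0)
  if (nrow(foci_a) == 0L || nrow(foci_b) == 0L)
    return(foci_a[integer(0), , drop = FALSE])
  pa <- as.matrix(foci_a[, c("x_um", "y_um", "z_um")])
  pb <- as.matrix(foci_b[, c("x_um", "y_um", "z_um")])
  keep <- vapply(seq_len(nrow(pa)), function(i) {
    min(sqrt(colSums((t(pb) - pa[i, ])^2))) <= radius
  }, logical(1))
  foci_a[keep, , drop = FALSE]
}

#' Per-track IRIF statistics
#'
#' Track length is the distance between the two extreme foci projected on the
#' track axis (measured from first to last signal); a single focus cannot
#' span a length, so the conventional 7.6 um mean track length is used. An
#' optional `1/cos(tilt)` correction for a beam tilted out of the imaging
#' plane is available but off by default.
#'
#' @param foci data.frame of detections along one track (`x_um`, `y_um`,
#'   `z_um`); at least one row.
#' @param axis Track direction (length-3; normalised internally).
#' @param fallback Track length assumed for a single focus, um.
#' @param tilt_correction Divide the projected length by `cos(tilt_deg)`?
#' @param tilt_deg Beam tilt out of the imaging plane, degrees.
#' @return list with `n_foci`, `track_length_um`, `lid` (foci per um).
#' @export
track_irif_stats <- function(foci, axis = c(1, 0, 0), fallback = 7.6,
                             tilt_correction = FALSE, tilt_deg = 9) {
  if (nrow(foci) == 0L) .stopf("no foci: track statistics undefined")
  .check_number(fallback, "fallback", 0, strict = TRUE)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.matrix(foci[, c("x_um", "y_um", "z_um")]) %*% axis
  len <- if (nrow(foci) >= 2L) max(proj) - min(proj) else fallback
  if (nrow(foci) >= 2L && tilt_correction)
    len <- len / cos(tilt_deg * pi / 180)
  list(n_foci = nrow(foci), track_length_um = len,
       lid = nrow(foci) / len)
}

#' IRIF density per nuclear volume
#'
#' Number of foci in a nucleus divided by the nuclear volume; densities are
#' computed per cell and then averaged across cells (not a ratio of means),
#' which is robust to the large cell-to-cell volume variation.
#'
#' @param n_foci Focus count(s).
#' @param nucleus_volume Nuclear volume(s), um^3.
#' @return Density in um^-3 (vectorised).
#' @export
#' @examples
#' irif_density_per_volume(30, 1000)  # 0.03
irif_density_per_volume <- function(n_foci, nucleus_volume) {
  if (any(nucleus_volume <= 0)) .stopf("nuclear volume must be positive")
  if (any(n_foci < 0)) .stopf("focus counts must be non-negative")
  n_foci / nucleus_volume
}

#' Nuclear volume from a bounding box
#'
#' Length x width x height, the box-product volume measured in the assay;
#' note this overestimates an ellipsoidal nucleus by a factor pi/6.
#'
#' @param length_um,width_um,height_um Box sides, um.
#' @return Volume in um^3.
#' @export
nuclear_box_volume <- function(length_um, width_um, height_um) {
  if (any(c(length_um, width_um, height_um) <= 0))
    .stopf("box sides must be positive")
  length_um * width_um * height_um
}

#' Reference gamma-ray focus densities
#'
#' Bundled reference table of IRIF counts and per-volume densities measured
#' in HeLa cells after 60Co gamma irradiation at 1.9 and 3.0 Gy (two damage
#' markers, four fixation times, standard errors of the mean).
#'
#' @return data.frame with columns `dose_gy`, `time_min`, `marker`,
#'   `irif_per_cell`, `irif_per_cell_se`, `irif_per_um3`, `irif_per_um3_se`,
#'   `volume_um3`, `volume_se`, `n_cells`.
#' @export
gamma_reference_densities <- function() {
  path <- system.file("extdata", "gamma_irif_reference.csv",
                      package = "irifdose", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Early-time mean IRIF density for one dose
#'
#' Averages the per-volume focus density over the early fixation times
#' (3, 5 and 10 min by default), the window in which the density reflects
#' unprocessed radiation-induced damage.
#'
#' @param table data.frame as returned by [gamma_reference_densities()].
#' @param dose_gy Dose to select.
#' @param marker Marker to select.
#' @param times Fixation times (min) to average over.
#' @return Mean density, um^-3.
#' @export
average_early_density <- function(table = gamma_reference_densities(),
                                  dose_gy, marker = "pDNA-PKcs",
                                  times = c(3, 5, 10)) {
  sel <- table$dose_gy == dose_gy & table$marker == marker &
    table$time_min %in% times
  if (!any(sel)) .stopf("no rows for dose %.3g Gy / marker '%s'",
                        dose_gy, marker)
  mean(table$irif_per_um3[sel])
}
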