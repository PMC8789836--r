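# Synthetic STED-like stack rendering: each focus becomes a 3D Gaussian blob
# at the configured lateral/axial FWHM, on a constant background, with
# optional Poisson shot noise. Fixture generator for the imaging module.

.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Image stack container
#'
#' A 3D voxel grid with physical voxel pitch. The array is indexed
#' `[i, j, k]` for (x, y, z); voxel `i` is centered at `(i - 0.5) * pitch_x`
#' um, and likewise for y and z.
#'
#' @param data Numeric 3D array of non-negative intensities.
#' @param voxel_pitch Length-3 pitch (x, y, z) in um; default the 40 x 40 x
#'   160 nm sampling of the STED stacks this emulates.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_pitch = c(0.04, 0.04, 0.16)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    .stopf("'data' must be a 3D array")
  if (length(voxel_pitch) != 3L || any(voxel_pitch <= 0))
    .stopf("'voxel_pitch' must be three positive lengths (um)")
  if (any(data < 0)) .stopf("intensities must be non-negative")
  structure(list(data = data, voxel_pitch = as.numeric(voxel_pitch)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels at %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3]))
  invisible(x)
}

#' Rendering configuration for synthetic foci stacks
#'
#' @param voxel_pitch Voxel pitch (x, y, z), um.
#' @param lateral_fwhm,axial_fwhm Blob FWHM in the focal plane and along the
#'   optical axis, um (defaults: the ~140 nm small-focus size laterally and
#'   the 200 nm axial resolution).
#' @param peak_intensity Peak counts added by one focus.
#' @param background Constant background counts.
#' @param poisson_noise Apply Poisson shot noise to the final expectation?
#' @param seed Optional seed for the noise draw.
#' @return Object of class `foci_render_config`.
#' @export
foci_render_config <- function(voxel_pitch = c(0.04, 0.04, 0.16),
                               lateral_fwhm = 0.14, axial_fwhm = 0.20,
                               peak_intensity = 1000, background = 10,
                               poisson_noise = FALSE, seed = NULL) {
  if (length(voxel_pitch) != 3L || any(voxel_pitch <= 0))
    .stopf("'voxel_pitch' must be three positive lengths (um)")
  .check_number(lateral_fwhm, "lateral_fwhm", 0, strict = TRUE)
  .check_number(axial_fwhm, "axial_fwhm", 0, strict = TRUE)
  .check_number(peak_intensity, "peak_intensity", 0)
  .check_number(background, "background", 0)
  structure(list(voxel_pitch = as.numeric(voxel_pitch),
                 lateral_fwhm = lateral_fwhm, axial_fwhm = axial_fwhm,
                 peak_intensity = peak_intensity, background = background,
                 poisson_noise = isTRUE(poisson_noise), seed = seed),
            class = "foci_render_config")
}

#' Render a synthetic foci stack
#'
#' Adds one separable 3D Gaussian blob per center (sampled at voxel centers)
#' to a constant background; Poisson noise, if enabled, is applied last to
#' the summed expectation.
#'
#' @param centers n x 3 matrix of focus centers, um (may be empty).
#' @param cfg A [foci_render_config()].
#' @param dim Stack dimensions in voxels (nx, ny, nz).
#' @return An [image_stack()].
#' @export
render_foci_stack <- function(centers, cfg = foci_render_config(),
                              dim = c(64, 64, 16)) {
  stopifnot(inherits(cfg, "foci_render_config"))
  centers <- .as_coord_matrix(centers)
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) .stopf("'dim' must be 3 positive sizes")
  extent <- dim * cfg$voxel_pitch
  if (nrow(centers) > 0L &&
      (any(centers < 0) || any(centers > matrix(extent, nrow(centers), 3,
                                                byrow = TRUE))))
    .stopf("all centers must lie inside the stack extent (%.3g x %.3g x %.3g um)",
           extent[1], extent[2], extent[3])
  sig <- c(cfg$lateral_fwhm, cfg$lateral_fwhm, cfg$axial_fwhm) *
    .FWHM_TO_SIGMA
  ax <- lapply(1:3, function(a) (seq_len(dim[a]) - 0.5) * cfg$voxel_pitch[a])
  img <- array(cfg$background, dim = dim)
  for (i in seq_len(nrow(centers))) {
    prof <- lapply(1:3, function(a) {
      g <- exp(-(ax[[a]] - centers[i, a])^2 / (2 * sig[a]^2))
      g[g < 1e-8] <- 0
      g
    })
    nz <- lapply(prof, function(g) which(g > 0))
    if (any(vapply(nz, length, integer(1)) == 0L)) next
    blob <- cfg$peak_intensity *
      outer(outer(prof[[1]][nz[[1]]], prof[[2]][nz[[2]]]), prof[[3]][nz[[3]]])
    img[nz[[1]], nz[[2]], nz[[3]]] <- img[nz[[1]], nz[[2]], nz[[3]]] + blob
  }
  if (cfg$poisson_noise) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    img <- array(rpois(length(img), img), dim = dim)
  }
  image_stack(img, cfg$voxel_pitch)
}
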