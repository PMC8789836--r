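# Finite-size clustering of DSB positions: the simulation counterpart of a
# measured IRIF. Two DSBs belong to the same cluster whenever they can be
# linked by a chain of steps each no longer than the focus size d, i.e.
# clusters are the connected components of the <= d proximity graph
# (single linkage at a fixed cut distance).

#' Cluster DSB coordinates at a finite focus size
#'
#' Groups 3D points into clusters such that every point is within `d` of at
#' least one other member of its cluster (chaining: clusters are connected
#' components of the graph joining all pairs at distance `<= d`; ties at
#' exactly `d` merge). Cluster labels are deterministic, ordered by the
#' smallest member index.
#'
#' @param coords n x 3 numeric matrix of positions (um), or an `ion_track`.
#' @param d Cluster (focus) size in um; 0.14 for the small DNA-PKcs-type
#'   focus, 0.6 for the large 53BP1-type focus.
#' @param members Also return the per-cluster member coordinate lists?
#'   Skipping them (`FALSE`) is much cheaper on very large point sets where
#'   only counts, assignments and centroids are needed.
#' @return An object of class `cluster_set`: `d`, `assignments` (integer per
#'   point), `clusters` (list of member coordinate matrices, or `NULL` when
#'   `members = FALSE`), `centroids` (k x 3 matrix of member means),
#'   `n_clusters`.
#' @export
#' @examples
#' pts <- cbind(c(0, 0.13, 0.26), 0, 0)
#' cluster_dsbs(pts, 0.14)$n_clusters  # 1: chaining merges the end points
cluster_dsbs <- function(coords, d, members = TRUE) {
  if (inherits(coords, "ion_track")) coords <- coords$dsb_coords
  coords <- .as_coord_matrix(coords)
  .check_number(d, "d", 0)
  n <- nrow(coords)
  if (n == 0L) {
    return(structure(list(d = d, assignments = integer(0),
                          clusters = list(),
                          centroids = .as_coord_matrix(NULL),
                          n_clusters = 0L),
                     class = "cluster_set"))
  }
  labels <- .sl_cluster_labels(coords, d)
  k <- max(labels)
  sizes <- tabulate(labels, k)
  centroids <- rowsum(coords, labels, reorder = TRUE) / sizes
  colnames(centroids) <- c("x", "y", "z")
  clusters <- if (members) {
    idx <- split(seq_len(n), labels)
    lapply(idx, function(i) coords[i, , drop = FALSE])
  }
  structure(list(d = d, assignments = labels, clusters = clusters,
                 centroids = centroids, n_clusters = k),
            class = "cluster_set")
}

#' Effective track length
#'
#' The separation distance between the farthermost DSB pair of a track. For
#' tracks with at most one DSB this span is undefined and a fixed mean track
#' length (7.6 um by default) is assumed instead.
#'
#' @param coords n x 3 coordinate matrix (um) or an `ion_track`.
#' @param fallback Length assumed for tracks with fewer than two DSBs, um.
#' @return Length in um.
#' @export
#' @examples
#' effective_track_length(cbind(c(0, 2, 5), 0, 0))  # 5
#' effective_track_length(cbind(1, 1, 1))           # 7.6
effective_track_length <- function(coords, fallback = 7.6) {
  if (inherits(coords, "ion_track")) coords <- coords$dsb_coords
  coords <- .as_coord_matrix(coords)
  .check_number(fallback, "fallback", 0, strict = TRUE)
  if (nrow(coords) < 2L) return(fallback)
  .point_set_diameter(coords)
}

#' Per-track linear densities
#'
#' Linear DSB density (LDD) and linear cluster density (LCD) of one track:
#' counts divided by the effective track length.
#'
#' @param track An `ion_track`, or an n x 3 coordinate matrix.
#' @param d Cluster size in um.
#' @param fallback Effective length for tracks with fewer than two DSBs, um.
#' @return An object of class `track_densities` (also a one-row data.frame)
#'   with columns `track_id`, `let`, `n_dsb`, `n_clusters`, `eff_len_um`,
#'   `ldd`, `lcd`.
#' @export
#' @examples
#' td <- track_densities(cbind(c(0, 0.1, 1.0, 1.1), 0, 0), d = 0.14)
#' td$n_clusters  # 2
#' td$lcd         # 2 / 1.1
track_densities <- function(track, d, fallback = 7.6) {
  if (inherits(track, "ion_track")) {
    coords <- track$dsb_coords
    track_id <- track$track_id
    let <- track$let
  } else {
    coords <- .as_coord_matrix(track)
    track_id <- NA_integer_
    let <- NA_real_
  }
  n_dsb <- nrow(coords)
  cs <- cluster_dsbs(coords, d, members = FALSE)
  len <- effective_track_length(coords, fallback)
  out <- data.frame(track_id = track_id, let = let, n_dsb = n_dsb,
                    n_clusters = cs$n_clusters, eff_len_um = len,
                    ldd = n_dsb / len, lcd = cs$n_clusters / len)
  class(out) <- c("track_densities", "data.frame")
  out
}

#' Density table for a track ensemble
#'
#' Applies [track_densities()] to every track and binds the rows; this is the
#' input format of [build_calibration()].
#'
#' @param tracks List of `ion_track` objects (e.g. from [simulate_tracks()]).
#' @param d Cluster size, um.
#' @param fallback Fallback effective length, um.
#' @return data.frame with one row per track.
#' @export
density_table <- function(tracks, d, fallback = 7.6) {
  .check_number(d, "d", 0)
  .check_number(fallback, "fallback", 0, strict = TRUE)
  n <- length(tracks)
  track_id <- let <- n_dsb <- n_clusters <- eff_len <- numeric(n)
  for (i in seq_len(n)) {
    tr <- tracks[[i]]
    coords <- if (inherits(tr, "ion_track")) tr$dsb_coords else
      .as_coord_matrix(tr)
    track_id[i] <- if (inherits(tr, "ion_track")) tr$track_id else i
    let[i] <- if (inherits(tr, "ion_track")) tr$let else NA_real_
    n_dsb[i] <- nrow(coords)
    n_clusters[i] <- if (n_dsb[i] > 0L)
      max(.sl_cluster_labels(coords, d)) else 0L
    eff_len[i] <- if (n_dsb[i] >= 2L) .point_set_diameter(coords)
                  else fallback
  }
  data.frame(track_id = track_id, let = let, n_dsb = n_dsb,
             n_clusters = n_clusters, eff_len_um = eff_len,
             ldd = n_dsb / eff_len, lcd = n_clusters / eff_len)
}

#' Ensemble linear cluster density
#'
#' Pooled linear cluster density of a track ensemble: total clusters divided
#' by total effective track length (clusters per um of track), with a
#' ratio-estimator standard error. This is the ensemble summary used for the
#' calibration central curve and for measured ensembles fed into LET
#' estimation; unlike the mean of per-track ratios it is not dominated by
#' rare short-span tracks.
#'
#' @param densities data.frame from [density_table()] (columns `n_clusters`,
#'   `eff_len_um`).
#' @return list with `lcd` (um^-1), `se` and `n_tracks`.
#' @export
ensemble_lcd <- function(densities) {
  if (!all(c("n_clusters", "eff_len_um") %in% names(densities)))
    .stopf("densities needs columns 'n_clusters' and 'eff_len_um'")
  n <- nrow(densities)
  if (n == 0L) .stopf("empty ensemble")
  r <- sum(densities$n_clusters) / sum(densities$eff_len_um)
  se <- if (n > 1L)
    sqrt(sum((densities$n_clusters - r * densities$eff_len_um)^2) /
           (n - 1) / n) / mean(densities$eff_len_um)
  else NA_real_
  list(lcd = r, se = se, n_tracks = n)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> d = %.3g um: %d point(s) in %d cluster(s)\n",
              x$d, length(x$assignments), x$n_clusters))
  invisible(x)
}
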