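# Readers/writers for the package's exchange formats: track tables (CSV),
# calibration curves (JSON with a schema version), per-track density tables,
# and multi-page TIFF stacks with a voxel-pitch sidecar.

.TRACK_COLUMNS <- c("track_id", "let_kev_um", "dsb_index",
                    "x_um", "y_um", "z_um")
.CALIBRATION_SCHEMA <- "irifdose-calibration-1"

#' Write ion tracks to CSV
#'
#' One row per DSB (tracks with zero DSBs keep a row with NA coordinates so
#' that the ensemble composition round-trips). Header, '.' decimal, UTF-8;
#' coordinates carry full double precision.
#'
#' @param tracks List of `ion_track` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    n <- nrow(tr$dsb_coords)
    if (n == 0L)
      data.frame(track_id = tr$track_id, let_kev_um = tr$let,
                 dsb_index = NA_integer_, x_um = NA_real_, y_um = NA_real_,
                 z_um = NA_real_)
    else
      data.frame(track_id = tr$track_id, let_kev_um = tr$let,
                 dsb_index = seq_len(n), x_um = tr$dsb_coords[, 1],
                 y_um = tr$dsb_coords[, 2], z_um = tr$dsb_coords[, 3])
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else setNames(as.data.frame(matrix(numeric(0), ncol = 6L)),
                      .TRACK_COLUMNS)
  num <- c("let_kev_um", "x_um", "y_um", "z_um")
  for (cn in num)
    df[[cn]] <- ifelse(is.na(df[[cn]]), NA_character_,
                       sprintf("%.17g", df[[cn]]))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read ion tracks from CSV
#'
#' Inverse of [write_tracks()]. The schema is validated; a missing or
#' non-numeric column raises an error naming the offending column. Track
#' geometry is not stored in the table, so reread tracks carry a minimal
#' geometry reconstructed from the DSB span.
#'
#' @param path CSV file with columns `track_id, let_kev_um, dsb_index, x_um,
#'   y_um, z_um`.
#' @return List of `ion_track` objects.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (cn in .TRACK_COLUMNS) {
    if (!cn %in% names(df))
      .stopf("track table '%s' is missing column '%s'", path, cn)
    if (cn != "track_id" && !is.numeric(df[[cn]]) &&
        !all(is.na(df[[cn]])))
      .stopf("column '%s' in '%s' is not numeric", cn, path)
  }
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    g <- df[df$track_id == id, , drop = FALSE]
    coords <- as.matrix(g[!is.na(g$dsb_index), c("x_um", "y_um", "z_um"),
                          drop = FALSE])
    colnames(coords) <- c("x", "y", "z")
    span <- if (nrow(coords) >= 2L) .point_set_diameter(coords) else 0
    entry <- if (nrow(coords)) coords[1, ] else c(0, 0, 0)
    structure(list(track_id = id, let = g$let_kev_um[1],
                   geometry = track_geometry(entry, c(1, 0, 0), span),
                   dsb_coords = coords),
              class = "ion_track")
  })
}

#' Write per-track densities to CSV
#'
#' @param densities data.frame from [density_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(densities, path) {
  write.csv(densities, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Persist a calibration curve as JSON
#'
#' The file carries a schema-version tag, the knot grid, central and band
#' values, validity limits and provenance, with full numeric precision so
#' that curve evaluations are identical after a round trip.
#'
#' @param curve A `calibration_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  payload <- list(schema = .CALIBRATION_SCHEMA,
                  d = curve$d,
                  let_grid = curve$let_grid,
                  mean_lcd = curve$mean_lcd,
                  mean_lcd_raw = curve$mean_lcd_raw,
                  band_low = curve$band_low,
                  band_high = curve$band_high,
                  detection_threshold = curve$detection_threshold,
                  let_min_detect = curve$let_min_detect,
                  let_max_invertible = curve$let_max_invertible,
                  provenance = curve$provenance)
  # 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' Errors on a schema-version mismatch or a truncated/invalid file (no
#' partial curve is returned); unknown extra keys are ignored with a
#' warning.
#'
#' @param path JSON file written by [write_calibration()].
#' @return A `calibration_curve`.
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema) || !identical(payload$schema,
                                            .CALIBRATION_SCHEMA))
    .stopf("calibration schema mismatch in '%s': expected '%s', found '%s'",
           path, .CALIBRATION_SCHEMA,
           if (is.null(payload$schema)) "<none>" else payload$schema)
  known <- c("schema", "d", "let_grid", "mean_lcd", "mean_lcd_raw",
             "band_low", "band_high", "detection_threshold",
             "let_min_detect", "let_max_invertible", "provenance")
  extra <- setdiff(names(payload), known)
  if (length(extra))
    warning(sprintf("ignoring unknown calibration key(s): %s",
                    paste(extra, collapse = ", ")))
  need <- setdiff(known, c("schema", "mean_lcd_raw", "provenance"))
  miss <- setdiff(need, names(payload))
  if (length(miss))
    .stopf("calibration file '%s' is missing field(s): %s", path,
           paste(miss, collapse = ", "))
  structure(list(d = payload$d,
                 let_grid = as.numeric(payload$let_grid),
                 mean_lcd = as.numeric(payload$mean_lcd),
                 mean_lcd_raw = as.numeric(payload$mean_lcd_raw),
                 band_low = as.numeric(payload$band_low),
                 band_high = as.numeric(payload$band_high),
                 detection_threshold = payload$detection_threshold,
                 let_min_detect = .null_as_na(payload$let_min_detect),
                 let_max_invertible = .null_as_na(payload$let_max_invertible),
                 provenance = payload$provenance),
            class = "calibration_curve")
}

.null_as_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Write an image stack as multi-page TIFF
#'
#' One 16-bit page per z-slice (intensities clipped to `[0, 65535]`); the
#' voxel pitch goes to a JSON sidecar `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF file.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- t(stack$data[, , k])        # rows = y, cols = x
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535                        # tiff writes [0,1] at 16 bits
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(schema = "irifdose-stack-1",
                            voxel_pitch_um = stack$voxel_pitch),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file (8 or 16 bit); if a `<path>.json` sidecar exists its
#'   voxel pitch is used.
#' @param voxel_pitch Pitch override, um.
#' @return An [image_stack()] with intensities on the original integer scale.
#' @export
read_tiff_stack <- function(path, voxel_pitch = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]]) * 65535
  arr <- round(arr)
  if (is.null(voxel_pitch)) {
    sidecar <- paste0(path, ".json")
    voxel_pitch <- if (file.exists(sidecar))
      as.numeric(jsonlite::read_json(sidecar,
                                     simplifyVector = TRUE)$voxel_pitch_um)
    else c(0.04, 0.04, 0.16)
  }
  image_stack(arr, voxel_pitch)
}
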