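## File formats: multi-page TIFF + JSON sidecar for movies, long-format CSV
## for profiles, CSV for quantification tables.

TIFF_SCALE <- 65535

#' Write a FRAP movie as multi-page TIFF plus JSON sidecar
#'
#' Frames are rounded to integer counts and stored as 16-bit TIFF pages;
#' calibration, frame times, bleach events, centrosome positions, seed and
#' simulator/optics parameters go to `<prefix>.json`.
#'
#' @param movie A `"frap_movie"`.
#' @param prefix Output path prefix (writes `<prefix>.tif` and
#'   `<prefix>.json`).
#' @return The two file paths, invisibly.
#' @export
write_frap_movie <- function(movie, prefix) {
  if (!inherits(movie, "frap_movie"))
    pcm_stop("invalid_argument", "'movie' must be a frap_movie")
  tif <- paste0(prefix, ".tif")
  sidecar <- paste0(prefix, ".json")
  pages <- lapply(movie$frames, function(fr)
    pmin(pmax(round(fr), 0), TIFF_SCALE) / TIFF_SCALE)
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L, compression = "none")
  meta <- list(
    pixel_size_um = movie$pixel_size,
    frame_times_s = movie$times,
    intensity_scale = TIFF_SCALE,
    bleach_events = lapply(movie$bleaches, unclass),
    positions_um = unname(apply(movie$positions, 1, as.numeric,
                                simplify = FALSE)),
    seed = movie$seed,
    optics = if (!is.null(movie$optics)) unclass(movie$optics))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(tif, sidecar))
}

#' Read a FRAP movie written by [write_frap_movie()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `"frap_movie"` with integer-count frames.
#' @export
read_frap_movie <- function(prefix) {
  tif <- paste0(prefix, ".tif")
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(tif) || !file.exists(sidecar))
    pcm_stop("missing_file", "missing %s or %s", tif, sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (is.null(meta$pixel_size_um) || is.null(meta$frame_times_s))
    pcm_stop("config_error", "malformed sidecar %s", sidecar)
  pages <- tiff::readTIFF(tif, all = TRUE)
  frames <- lapply(pages, function(p) round(p * meta$intensity_scale))
  bleaches <- lapply(meta$bleach_events, function(ev)
    bleach_event(ev$time, unlist(ev$center), ev$radius, ev$efficiency))
  pos <- matrix(unlist(meta$positions_um), ncol = 2, byrow = TRUE)
  optics <- if (!is.null(meta$optics))
    do.call(optics_params, meta$optics) else NULL
  structure(list(frames = frames, times = meta$frame_times_s,
                 pixel_size = meta$pixel_size_um, positions = pos,
                 bleaches = bleaches, optics = optics,
                 seed = meta$seed),
            class = "frap_movie")
}

#' Write a profile set as long-format CSV
#'
#' One row per (time point, ring): `time_s`, `radius_um`, `value`,
#' `n_subpixels`, plus flag columns.
#'
#' @param profiles A `"profile_set"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profiles, path) {
  if (!inherits(profiles, "profile_set"))
    pcm_stop("invalid_argument", "'profiles' must be a profile_set")
  rows <- do.call(rbind, lapply(seq_along(profiles$times), function(i) {
    p <- profiles$profiles[[i]]
    data.frame(time_s = profiles$times[i], radius_um = p$radii,
               value = p$values, n_subpixels = p$n_subpixels,
               background_subtracted = p$flags$background_subtracted,
               normalized = p$flags$normalized,
               mirrored = p$flags$mirrored)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write or read a per-centrosome quantification table
#'
#' @param table Data frame as produced by [simulate_fixed_cell_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_cellquant_csv <- function(table, path) {
  need <- c("centrosome_id", "brain_id", "genotype", "phase", "marker",
            "intensity")
  if (!all(need %in% names(table)))
    pcm_stop("missing_column", "table needs columns %s",
             paste(setdiff(need, names(table)), collapse = ", "))
  write.csv(table[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cellquant_csv
#' @export
read_cellquant_csv <- function(path) {
  if (!file.exists(path))
    pcm_stop("missing_file", "no such file: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("brain_id", "genotype", "phase", "intensity")
  if (!all(need %in% names(tab)))
    pcm_stop("missing_column", "%s lacks columns %s", path,
             paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}
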