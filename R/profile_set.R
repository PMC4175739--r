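## From movies to averaged per-time radial profiles.

#' Options controlling movie profiling
#'
#' @param upsample Integer pixel-splitting factor (default 5).
#' @param threshold_frac Centre-detection threshold fraction.
#' @param bg_annulus Background-estimation annulus `c(inner, outer)` in um
#'   around each centrosome. Must lie outside the centrosomal signal; the
#'   default suits the simulator's 1.2 um PCM.
#' @param crop_halfwidth Half-width of the per-centrosome crop, um; must
#'   accommodate the profiling grid and the background annulus.
#' @param min_n Minimum number of centrosomes averaged per time point.
#' @param normalize_first Normalize each centrosome's profiles by its own
#'   pre-bleach peak before averaging (`TRUE`, default) or average raw
#'   background-subtracted profiles and normalize afterwards.
#' @return A list of class `"profiling_options"`.
#' @export
profiling_options <- function(upsample = 5L, threshold_frac = 0.5,
                              bg_annulus = c(2.0, 2.8),
                              crop_halfwidth = 3.1, min_n = 10L,
                              normalize_first = TRUE) {
  if (length(bg_annulus) != 2L || bg_annulus[1] >= bg_annulus[2])
    pcm_stop("invalid_argument", "'bg_annulus' must be c(inner, outer)")
  structure(list(upsample = as.integer(upsample),
                 threshold_frac = threshold_frac,
                 bg_annulus = as.numeric(bg_annulus),
                 crop_halfwidth = crop_halfwidth,
                 min_n = as.integer(min_n),
                 normalize_first = isTRUE(normalize_first)),
            class = "profiling_options")
}

## crop a square window (um) around a position from a frame matrix
crop_window <- function(frame, pixel_size, center, halfwidth) {
  px <- pixel_size
  c0 <- max(1L, floor((center[1] - halfwidth) / px) + 1L)
  c1 <- min(ncol(frame), ceiling((center[1] + halfwidth) / px))
  r0 <- max(1L, floor((center[2] - halfwidth) / px) + 1L)
  r1 <- min(nrow(frame), ceiling((center[2] + halfwidth) / px))
  list(pixels = frame[r0:r1, c0:c1, drop = FALSE],
       offset = c((c0 - 1L) * px, (r0 - 1L) * px))
}

## profile one centrosome in one frame: upsample, centre, ring-average,
## estimate + subtract the cytosolic background
profile_one <- function(frame, pixel_size, position, grid, opts) {
  cw <- crop_window(frame, pixel_size, position, opts$crop_halfwidth)
  img <- image_stack(cw$pixels, pixel_size)
  bg0 <- median(cw$pixels)              # coarse level for thresholding
  up <- upsample_image(img, opts$upsample)
  ctr <- find_center(up, opts$threshold_frac, background = bg0)
  bg <- estimate_cytosol_background(img, ctr, opts$bg_annulus[1],
                                    opts$bg_annulus[2])
  prof <- radial_profile(up, ctr, grid)
  subtract_background(prof, bg)
}

#' Radial-profile a FRAP movie
#'
#' For every frame and every centrosome, crops a window around the seeded
#' position, upsamples it, locates the centre of mass, measures the
#' concentric-ring radial profile and subtracts the locally estimated
#' cytosolic background. Per-centrosome profiles are divided by that
#' centrosome's pre-bleach peak (when `normalize_first`) and averaged
#' across centrosomes (at least `min_n`), giving one averaged profile per
#' time point; pre-bleach frames are additionally pooled into a single
#' pre-bleach profile.
#'
#' @param movie A [render_movie()] result (or a movie read back from disk).
#' @param grid A [ring_grid()].
#' @param opts A [profiling_options()] list.
#' @return An object of class `"profile_set"`: `times` (s, relative to the
#'   first bleach when present), `profiles` (averaged `"radial_profile"` per
#'   time point), `prebleach` (averaged pre-bleach profile),
#'   `bleach_times` (relative), `n_centrosomes` and the options used.
#' @export
profile_frap_movie <- function(movie, grid = ring_grid(),
                               opts = profiling_options()) {
  if (!inherits(movie, "frap_movie"))
    pcm_stop("invalid_argument", "'movie' must be a frap_movie")
  n_cs <- nrow(movie$positions)
  if (n_cs < opts$min_n)
    pcm_stop("too_few_profiles",
             "movie has %d centrosomes but min_n = %d", n_cs, opts$min_n)
  bt <- vapply(movie$bleaches, `[[`, 0, "time")
  t0 <- if (length(bt)) min(bt) else 0
  times <- movie$times - t0
  pre_idx <- which(times < 0)
  if (length(bt) && !length(pre_idx))
    pcm_stop("invalid_argument", "movie has no pre-bleach frame")

  ## per centrosome: profiles for all frames, then the pre-bleach average
  per_cs <- lapply(seq_len(n_cs), function(k) {
    profs <- lapply(movie$frames, function(fr)
      profile_one(fr, movie$pixel_size, movie$positions[k, ], grid, opts))
    pre <- if (length(pre_idx)) {
      pp <- profs[[pre_idx[1]]]
      if (length(pre_idx) > 1L) {
        vals <- rowMeans(vapply(profs[pre_idx], `[[`, pp$values, "values"))
        pp$values <- vals
      }
      pp
    } else profs[[1]]
    if (opts$normalize_first) {
      pk <- suppressWarnings(max(pre$values, na.rm = TRUE))
      if (!is.finite(pk) || pk <= 0)
        pcm_stop("normalization_error",
                 "centrosome %d has a non-positive pre-bleach peak", k)
      profs <- lapply(profs, function(p) { p$values <- p$values / pk; p })
      pre$values <- pre$values / pk
    }
    list(profs = profs, pre = pre)
  })

  avg_at <- function(i)
    average_profiles(lapply(per_cs, function(cs) cs$profs[[i]]),
                     min_n = opts$min_n)
  profiles <- lapply(seq_along(times), avg_at)
  prebleach <- average_profiles(lapply(per_cs, `[[`, "pre"),
                                min_n = opts$min_n)
  structure(list(times = times, profiles = profiles, prebleach = prebleach,
                 bleach_times = if (length(bt)) bt - t0 else numeric(0),
                 n_centrosomes = n_cs, grid = grid, opts = opts),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf(
    "Profile set: %d time points (t = %g..%g s), %d centrosomes averaged, %d bleach event(s)\n",
    length(x$times), min(x$times), max(x$times), x$n_centrosomes,
    length(x$bleach_times)))
  invisible(x)
}

#' @export
plot.profile_set <- function(x, normalized = TRUE, ...) {
  post <- which(x$times >= 0)
  pre_m <- normalize_and_mirror(x$prebleach)
  cols <- hcl.colors(max(length(post), 2L), "Reds 3", rev = TRUE)
  plot(pre_m$radii, pre_m$values, type = "l", col = "blue", lwd = 2,
       xlab = "radius (um)", ylab = "normalized intensity", ...)
  for (j in seq_along(post)) {
    p <- x$profiles[[post[j]]]
    p <- if (normalized)
      mirror_profile(normalize_to_prebleach_peak(p, x$prebleach))
    else mirror_profile(p)
    lines(p$radii, p$values / max(pre_m$values, na.rm = TRUE),
          col = cols[j])
  }
  invisible(x)
}

## normalized, mirrored recovery profiles for the post-bleach time points;
## NULL where normalization fails (e.g. no recovered signal yet)
normalized_recovery_profiles <- function(profiles) {
  post <- which(profiles$times >= 0)
  lapply(post, function(i)
    tryCatch(mirror_profile(normalize_to_prebleach_peak(
      profiles$profiles[[i]], profiles$prebleach)),
      pcmfrap_error = function(e) NULL))
}
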