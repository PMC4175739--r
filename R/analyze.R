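## End-to-end FRAP analysis of one movie.

#' Analyze a FRAP movie end to end
#'
#' Runs the full quantification chain on a movie: radial profiling of every
#' centrosome at every time point ([profile_frap_movie()]), central and
#' peripheral ROI recovery curves, initial rates, peripheral acceleration,
#' profile-spreading statistics, double-bleach rate comparison (when the
#' movie has two bleach events) and the recovery-mode classification.
#'
#' @param movie A [render_movie()] result or a movie read with
#'   [read_frap_movie()].
#' @param grid A [ring_grid()].
#' @param roi A [roi_spec()].
#' @param opts A [profiling_options()] list.
#' @param thresholds A [mode_thresholds()] list.
#' @param rate_window Initial-rate window, s.
#' @param accel_window Acceleration-fit window, s.
#' @return An object of class `"frap_analysis"` with components
#'   `profiles`, `central`, `peripheral` (recovery curves),
#'   `central_rate`, `peripheral_rate`, `rate_ratio`,
#'   `peripheral_acceleration`, `spread`, `double_bleach` (or `NULL`),
#'   `mode` and the parameters used.
#' @export
analyze_frap <- function(movie, grid = ring_grid(), roi = roi_spec(),
                         opts = profiling_options(),
                         thresholds = mode_thresholds(),
                         rate_window = 60, accel_window = 120) {
  profiles <- profile_frap_movie(movie, grid, opts)
  central <- roi_curve(profiles, roi$central, "central")
  peripheral <- roi_curve(profiles, roi$peripheral, "peripheral")
  has_bleach <- length(profiles$bleach_times) > 0L
  central_rate <- if (has_bleach)
    initial_rate(central, rate_window) else NULL
  peripheral_rate <- if (has_bleach)
    initial_rate(peripheral, rate_window) else NULL
  accel <- if (has_bleach)
    tryCatch(acceleration_index(peripheral, accel_window),
             pcmfrap_error = function(e) NA_real_) else NA_real_
  spread <- tryCatch(spread_index(profiles),
                     pcmfrap_error = function(e) NULL)
  dbl <- if (length(profiles$bleach_times) == 2L)
    list(central = double_bleach_compare(central, rate_window),
         peripheral = double_bleach_compare(peripheral, rate_window))
  else NULL
  mode <- classify_mode(profiles, thresholds)
  structure(list(
    profiles = profiles, central = central, peripheral = peripheral,
    central_rate = central_rate, peripheral_rate = peripheral_rate,
    rate_ratio = if (has_bleach)
      central_rate$slope / peripheral_rate$slope else NA_real_,
    peripheral_acceleration = accel, spread = spread,
    double_bleach = dbl, mode = mode, grid = grid, roi = roi,
    opts = opts, thresholds = thresholds, rate_window = rate_window,
    accel_window = accel_window),
    class = "frap_analysis")
}

#' @export
print.frap_analysis <- function(x, ...) {
  cat("FRAP analysis\n")
  print(x$profiles)
  if (!is.null(x$central_rate))
    cat(sprintf(
      "  central rate %.4g /s, peripheral rate %.4g /s (ratio %.3g)\n",
      x$central_rate$slope, x$peripheral_rate$slope, x$rate_ratio))
  if (!is.null(x$spread))
    cat(sprintf("  FWHM slope %.3g um/s (t = %.2f)\n", x$spread$slope,
                x$spread$t_stat))
  if (!is.null(x$double_bleach))
    cat(sprintf(
      "  re-bleach rate ratios: central %.3g, peripheral %.3g\n",
      x$double_bleach$central$ratio, x$double_bleach$peripheral$ratio))
  print(x$mode)
  invisible(x)
}

#' @export
summary.frap_analysis <- function(object, ...) {
  ev <- object$mode$evidence
  data.frame(
    mode = object$mode$call,
    central_rate = object$central_rate$slope %||% NA_real_,
    peripheral_rate = object$peripheral_rate$slope %||% NA_real_,
    rate_ratio = object$rate_ratio,
    peripheral_acceleration = object$peripheral_acceleration,
    early_fwhm_ratio = ev$early_fwhm_ratio,
    fwhm_slope = ev$fwhm_slope,
    shape_deviation = ev$shape_deviation)
}

#' @export
plot.frap_analysis <- function(x, which = c("profiles", "curves"), ...) {
  which <- match.arg(which)
  if (which == "profiles") {
    plot(x$profiles, ...)
  } else {
    per <- rescale_peripheral(x$peripheral, x$central)
    rng <- range(c(x$central$values, per$values), na.rm = TRUE)
    plot(x$central, ylim = rng, col = "darkgreen", ...)
    lines(per$times, per$values, type = "b", pch = 16, cex = 0.6,
          col = "red")
    legend("bottomright", legend = c("central", "peripheral (rescaled)"),
           col = c("darkgreen", "red"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Default frame-acquisition scheme
#'
#' Two pre-bleach frames, dense sampling (every 10 s) across the first
#' minute after the bleach — the initial-rate window — then every 30 s out
#' to ~5 min, where the flux-model recovery profile has reached its
#' steady shape.
#'
#' @param rebleach_at Optional time of a second bleach; when given, the
#'   scheme adds dense sampling over the minute following it.
#' @return Numeric vector of frame times (s), bleach at t = 0.
#' @export
default_frame_times <- function(rebleach_at = NULL) {
  tt <- c(-20, -10, seq(10, 60, 10), seq(85, 295, 30))
  if (!is.null(rebleach_at)) {
    stopifnot_scalar(rebleach_at, "rebleach_at", positive = TRUE)
    tt <- sort(unique(c(tt[tt < rebleach_at],
                        seq(rebleach_at + 10, rebleach_at + 60, 10),
                        rebleach_at + c(90, 120))))
  }
  tt
}

#' Simulate and render a synthetic FRAP movie in one call
#'
#' Convenience wrapper tying the mechanistic simulator to the optical
#' model: integrates the ring chain over the frame times, applies the
#' requested bleach events, lays out centrosomes on a grid with a small
#' random subpixel jitter, and renders the movie.
#'
#' @param params A [mechanistic_params()] object.
#' @param frame_times Frame acquisition times (s).
#' @param bleaches [bleach_event()] or list of them.
#' @param n_centrosomes Number of centrosomes rendered (default 10).
#' @param optics An [optics_params()] object.
#' @param spacing_um Centre-to-centre grid spacing of the layout.
#' @param seed Integer seed covering layout jitter and camera noise.
#' @return A `"frap_movie"`.
#' @export
simulate_frap_movie <- function(params = mechanistic_params("flux"),
                                frame_times = default_frame_times(),
                                bleaches = bleach_event(time = 0),
                                n_centrosomes = 10L,
                                optics = optics_params(),
                                spacing_um = 7, seed = 1L) {
  state <- simulate_ring_chain(params, frame_times, bleaches)
  ncols <- ceiling(sqrt(n_centrosomes))
  nrows <- ceiling(n_centrosomes / ncols)
  margin <- params$n_rings * params$ring_width + 3.2
  gx <- margin + (seq_len(ncols) - 1L) * spacing_um
  gy <- margin + (seq_len(nrows) - 1L) * spacing_um
  pos <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n_centrosomes), ,
                                                drop = FALSE]
  set.seed(as.integer(seed) %% 2147483629L)
  pos <- pos + matrix(runif(2 * n_centrosomes, -0.5, 0.5) *
                        optics$camera_pixel, ncol = 2)
  field <- c(max(gx) + margin, max(gy) + margin)
  render_movie(state, optics, pos, field_um = field,
               seed = stage_seed(seed, "render"))
}
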