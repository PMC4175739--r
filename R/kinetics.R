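## Recovery kinetics: ROI curves, rates, curvature, spreading, and the
## recovery-mode classification.

#' Central and peripheral ROI bands
#'
#' Radial bands over which ring values are averaged to form recovery
#' curves. A ring belongs to a band when its inner radius lies within the
#' band limits (with a quarter-spacing tolerance, so that printed, rounded
#' band limits select the intended rings). At the default 0.028 um grid
#' each default band contains exactly 5 rings.
#'
#' @param central Central band `c(lo, hi)` in um.
#' @param peripheral Peripheral band `c(lo, hi)` in um.
#' @return A list of class `"roi_spec"`.
#' @export
roi_spec <- function(central = c(0.028, 0.14),
                     peripheral = c(0.62, 0.73)) {
  for (b in list(central, peripheral))
    if (length(b) != 2L || b[1] >= b[2])
      pcm_stop("invalid_argument", "bands must be c(lo, hi) with lo < hi")
  if (central[2] > peripheral[1] && peripheral[2] > central[1])
    pcm_stop("invalid_argument", "bands must not overlap")
  structure(list(central = as.numeric(central),
                 peripheral = as.numeric(peripheral)),
            class = "roi_spec")
}

## ring indices of a band: inner radius within [lo - s/4, hi + s/4]
band_rings <- function(grid, band) {
  inner <- (seq_len(grid$n_rings) - 1L) * grid$spacing
  tol <- grid$spacing / 4
  which(inner >= band[1] - tol & inner <= band[2] + tol)
}

#' ROI mean intensity through time
#'
#' Averages, per time point, the profile values of the rings in the band,
#' yielding an intensity-versus-time recovery curve spanning the pre- and
#' post-bleach frames.
#'
#' @param profiles A [profile_frap_movie()] result.
#' @param band Radial band `c(lo, hi)` in um, e.g. a [roi_spec()]
#'   component.
#' @param label Optional curve label.
#' @return An object of class `"recovery_curve"`: `times` (s, relative to
#'   the first bleach), `values`, `bleach_times`, `label`.
#' @export
roi_curve <- function(profiles, band, label = NULL) {
  if (!inherits(profiles, "profile_set"))
    pcm_stop("invalid_argument", "'profiles' must be a profile_set")
  rings <- band_rings(profiles$grid, band)
  if (!length(rings))
    pcm_stop("invalid_argument", "band [%g, %g] outside the grid",
             band[1], band[2])
  vals <- vapply(profiles$profiles, function(p) mean(p$values[rings]),
                 0)
  structure(list(times = profiles$times, values = vals,
                 bleach_times = profiles$bleach_times,
                 label = label %||% sprintf("[%g, %g] um", band[1],
                                            band[2])),
            class = "recovery_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("Recovery curve %s: %d samples, t = %g..%g s, %d bleach(es)\n",
              x$label, length(x$times), min(x$times), max(x$times),
              length(x$bleach_times)))
  invisible(x)
}

#' @export
plot.recovery_curve <- function(x, ..., xlab = "time since bleach (s)",
                                ylab = "ROI intensity") {
  plot(x$times, x$values, type = "b", pch = 16, cex = 0.6, xlab = xlab,
       ylab = ylab, ...)
  for (tb in x$bleach_times) abline(v = tb, lty = 3)
  invisible(x)
}

## samples of a curve in [tb, tb + window], truncated at the next bleach
window_samples <- function(curve, window, after = 1L) {
  bt <- sort(curve$bleach_times)
  if (after > length(bt))
    pcm_stop("invalid_argument", "curve has only %d bleach event(s)",
             length(bt))
  tb <- bt[after]
  hi <- tb + window
  if (after < length(bt)) hi <- min(hi, bt[after + 1L] - 1e-9)
  sel <- curve$times >= tb - 1e-9 & curve$times <= hi + 1e-9
  list(t = curve$times[sel] - tb, y = curve$values[sel], tb = tb)
}

#' Initial recovery rate
#'
#' Least-squares slope of the ROI intensity over the first `window` seconds
#' after a bleach (the gradient of the initial phase of recovery). Samples
#' at the bleach time itself, when present, anchor the fit.
#'
#' @param curve A [roi_curve()] result.
#' @param window Fit window in seconds (default 60).
#' @param after Index of the bleach event the window follows.
#' @return An object of class `"rate_estimate"` with `slope`
#'   (intensity/s), `se`, `window`, `n_points`.
#' @export
initial_rate <- function(curve, window = 60, after = 1L) {
  if (!inherits(curve, "recovery_curve"))
    pcm_stop("invalid_argument", "'curve' must be a recovery_curve")
  stopifnot_scalar(window, "window", positive = TRUE)
  ws <- window_samples(curve, window, after)
  if (sum(ws$t > 1e-9) < 2L)
    pcm_stop("too_few_samples",
             "need at least 2 post-bleach samples within the window")
  fit <- lm(ws$y ~ ws$t)
  se <- if (length(ws$t) > 2L)
    suppressWarnings(summary(fit))$coefficients[2, 2] else NA_real_
  structure(list(slope = unname(coef(fit)[2]), se = se, window = window,
                 n_points = length(ws$t)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Initial rate: %.4g per s (se %.3g, %d points over %g s)\n",
              x$slope, x$se, x$n_points, x$window))
  invisible(x)
}

#' Rescale a peripheral curve to the central pre-bleach level
#'
#' Multiplies the peripheral curve so that its mean pre-bleach value equals
#' the central curve's mean pre-bleach value, the normalization used to
#' overlay curves of very different absolute intensity.
#'
#' @param peripheral,central [roi_curve()] results sharing time points.
#' @return The rescaled peripheral curve.
#' @export
rescale_peripheral <- function(peripheral, central) {
  for (cv in list(peripheral, central))
    if (!inherits(cv, "recovery_curve"))
      pcm_stop("invalid_argument", "inputs must be recovery_curves")
  pre_p <- peripheral$values[peripheral$times < 0]
  pre_c <- central$values[central$times < 0]
  if (!length(pre_p) || !length(pre_c))
    pcm_stop("invalid_argument", "both curves need pre-bleach samples")
  if (mean(pre_p) <= 0)
    pcm_stop("normalization_error", "peripheral pre-bleach signal is zero")
  peripheral$values <- peripheral$values * (mean(pre_c) / mean(pre_p))
  peripheral
}

#' Acceleration index of a recovery curve
#'
#' Quadratic coefficient of a least-squares quadratic fit to the
#' post-bleach window. Positive values indicate recovery that speeds up
#' over time — the signature of material arriving from the centre — while
#' ordinary saturating recovery gives negative values.
#'
#' @param curve A [roi_curve()] result.
#' @param window Fit window, s.
#' @param after Index of the bleach event.
#' @return Signed curvature (intensity/s^2).
#' @export
acceleration_index <- function(curve, window = 120, after = 1L) {
  if (!inherits(curve, "recovery_curve"))
    pcm_stop("invalid_argument", "'curve' must be a recovery_curve")
  ws <- window_samples(curve, window, after)
  if (length(ws$t) < 3L)
    pcm_stop("too_few_samples", "need at least 3 samples in the window")
  fit <- lm(ws$y ~ ws$t + I(ws$t^2))
  unname(coef(fit)[3])
}

#' Compare recovery rates after two successive bleaches
#'
#' Measures the initial rate after each of exactly two bleach events (the
#' window after the first bleach is truncated at the second) and reports
#' their ratio. For inside-out flux, recovery rates reset to their
#' original values after a re-bleach because recovery is driven by steady
#' incorporation, not by site refilling.
#'
#' @param curve A [roi_curve()] result with exactly two bleach events.
#' @param window Rate window, s.
#' @return List with `rate1`, `rate2` ([initial_rate()] objects) and
#'   `ratio` = `rate2$slope / rate1$slope`.
#' @export
double_bleach_compare <- function(curve, window = 60) {
  if (!inherits(curve, "recovery_curve"))
    pcm_stop("invalid_argument", "'curve' must be a recovery_curve")
  if (length(curve$bleach_times) != 2L)
    pcm_stop("invalid_argument", "curve must have exactly 2 bleach events")
  r1 <- initial_rate(curve, window, after = 1L)
  r2 <- initial_rate(curve, window, after = 2L)
  list(rate1 = r1, rate2 = r2, ratio = r2$slope / r1$slope)
}

## FWHM of each normalized post-bleach recovery profile; NA if unbounded
recovery_fwhms <- function(profiles) {
  post <- which(profiles$times >= 0)
  nrm <- normalized_recovery_profiles(profiles)
  fw <- vapply(nrm, function(p) {
    if (is.null(p)) return(NA_real_)
    tryCatch(profile_fwhm(p), pcmfrap_error = function(e) NA_real_)
  }, 0)
  list(times = profiles$times[post], fwhm = fw)
}

#' Profile-spreading statistic
#'
#' Least-squares slope of the full width at half maximum (FWHM) of the
#' pre-bleach-peak-normalized recovery profiles against time. Inside-out
#' assembly gives a positive slope (profiles start narrow and spread
#' outward); distributed exchange gives a slope near zero.
#'
#' @param profiles A [profile_frap_movie()] result with at least 3
#'   post-bleach time points.
#' @return An object of class `"spread_index"` with `slope` (um/s), `se`,
#'   `t_stat`, `n` and the per-time widths.
#' @export
spread_index <- function(profiles) {
  if (!inherits(profiles, "profile_set"))
    pcm_stop("invalid_argument", "'profiles' must be a profile_set")
  fw <- recovery_fwhms(profiles)
  ok <- is.finite(fw$fwhm)
  if (length(fw$fwhm) < 3L || sum(!ok) >= length(fw$fwhm) / 2)
    pcm_stop("width_uncomputable",
             "FWHM uncomputable at %d of %d post-bleach time points",
             sum(!ok), length(fw$fwhm))
  if (sum(ok) < 3L)
    pcm_stop("width_uncomputable", "fewer than 3 computable widths")
  fit <- lm(fw$fwhm[ok] ~ fw$times[ok])
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = unname(coef(fit)[2]), se = sm[2, 2],
                 t_stat = sm[2, 3], n = sum(ok), times = fw$times,
                 fwhm = fw$fwhm),
            class = "spread_index")
}

#' @export
print.spread_index <- function(x, ...) {
  cat(sprintf("Spread index: %.4g um/s (se %.3g, t = %.2f, n = %d)\n",
              x$slope, x$se, x$t_stat, x$n))
  invisible(x)
}

#' Classification thresholds for the recovery mode
#'
#' @param fwhm_ratio Earliest recovery FWHM must be below this fraction of
#'   the pre-bleach FWHM to call inside-out assembly.
#' @param shape_dev Maximum allowed deviation (fraction of peak) between
#'   normalized recovery profiles and the pre-bleach profile to call
#'   distributed exchange.
#' @param t_stat Minimum t statistic of the spreading slope for inside-out
#'   assembly.
#' @return A named list.
#' @export
mode_thresholds <- function(fwhm_ratio = 0.8, shape_dev = 0.05,
                            t_stat = 2) {
  list(fwhm_ratio = fwhm_ratio, shape_dev = shape_dev, t_stat = t_stat)
}

## max abs deviation between each normalized recovery profile and the
## prebleach profile, as a fraction of the prebleach peak
shape_deviation <- function(profiles) {
  pre <- tryCatch(normalize_and_mirror(profiles$prebleach),
                  pcmfrap_error = function(e) NULL)
  if (is.null(pre)) return(NA_real_)
  pk_raw <- suppressWarnings(max(profiles$prebleach$values, na.rm = TRUE))
  nrm <- normalized_recovery_profiles(profiles)
  devs <- vapply(nrm, function(p) {
    if (is.null(p)) return(NA_real_)
    suppressWarnings(max(abs(p$values / pk_raw - pre$values),
                         na.rm = TRUE))
  }, 0)
  if (!length(devs) || all(!is.finite(devs))) NA_real_
  else max(devs, na.rm = TRUE)
}

#' Classify the recovery mode of a profiled FRAP movie
#'
#' Operationalizes the dichotomy between distributed binding-site exchange
#' and inside-out incorporation-plus-outward-flux:
#'
#' * **inside_out** — the earliest computable recovery FWHM is below
#'   `fwhm_ratio` times the pre-bleach FWHM, *and* the spreading slope is
#'   positive with `|t| >` `t_stat`.
#' * **distributed** — the normalized recovery profiles deviate from the
#'   pre-bleach profile by less than `shape_dev` of the peak at every
#'   post-bleach time point.
#' * **indeterminate** — neither pattern (or the evidence is uncomputable,
#'   e.g. no detectable signal).
#'
#' @param profiles A [profile_frap_movie()] result spanning pre-bleach and
#'   at least 3 post-bleach times.
#' @param thresholds A [mode_thresholds()] list.
#' @return An object of class `"mode_call"`: `call` (one of
#'   `"distributed"`, `"inside_out"`, `"indeterminate"`) and the `evidence`
#'   (early FWHM ratio, spreading slope and t, shape deviation, peripheral
#'   acceleration index) plus the thresholds applied.
#' @export
classify_mode <- function(profiles, thresholds = mode_thresholds()) {
  if (!inherits(profiles, "profile_set"))
    pcm_stop("invalid_argument", "'profiles' must be a profile_set")
  if (sum(profiles$times >= 0) < 3L)
    pcm_stop("too_few_samples", "need at least 3 post-bleach time points")

  pre_fwhm <- tryCatch(profile_fwhm(normalize_and_mirror(
    profiles$prebleach)), pcmfrap_error = function(e) NA_real_)
  fw <- recovery_fwhms(profiles)
  early <- which(is.finite(fw$fwhm))[1]
  early_ratio <- if (is.finite(pre_fwhm) && !is.na(early))
    fw$fwhm[early] / pre_fwhm else NA_real_
  sp <- tryCatch(spread_index(profiles),
                 pcmfrap_error = function(e) NULL)
  dev <- shape_deviation(profiles)
  accel <- tryCatch(acceleration_index(
    roi_curve(profiles, c(0.62, 0.73), "peripheral")),
    pcmfrap_error = function(e) NA_real_)

  evidence <- list(early_fwhm_ratio = early_ratio,
                   fwhm_slope = if (is.null(sp)) NA_real_ else sp$slope,
                   fwhm_slope_t = if (is.null(sp)) NA_real_ else sp$t_stat,
                   shape_deviation = dev,
                   peripheral_acceleration = accel,
                   prebleach_fwhm = pre_fwhm)
  call <- if (!is.na(early_ratio) && early_ratio < thresholds$fwhm_ratio &&
              !is.null(sp) && sp$slope > 0 &&
              abs(sp$t_stat) > thresholds$t_stat) {
    "inside_out"
  } else if (is.finite(dev) && dev < thresholds$shape_dev) {
    "distributed"
  } else "indeterminate"
  structure(list(call = call, evidence = evidence,
                 thresholds = thresholds),
            class = "mode_call")
}

#' @export
print.mode_call <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf("Recovery mode: %s\n", x$call))
  cat(sprintf(
    "  early FWHM ratio %.3g (< %.2g?), FWHM slope %.3g um/s (t = %.2f), shape dev %.3g (< %.2g?)\n",
    ev$early_fwhm_ratio, x$thresholds$fwhm_ratio, ev$fwhm_slope,
    ev$fwhm_slope_t, ev$shape_deviation, x$thresholds$shape_dev))
  invisible(x)
}
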