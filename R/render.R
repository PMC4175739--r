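## Optical model: radially symmetric rendering of ring amounts.
##
## A unit amount spread uniformly on an annulus and convolved with an
## isotropic Gaussian PSF has the per-area intensity
##   g(d) = (1/A) \int_{r1}^{r2} (rho/sigma^2) exp(-(d^2+rho^2)/(2 sigma^2))
##                                I0(d rho / sigma^2) d rho,
## with A the annulus area. The integrand is evaluated with the
## exponentially scaled Bessel I0 to stay finite at large arguments, and
## integrated with Simpson's rule. Rendering a frame is then a linear
## combination of per-ring basis profiles, evaluated at pixel-centre
## distances.

## per-area blurred intensity of a unit-mass uniform annulus [r1, r2)
blurred_annulus <- function(d, r1, r2, sigma, n_quad = 257L) {
  if (r2 <= r1) pcm_stop("invalid_argument", "empty annulus")
  rho <- seq(r1, r2, length.out = n_quad)
  h <- rho[2] - rho[1]
  w <- rep(c(4, 2), length.out = n_quad)
  w[1] <- w[n_quad] <- 1
  area <- pi * (r2^2 - r1^2)
  vapply(d, function(dd) {
    f <- (rho / sigma^2) * exp(-(dd - rho)^2 / (2 * sigma^2)) *
      besselI(dd * rho / sigma^2, 0, expon.scaled = TRUE)
    sum(w * f) * h / 3 / area
  }, 0)
}

## basis profiles for all rings of a parameter set, tabulated on a fine
## distance grid for cheap interpolation while rendering
ring_basis <- function(params, optics, d_max = NULL, d_step = 0.005) {
  N <- params$n_rings
  w <- params$ring_width
  if (is.null(d_max)) d_max <- N * w + 5 * optics$psf_sigma
  d <- seq(0, d_max, by = d_step)
  B <- vapply(seq_len(N), function(i)
    blurred_annulus(d, (i - 1) * w, i * w, optics$psf_sigma), d)
  list(d = d, B = B)
}

#' Calibrated image container
#'
#' @param pixels Numeric matrix (one plane, rows = y, columns = x) or a 3D
#'   array (z stack) of intensities in counts.
#' @param pixel_size Pixel size in micrometres.
#' @param frame_time Optional acquisition time (s).
#' @param channel Optional channel label.
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(pixels, pixel_size, frame_time = NULL,
                        channel = NULL) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    pcm_stop("invalid_argument", "'pixels' must be a matrix or 3D array")
  if (any(!is.finite(pixels)))
    pcm_stop("invalid_argument", "'pixels' must be finite")
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_time = frame_time, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Image %s px (%.3g um/px)%s\n",
              paste(d, collapse = " x "), x$pixel_size,
              if (is.null(x$channel)) "" else paste0(", channel ",
                                                    x$channel)))
  invisible(x)
}

## pixel-centre coordinate vectors (um); origin at the image corner,
## pixel (row r, col c) centre at ((c - 0.5) px, (r - 0.5) px)
pixel_centers <- function(n, pixel_size) (seq_len(n) - 0.5) * pixel_size

## expected (noise-free) frame for ring amounts F at given positions
expected_frame <- function(Famounts, basis, optics, positions, nrow_px,
                           ncol_px) {
  px <- optics$camera_pixel
  img <- matrix(optics$background, nrow_px, ncol_px)
  prof <- drop(basis$B %*% Famounts)   # per-area intensity vs distance
  fun <- approxfun(basis$d, prof, yleft = prof[1], yright = 0, rule = 2)
  xs <- pixel_centers(ncol_px, px)
  ys <- pixel_centers(nrow_px, px)
  reach <- max(basis$d)
  for (k in seq_len(nrow(positions))) {
    cx <- positions[k, 1]; cy <- positions[k, 2]
    ci <- which(abs(xs - cx) <= reach)
    ri <- which(abs(ys - cy) <= reach)
    if (!length(ci) || !length(ri)) next
    dmat <- sqrt(outer((ys[ri] - cy)^2, (xs[ci] - cx)^2, `+`))
    img[ri, ci] <- img[ri, ci] + optics$gain * px^2 * fun(dmat)
  }
  img
}

apply_camera_noise <- function(img, optics) {
  if (optics$poisson_noise)
    img[] <- rpois(length(img), lambda = pmax(img, 0))
  if (optics$read_noise_sd > 0)
    img[] <- img + rnorm(length(img), sd = optics$read_noise_sd)
  img
}

#' Render a ring-chain trajectory into a synthetic FRAP movie
#'
#' Places each ring's fluorescent amount uniformly on its annulus around
#' every centrosome position, convolves with the Gaussian PSF, samples at
#' the camera pixel pitch, scales by the gain, adds the uniform background
#' and (optionally) Poisson photon noise plus Gaussian read noise. Before
#' noise, the integrated signal above background in a sufficiently large
#' field equals `gain` times the total fluorescent amount (convolution
#' conserves mass).
#'
#' @param state A [simulate_ring_chain()] result.
#' @param optics An [optics_params()] object.
#' @param positions Matrix (n x 2) of centrosome centres (um), or `NULL` to
#'   place a single centrosome at the field centre.
#' @param field_um Field of view `c(width, height)` in um. Defaults to a
#'   square field wrapping all positions with a margin that keeps all
#'   profiling rings inside the field.
#' @param margin_um Margin added around the outermost positions when
#'   `field_um` is `NULL`.
#' @param seed Integer seed for the noise; `NULL` leaves the RNG state
#'   alone.
#' @return An object of class `"frap_movie"`: frames (list of matrices,
#'   counts), `times` (s), `pixel_size` (um), `positions`, `bleaches`
#'   (carried over from the state), `optics` and `seed`.
#' @export
render_movie <- function(state, optics = optics_params(), positions = NULL,
                         field_um = NULL, margin_um = 3.2, seed = NULL) {
  if (!inherits(state, "ring_state"))
    pcm_stop("invalid_argument", "'state' must be a ring_state")
  if (!inherits(optics, "optics_params"))
    pcm_stop("invalid_argument", "'optics' must be optics_params")
  if (length(state$times) < 1L || all(!is.finite(state$fluorescent)))
    pcm_stop("invalid_argument", "empty ring state")
  if (is.null(positions)) {
    ext <- state$params$n_rings * state$params$ring_width + margin_um
    positions <- matrix(c(ext, ext), 1)
    if (is.null(field_um)) field_um <- c(2 * ext, 2 * ext)
  }
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    pcm_stop("invalid_argument", "'positions' must be an n x 2 matrix")
  if (is.null(field_um))
    field_um <- c(max(positions[, 1]) + margin_um,
                  max(positions[, 2]) + margin_um)
  if (any(positions[, 1] < 0 | positions[, 1] > field_um[1] |
          positions[, 2] < 0 | positions[, 2] > field_um[2]))
    pcm_stop("outside_field", "centrosome position outside the field")
  px <- optics$camera_pixel
  ncol_px <- ceiling(field_um[1] / px - 1e-9)
  nrow_px <- ceiling(field_um[2] / px - 1e-9)
  basis <- ring_basis(state$params, optics)
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483629L)
  frames <- lapply(seq_along(state$times), function(i) {
    img <- expected_frame(state$fluorescent[i, ], basis, optics, positions,
                          nrow_px, ncol_px)
    apply_camera_noise(img, optics)
  })
  structure(list(frames = frames, times = state$times, pixel_size = px,
                 positions = positions, bleaches = state$bleaches,
                 optics = optics, seed = seed),
            class = "frap_movie")
}

#' @export
print.frap_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "FRAP movie: %d frames (%d x %d px, %.3g um/px), t in [%g, %g] s, %d centrosome(s), %d bleach event(s)\n",
    length(x$frames), d[1], d[2], x$pixel_size, min(x$times), max(x$times),
    nrow(x$positions), length(x$bleaches)))
  invisible(x)
}

#' Render a sub-resolution bead reference image
#'
#' A fluorescent bead smaller than the diffraction limit images as a uniform
#' disk convolved with the PSF; its profile approximates the PSF itself and
#' serves as the width reference that centriole-tight proteins are compared
#' against. The default diameter is 0.17 um (170 nm beads).
#'
#' @param optics An [optics_params()] object.
#' @param bead_diameter Bead diameter in um.
#' @param amount Total fluorescent amount of the bead.
#' @param field_um Square field edge, um.
#' @param seed Noise seed, or `NULL`.
#' @return An [image_stack()] of the bead.
#' @export
simulate_bead_image <- function(optics = optics_params(),
                                bead_diameter = 0.17, amount = 1,
                                field_um = 4, seed = NULL) {
  stopifnot_scalar(bead_diameter, "bead_diameter", positive = TRUE)
  if (bead_diameter >= field_um)
    pcm_stop("invalid_argument", "bead larger than the field")
  px <- optics$camera_pixel
  n <- ceiling(field_um / px - 1e-9)
  d <- seq(0, field_um, by = min(px, optics$psf_sigma) / 10)
  prof <- blurred_annulus(d, 0, bead_diameter / 2, optics$psf_sigma)
  fun <- approxfun(d, prof, yleft = prof[1], yright = 0, rule = 2)
  xs <- pixel_centers(n, px)
  c0 <- (ceiling(n / 2) - 0.5) * px    # bead on the central pixel centre
  dmat <- sqrt(outer((xs - c0)^2, (xs - c0)^2, `+`))
  img <- dmat
  img[] <- optics$background + optics$gain * amount * px^2 * fun(dmat)
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483629L)
  img <- apply_camera_noise(img, optics)
  image_stack(img, px, channel = "bead")
}
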