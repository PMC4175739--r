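# Independent numerical oracles used by the tests. These deliberately take
# different computational routes from the package internals (Riemann-sum
# convolution instead of Bessel quadrature, combinatorial enumeration
# instead of the partition recurrence).

# Fine-grid ring averaging of an analytic radial function f(r): the mean of
# f over subpixel centres falling in each ring, on a grid much finer than
# the profiling grid.
oracle_ring_average <- function(f, grid, extent, step = grid$spacing / 9) {
  xs <- seq(-extent, extent, by = step)
  d <- sqrt(outer(xs^2, xs^2, `+`))
  bin <- floor(d / grid$spacing) + 1
  keep <- bin <= grid$n_rings
  vals <- tapply(f(d[keep]), bin[keep], mean)
  out <- rep(NA_real_, grid$n_rings)
  out[as.integer(names(vals))] <- vals
  out
}

# Dense-grid numerical convolution: a uniform annulus [r1, r2) of total
# mass M, blurred with a 2D Gaussian, integrated over camera pixels.
# Returns the expected image above background on an n x n pixel field with
# the annulus centred at (cx, cy) um.
oracle_conv_image <- function(M, r1, r2, sigma, pixel, n, cx, cy,
                              sub = 12L) {
  h <- pixel / sub
  ext <- r2 + 5 * sigma
  src <- seq(-ext + h / 2, ext - h / 2, by = h)
  dsrc <- sqrt(outer(src^2, src^2, `+`))
  in_ann <- dsrc >= r1 & dsrc < r2
  dens <- M / (sum(in_ann) * h^2)               # mass per area
  sx <- rep(src, each = length(src))[in_ann]
  sy <- rep(src, times = length(src))[in_ann]
  px <- (seq_len(n) - 0.5) * pixel
  img <- matrix(0, n, n)
  g <- function(u) exp(-u / (2 * sigma^2)) / (2 * pi * sigma^2)
  for (i in seq_len(n)) {
    dy2 <- (px[i] - (cy + sy))^2
    for (j in seq_len(n)) {
      d2 <- (px[j] - (cx + sx))^2 + dy2
      img[i, j] <- sum(g(d2)) * dens * h^2 * pixel^2
    }
  }
  img
}

# FWHM of a disk of given diameter convolved with a Gaussian, from a fine
# 1D radial sampling of the dense 2D convolution.
oracle_disk_fwhm <- function(diameter, sigma, step = 0.002) {
  r2 <- diameter / 2
  h <- min(sigma, r2) / 40
  src <- seq(-r2, r2, by = h)
  dsrc <- sqrt(outer(src^2, src^2, `+`))
  keep <- dsrc < r2
  sx <- rep(src, each = length(src))[keep]
  sy <- rep(src, times = length(src))[keep]
  d <- seq(0, r2 + 4 * sigma, by = step)
  prof <- vapply(d, function(dd)
    sum(exp(-((dd - sx)^2 + sy^2) / (2 * sigma^2))), 0)
  half <- prof[1] / 2
  i <- which(prof < half)[1]
  x <- d[i - 1] + step * (prof[i - 1] - half) / (prof[i - 1] - prof[i])
  2 * x
}

# Brute-force two-sided Mann-Whitney p by enumerating every assignment of
# the pooled ranks to group 1 and counting assignments at least as extreme
# (|U - n1 n2 / 2| >= observed) — an independent route and an independent
# two-sidedness definition (equivalent under the symmetric null).
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, `>`)) + sum(outer(x, y, `==`)) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# Triangular mirrored profile peaking at 0 with FWHM w0, on the default
# grid; background-subtracted so the normalization path accepts it.
make_triangle_profile <- function(w0, grid = ring_grid(), peak = 1) {
  radii <- (seq_len(grid$n_rings) - 0.5) * grid$spacing
  vals <- peak * pmax(0, 1 - radii / w0)
  structure(list(radii = c(-rev(radii), radii),
                 values = c(rev(vals), vals),
                 n_subpixels = rep(1L, 2 * grid$n_rings),
                 spacing = grid$spacing,
                 flags = list(background_subtracted = TRUE,
                              normalized = FALSE, mirrored = TRUE)),
            class = "radial_profile")
}

# Unmirrored constant-shape profile with a given amplitude
make_shape_profile <- function(shape_fun, amplitude = 1,
                               grid = ring_grid()) {
  radii <- (seq_len(grid$n_rings) - 0.5) * grid$spacing
  structure(list(radii = radii, values = amplitude * shape_fun(radii),
                 n_subpixels = rep(1L, grid$n_rings),
                 spacing = grid$spacing,
                 flags = list(background_subtracted = TRUE,
                              normalized = FALSE, mirrored = FALSE)),
            class = "radial_profile")
}

# Hand-built profile_set: a shape that recovers with per-time amplitudes
# and per-time widths (for spreading tests)
make_profile_set <- function(times, widths = NULL, amplitudes = NULL,
                             shape_fun = function(r) exp(-r^2 / (2 *
                                                                   0.3^2)),
                             grid = ring_grid(), bleach_times = 0) {
  n <- length(times)
  if (is.null(amplitudes)) amplitudes <- rep(1, n)
  profs <- lapply(seq_len(n), function(i) {
    sf <- if (is.null(widths)) shape_fun
    else {
      s <- widths[i] / 2.3548
      function(r) exp(-r^2 / (2 * s^2))
    }
    make_shape_profile(sf, amplitudes[i], grid)
  })
  pre <- make_shape_profile(if (is.null(widths)) shape_fun
                            else {
                              s <- max(widths) * 2 / 2.3548
                              function(r) exp(-r^2 / (2 * s^2))
                            }, 1, grid)
  structure(list(times = times, profiles = profs, prebleach = pre,
                 bleach_times = bleach_times, n_centrosomes = 10L,
                 grid = grid, opts = profiling_options()),
            class = "profile_set")
}

# Small, fast movie for pipeline tests (4 centrosomes, coarse grid)
tiny_movie_config <- function(kind = "flux", seed = 1L) {
  list(seed = seed,
       model = list(kind = kind),
       movie = list(frame_times = c(-15, -5, 10, 25, 40, 55),
                    n_centrosomes = 4L, spacing_um = 7),
       profiling = list(min_n = 4L))
}
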