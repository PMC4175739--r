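make_curve <- function(times, values, bleach_times = 0) {
  structure(list(times = times, values = values,
                 bleach_times = bleach_times, label = "test"),
            class = "recovery_curve")
}

test_that("the default ROI bands hold exactly five rings each", {
  g <- ring_grid()
  spec <- roi_spec()
  expect_length(pcmfrap:::band_rings(g, spec$central), 5L)
  expect_length(pcmfrap:::band_rings(g, spec$peripheral), 5L)
  expect_error(roi_spec(central = c(0.1, 0.05)),
               class = "pcmfrap_invalid_argument")
  expect_error(roi_spec(central = c(0.028, 0.7)),
               class = "pcmfrap_invalid_argument")  # overlapping bands
})

test_that("ROI curves average the in-band rings", {
  g <- ring_grid()
  ## ring values equal to the ring index: the central band holds rings
  ## 2..6, so the curve value is their mean
  ps <- make_profile_set(times = c(-10, 10, 20),
                         shape_fun = function(r) r)  # placeholder
  idx <- pcmfrap:::band_rings(g, roi_spec()$central)
  ps$profiles <- lapply(ps$profiles, function(p) {
    p$values <- seq_along(p$values); p })
  cv <- roi_curve(ps, roi_spec()$central)
  expect_true(all(cv$values == mean(idx)))

  ## worked example: central-band ring values 1..5 average to 3
  ps$profiles <- lapply(ps$profiles, function(p) {
    p$values[] <- 0; p$values[idx] <- 1:5; p })
  expect_true(all(roi_curve(ps, roi_spec()$central)$values == 3))

  ## constant profiles give a constant curve
  ps$profiles <- lapply(ps$profiles, function(p) { p$values[] <- 2.5; p })
  expect_true(all(roi_curve(ps, roi_spec()$peripheral)$values == 2.5))
  expect_error(roi_curve(ps, c(50, 60)),
               class = "pcmfrap_invalid_argument")
})

test_that("initial rate recovers known slopes", {
  tt <- c(-10, seq(0, 90, 10))
  lin <- make_curve(tt, pmax(0, 0.02 * tt))
  r <- initial_rate(lin, window = 60)
  expect_equal(r$slope, 0.02, tolerance = 1e-12)

  ## saturating curve sampled every 10 s over the first minute
  ts <- seq(0, 60, 10)
  sat <- make_curve(ts, 1 - exp(-0.01 * ts))
  expect_equal(initial_rate(sat, 60)$slope, 0.0075, tolerance = 1e-3)

  expect_error(initial_rate(make_curve(c(0, 10), c(0, 1)), 5),
               class = "pcmfrap_too_few_samples")
})

test_that("initial rate is shift-invariant and scale-linear", {
  set.seed(3)
  tt <- seq(0, 60, 5)
  y <- 1 - exp(-0.03 * tt) + rnorm(length(tt), 0, 0.01)
  base <- initial_rate(make_curve(tt, y))$slope
  expect_equal(initial_rate(make_curve(tt, y + 5))$slope, base,
               tolerance = 1e-10)
  expect_equal(initial_rate(make_curve(tt, 3 * y))$slope, 3 * base,
               tolerance = 1e-10)
})

test_that("peripheral curves rescale to the central pre-bleach level", {
  tt <- c(-20, -10, 10, 20)
  cen <- make_curve(tt, c(1, 1, 0.2, 0.4))
  per <- make_curve(tt, c(0.2, 0.2, 0.01, 0.05))
  out <- rescale_peripheral(per, cen)
  expect_equal(out$values, per$values * 5)
  expect_equal(mean(out$values[tt < 0]), mean(cen$values[tt < 0]))
  same <- rescale_peripheral(cen, cen)
  expect_equal(same$values, cen$values)
  zero <- make_curve(tt, c(0, 0, 1, 2))
  expect_error(rescale_peripheral(zero, cen),
               class = "pcmfrap_normalization_error")
})

test_that("acceleration index is the quadratic coefficient", {
  tt <- seq(0, 100, 10)
  expect_lt(abs(acceleration_index(make_curve(tt, 0.3 * tt), 100)), 1e-12)
  expect_equal(acceleration_index(make_curve(tt, tt^2), 100), 1,
               tolerance = 1e-9)
  expect_equal(acceleration_index(
    make_curve(tt, 5 - 2 * tt + 0.4 * tt^2), 100), 0.4, tolerance = 1e-9)
  expect_error(acceleration_index(make_curve(c(0, 10, 20), c(0, 1, 2)),
                                  15),
               class = "pcmfrap_too_few_samples")
})

test_that("double-bleach comparison requires exactly two bleaches", {
  tt <- c(-10, seq(0, 170, 10), seq(180, 300, 10))
  y <- numeric(length(tt))
  post1 <- tt >= 0 & tt < 180
  y[post1] <- 0.01 * tt[post1]
  y[tt >= 180] <- 0.012 * (tt[tt >= 180] - 180)
  cv <- make_curve(tt, y, bleach_times = c(0, 180))
  res <- double_bleach_compare(cv)
  expect_equal(res$rate1$slope, 0.01, tolerance = 1e-9)
  expect_equal(res$rate2$slope, 0.012, tolerance = 1e-9)
  expect_equal(res$ratio, 1.2, tolerance = 1e-9)
  expect_error(double_bleach_compare(make_curve(tt, y)),
               class = "pcmfrap_invalid_argument")
})

test_that("spread index measures FWHM growth", {
  tt <- c(-10, seq(10, 100, 10))
  widths <- c(NA, 0.3 + 0.001 * seq(10, 100, 10))
  ps <- make_profile_set(tt, widths = pmax(widths, 0.31, na.rm = TRUE))
  ## the constructed widths are exact FWHMs of Gaussian-shaped profiles
  si <- spread_index(ps)
  expect_equal(si$slope, 0.001, tolerance = 0.05)

  const <- make_profile_set(tt, widths = rep(0.5, length(tt)))
  expect_lt(abs(spread_index(const)$slope), 1e-6)

  ## widths uncomputable at most time points
  toowide <- make_profile_set(tt, widths = rep(1e3, length(tt)))
  expect_error(spread_index(toowide),
               class = "pcmfrap_width_uncomputable")
})

test_that("mode classification follows the declared decision rule", {
  tt <- c(-10, seq(10, 120, 10))
  nt <- length(tt)
  ## spreading, initially narrow: inside-out
  ps_flux <- make_profile_set(tt, widths = 0.4 + 0.004 * pmax(tt, 0))
  expect_identical(classify_mode(ps_flux)$call, "inside_out")
  ## constant shape at all times: distributed
  ps_dist <- make_profile_set(tt, amplitudes = 1 - exp(-0.02 *
                                                         pmax(tt, 1)))
  ps_dist$prebleach <- ps_dist$profiles[[1]]
  ps_dist$prebleach$values <- ps_dist$prebleach$values /
    max(ps_dist$prebleach$values)
  expect_identical(classify_mode(ps_dist)$call, "distributed")
  expect_error(classify_mode(make_profile_set(c(-10, 10, 20))),
               class = "pcmfrap_too_few_samples")
})

test_that("a pure-noise movie is classified as indeterminate", {
  p <- mechanistic_params("flux", n_rings = 2, J = 0, a = 0, k_loss = 0)
  st <- simulate_ring_chain(p, c(-15, -5, seq(10, 40, 10)),
                            bleach_event(0), init = c(0, 0))
  mv <- render_movie(st, optics_params(), seed = 9,
                     positions = matrix(rep(c(7, 7, 21, 21), 2), 4,
                                        byrow = FALSE),
                     field_um = c(28, 28))
  mv$positions <- matrix(c(7, 7, 7, 21, 21, 7, 21, 21), 4, 2,
                         byrow = TRUE)
  ps <- tryCatch(
    profile_frap_movie(mv, opts = profiling_options(min_n = 4L)),
    pcmfrap_error = function(e) NULL)
  if (is.null(ps)) succeed() else {
    expect_identical(classify_mode(ps)$call, "indeterminate")
  }
})
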