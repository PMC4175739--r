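gauss_img <- function(sigma = 0.2, pixel = 0.028, n = 251, peak = 100,
                      offset = 0) {
  xs <- (seq_len(n) - 0.5) * pixel
  c0 <- (n / 2) * pixel
  d2 <- outer((xs - c0)^2, (xs - c0)^2, `+`)
  image_stack(peak * exp(-d2 / (2 * sigma^2)) + offset, pixel)
}

test_that("the default ring grid reproduces the standard geometry", {
  g <- ring_grid()
  expect_identical(g$n_rings, 107L)
  expect_equal(g$spacing, 0.028)
  ## super-resolution variants are just finer grids
  expect_identical(ring_grid(0.011, 3.28)$n_rings, 298L)
  expect_error(ring_grid(0.1, 0.05), class = "pcmfrap_invalid_argument")
})

test_that("upsampling replicates pixels and preserves the mean exactly", {
  one <- image_stack(matrix(7, 1, 1), 0.14)
  up <- upsample_image(one, 5L)
  expect_equal(dim(up$pixels), c(5L, 5L))
  expect_true(all(up$pixels == 7))
  expect_equal(up$pixel_size, 0.028)

  img <- image_stack(matrix(runif(64), 8, 8), 0.14)
  expect_identical(upsample_image(img, 1L), img)
  up3 <- upsample_image(img, 3L)
  expect_identical(mean(up3$pixels), mean(img$pixels))
  ## block structure: each parent pixel value appears factor^2 times
  expect_equal(up3$pixels[1:3, 1:3], matrix(img$pixels[1, 1], 3, 3))
  expect_error(upsample_image(img, 0), class = "pcmfrap_invalid_argument")
})

test_that("centre detection finds symmetric spots and weighted centroids", {
  img <- gauss_img(n = 101)
  ctr <- find_center(img)
  expect_lt(max(abs(ctr - (101 / 2) * 0.028)), 0.1 * 0.028)

  ## 2x2 worked example: only the bright pixel passes a 0.5 threshold
  tiny <- image_stack(matrix(c(0, 0, 0, 8), 2, 2), 1)
  expect_equal(unname(find_center(tiny, 0.5)), c(1.5, 1.5))

  expect_error(find_center(image_stack(matrix(0, 4, 4), 1)),
               class = "pcmfrap_no_signal")
})

test_that("upsampling shifts no centroid", {
  set.seed(7)
  base <- gauss_img(sigma = 0.2, pixel = 0.14, n = 21, peak = 500)
  base$pixels <- base$pixels + matrix(rnorm(21 * 21, 20, 2), 21, 21)
  c1 <- find_center(base, background = 20)
  c2 <- find_center(upsample_image(base, 5L), background = 20)
  expect_lt(sqrt(sum((c1 - c2)^2)), 0.14)
})

test_that("radial profile averages rings correctly", {
  flat <- image_stack(matrix(4.2, 201, 201), 0.028)
  ctr <- c(201 / 2, 201 / 2) * 0.028
  prof <- radial_profile(flat, ctr, ring_grid(span = 2.5))
  valid <- is.finite(prof$values)
  expect_true(any(valid))
  expect_true(all(abs(prof$values[valid] - 4.2) < 1e-12))
  ## rings beyond the field are flagged invalid, not fabricated
  prof_far <- radial_profile(flat, c(0.3, 0.3), ring_grid(span = 2.5))
  expect_true(anyNA(prof_far$values))

  ## noise-free Gaussian spot vs fine-grid analytic ring averaging
  img <- gauss_img(pixel = 0.014, n = 501)
  ctr <- find_center(img)
  grid <- ring_grid(span = 1.5)
  prof <- radial_profile(img, ctr, grid)
  oracle <- oracle_ring_average(function(r) 100 * exp(-r^2 / (2 * 0.2^2)),
                                grid, extent = 1.6)
  ok <- is.finite(prof$values) & is.finite(oracle)
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(prof$values[ok] - oracle[ok])), 0.01 * 100)

  expect_error(radial_profile(img, c(-1, 2), grid),
               class = "pcmfrap_outside_field")
})

test_that("background estimation and subtraction behave as constructed", {
  flat <- image_stack(matrix(17, 61, 61), 0.14)
  ctr <- c(61 / 2, 61 / 2) * 0.14
  expect_equal(estimate_cytosol_background(flat, ctr, 1.2, 1.5), 17)

  ## a bright spot entirely inside the annulus inner radius is ignored
  spot <- gauss_img(sigma = 0.15, pixel = 0.14, n = 61, peak = 300,
                    offset = 17)
  expect_lt(abs(estimate_cytosol_background(spot, ctr, 2, 3) - 17), 0.05)

  ## median accuracy under Gaussian noise: 3 * 1.2533 * s / sqrt(n)
  set.seed(11)
  s <- 4
  noisy <- image_stack(matrix(rnorm(61 * 61, 50, s), 61, 61), 0.14)
  sel_n <- sum({
    xs <- (seq_len(61) - 0.5) * 0.14
    d <- sqrt(outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`))
    d >= 1.2 & d < 2.5
  })
  expect_gt(sel_n, 500)
  est <- estimate_cytosol_background(noisy, ctr, 1.2, 2.5)
  expect_lt(abs(est - 50), 3 * 1.2533 * s / sqrt(sel_n))
  expect_error(estimate_cytosol_background(flat, ctr, 1.5, 1.2),
               class = "pcmfrap_invalid_argument")

  prof <- radial_profile(flat, ctr, ring_grid(span = 2))
  expect_equal(subtract_background(prof, 0)$values, prof$values)
  zeroed <- subtract_background(prof, 17)
  expect_true(all(abs(zeroed$values[is.finite(zeroed$values)]) < 1e-12))
  expect_error(subtract_background(zeroed, 1),
               class = "pcmfrap_double_subtraction")
})

test_that("normalize-and-mirror yields a symmetric unit-peak profile", {
  img <- gauss_img()
  prof <- subtract_background(
    radial_profile(img, find_center(img), ring_grid(span = 1.5)), 0)
  nm <- normalize_and_mirror(prof)
  expect_equal(max(nm$values, na.rm = TRUE), 1)
  expect_true(nm$flags$mirrored && nm$flags$normalized)
  m <- length(nm$values)
  expect_identical(nm$values, rev(nm$values))
  expect_identical(nm$radii, -rev(nm$radii))
  ## idempotent on an already normalized, mirrored profile
  expect_equal(normalize_and_mirror(nm)$values, nm$values)

  flat0 <- subtract_background(
    radial_profile(image_stack(matrix(3, 101, 101), 0.028),
                   c(1.4, 1.4), ring_grid(span = 1)), 3)
  expect_error(normalize_and_mirror(flat0),
               class = "pcmfrap_normalization_error")
  expect_error(normalize_and_mirror(
    radial_profile(img, find_center(img), ring_grid(span = 1.5))),
    class = "pcmfrap_invalid_argument")  # background not yet subtracted
})

test_that("profile averaging enforces the centrosome minimum and grids", {
  profs <- replicate(10, make_triangle_profile(0.5), simplify = FALSE)
  avg <- average_profiles(profs)
  expect_equal(avg$values, profs[[1]]$values)
  expect_error(average_profiles(profs[1:9]),
               class = "pcmfrap_too_few_profiles")

  a <- make_triangle_profile(0.4)
  b <- make_triangle_profile(0.8)
  avg2 <- average_profiles(list(a, b), min_n = 2)
  expect_equal(avg2$values, (a$values + b$values) / 2)
  other <- make_triangle_profile(0.4, ring_grid(span = 2))
  expect_error(average_profiles(list(a, other), min_n = 2),
               class = "pcmfrap_grid_mismatch")
})

test_that("pre-bleach peak normalization rescales recovery profiles", {
  pre <- make_shape_profile(function(r) exp(-r^2 / 0.08), 2)
  rec <- make_shape_profile(function(r) exp(-r^2 / 0.08), 1)
  out <- normalize_to_prebleach_peak(rec, pre)
  expect_equal(out$values, pre$values, tolerance = 1e-12)
  same <- normalize_to_prebleach_peak(pre, pre)
  expect_equal(same$values, pre$values)
  zero <- make_shape_profile(function(r) 0 * r)
  expect_error(normalize_to_prebleach_peak(zero, pre),
               class = "pcmfrap_normalization_error")
})

test_that("FWHM is exact on known shapes and errors when unbounded", {
  ## Gaussian of sd 0.2 um: width 2.3548 * sigma
  g <- make_shape_profile(function(r) exp(-r^2 / (2 * 0.2^2)))
  gm <- normalize_and_mirror(g)
  expect_lt(abs(profile_fwhm(gm) - 2.3548 * 0.2), 0.028)
  ## triangle reaching half-max at +/- w0/2
  tri <- make_triangle_profile(0.7)
  ## discrete ring midpoints shift the apex by half a spacing
  expect_equal(profile_fwhm(tri), 0.7 + 0.028 / 2, tolerance = 1e-9)
  ## monotone non-crossing profile has no bounded width
  flat <- make_triangle_profile(1e3)
  expect_error(profile_fwhm(flat), class = "pcmfrap_unbounded_width")
  expect_error(profile_fwhm(g), class = "pcmfrap_invalid_argument")
})

test_that("width comparison against a bead reference separates scales", {
  opt <- optics_params(poisson_noise = FALSE, read_noise_sd = 0,
                       background = 0)
  bead <- simulate_bead_image(opt, seed = NULL)
  bp <- normalize_and_mirror(subtract_background(radial_profile(
    upsample_image(bead, 5L), find_center(bead), ring_grid(span = 1.8)),
    0))
  expect_equal(compare_to_reference(bp, bp), 1)

  ## a point-like toroid images at the same width as the bead
  p <- mechanistic_params("flux", n_rings = 2, ring_width = 0.05, J = 0,
                          a = 0, k_loss = 0)
  st <- simulate_ring_chain(p, c(0, 1), init = c(0, 1))
  tor <- render_movie(st, opt)
  ti <- image_stack(tor$frames[[1]], tor$pixel_size)
  tp <- normalize_and_mirror(subtract_background(radial_profile(
    upsample_image(ti, 5L), find_center(ti), ring_grid(span = 1.8)), 0))
  expect_lt(abs(compare_to_reference(tp, bp) - 1), 0.1)

  ## an extended PCM-like distribution is clearly wider than the bead
  broad <- make_triangle_profile(0.9)
  broad$flags$normalized <- TRUE
  expect_gt(compare_to_reference(broad, bp), 1)
})
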