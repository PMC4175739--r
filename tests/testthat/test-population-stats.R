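test_that("boxed-region quantification is background-corrected and linear", {
  flat <- image_stack(matrix(7.5, 40, 40), 0.14)
  expect_equal(quantify_centrosome_box(flat, c(5, 13, 5, 13),
                                       c(20, 30, 20, 30)), 0)

  ## spot of known integrated signal on a uniform background
  opt <- optics_params(poisson_noise = FALSE, read_noise_sd = 0,
                       background = 25)
  p <- mechanistic_params("flux", n_rings = 2, ring_width = 0.1, J = 0,
                          a = 0, k_loss = 0)
  for (M in c(1, 2)) {
    st <- simulate_ring_chain(p, c(0, 1), init = c(M, 0))
    mv <- render_movie(st, opt)
    img <- image_stack(mv$frames[[1]], mv$pixel_size)
    n <- nrow(img$pixels)
    ctr_px <- round(mv$positions[1, ] / mv$pixel_size)
    box <- c(ctr_px[2] - 10, ctr_px[2] + 10, ctr_px[1] - 10,
             ctr_px[1] + 10)
    got <- quantify_centrosome_box(img, box,
                                   list(center = mv$positions[1, ],
                                        inner_r = 2.2, outer_r = 2.8))
    expect_equal(got, opt$gain * M, tolerance = 0.01)
    if (M == 1) first <- got else expect_equal(got, 2 * first,
                                               tolerance = 1e-6)
  }

  expect_error(quantify_centrosome_box(flat, c(0, 5, 1, 5),
                                       c(20, 30, 20, 30)),
               class = "pcmfrap_region_out_of_bounds")
  expect_error(quantify_centrosome_box(flat, c(5, 13, 5, 13),
                                       c(10, 20, 10, 20)),
               class = "pcmfrap_invalid_argument")  # overlap
})

test_that("brain averages reduce centrosomes to one point per brain", {
  tab <- data.frame(brain_id = c("b1", "b1", "b2"), genotype = "wt",
                    phase = "mitotic", marker = "m",
                    intensity = c(2, 4, 10))
  br <- brain_averages(tab)
  expect_equal(nrow(br), 2L)
  expect_equal(br$mean_intensity[br$brain_id == "b1"], 3)
  expect_equal(br$n, c(2L, 1L))

  set.seed(5)
  big <- simulate_fixed_cell_table(
    data.frame(genotype = c("wt", "mut"), phase = "mitotic",
               mean = c(100, 50), sd = c(10, 5)),
    n_brains = 3, cells_per_brain = 7, seed = 2)
  br2 <- brain_averages(big)
  expect_equal(nrow(br2), 6L)
  one <- big[big$brain_id == br2$brain_id[1], "intensity"]
  expect_equal(br2$mean_intensity[1], mean(one))
  expect_error(brain_averages(big[0, ]),
               class = "pcmfrap_invalid_argument")
  expect_error(brain_averages(data.frame(intensity = 1)),
               class = "pcmfrap_missing_column")
})

test_that("fixed-cell tables honour group structure and truncation", {
  specs <- data.frame(genotype = "wt",
                      phase = c("interphase", "mitotic"),
                      mean = c(100, 100), sd = c(10, 10))
  expect_equal(nrow(simulate_fixed_cell_table(specs, 0, 10, seed = 1)),
               0L)
  tab <- simulate_fixed_cell_table(specs, 5, 40, seed = 1)
  expect_equal(as.integer(table(tab$phase)), c(200L, 200L))
  expect_true(all(tab$intensity >= 0))
  ## central-limit check on the group mean
  m <- mean(tab$intensity[tab$phase == "interphase"])
  expect_lt(abs(m - 100), 3 * 10 / sqrt(200))
  ## exchangeability: identically specified groups agree within noise
  m2 <- mean(tab$intensity[tab$phase == "mitotic"])
  expect_lt(abs(m - m2), 3 * sqrt(2) * 10 / sqrt(200))
  ## hard truncation visible at small mean
  low <- simulate_fixed_cell_table(
    data.frame(genotype = "wt", phase = "interphase", mean = 1, sd = 10),
    4, 50, seed = 3)
  expect_true(all(low$intensity >= 0))
  expect_error(simulate_fixed_cell_table(specs[0, ], 2, 2),
               class = "pcmfrap_invalid_argument")
})

test_that("Mann-Whitney matches worked examples and symmetry", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_true(mw$exact)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)

  set.seed(8)
  a <- rnorm(5); b <- rnorm(6)
  ua <- mann_whitney_u(a, b)$statistic
  ub <- mann_whitney_u(b, a)$statistic
  expect_equal(ua + ub, length(a) * length(b))

  expect_error(mann_whitney_u(numeric(0), 1),
               class = "pcmfrap_invalid_argument")
})

test_that("exact Mann-Whitney p equals brute-force enumeration", {
  set.seed(13)
  for (n1 in 1:6) for (n2 in 1:6) {
    for (rep in 1:3) {
      a <- sample(seq_len(50), n1)
      b <- sample(setdiff(seq_len(50), a), n2)
      got <- mann_whitney_u(a, b)
      expect_true(got$exact)
      expect_equal(got$p_value, oracle_mw_p(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
  ## and agrees with the reference implementation's exact p
  set.seed(14)
  for (rep in 1:5) {
    a <- runif(4); b <- runif(4)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large or tied samples fall back to the corrected normal approximation", {
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  got <- mann_whitney_u(a, b)
  expect_false(got$exact)
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  ## ties force the approximation even for small samples
  tied <- mann_whitney_u(c(1, 2, 2), c(2, 3))
  expect_false(tied$exact)
  ref2 <- stats::wilcox.test(c(1, 2, 2), c(2, 3), correct = TRUE,
                             exact = FALSE)
  expect_equal(tied$p_value, ref2$p.value, tolerance = 1e-10)
})

test_that("paired rate comparison reproduces the closed-form t", {
  res <- paired_rate_comparison(data.frame(
    control_rate = c(1.0, 0.8, 1.2),
    experimental_rate = c(0.5, 0.4, 0.7)))
  expect_equal(res$percent_reduction, 100 * (1 - 1.6 / 3), tolerance = 1e-9)
  expect_equal(res$t, 14.0, tolerance = 1e-9)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value,
               stats::t.test(c(1.0, 0.8, 1.2), c(0.5, 0.4, 0.7),
                             paired = TRUE)$p.value, tolerance = 1e-9)

  expect_warning(
    deg <- paired_rate_comparison(data.frame(
      control_rate = rep(1, 4), experimental_rate = rep(0.25, 4))),
    class = "pcmfrap_degenerate_variance")
  expect_true(deg$degenerate)
  expect_equal(deg$percent_reduction, 75)
  expect_true(is.na(deg$t))

  expect_error(paired_rate_comparison(data.frame(
    control_rate = 1, experimental_rate = 0.5)),
    class = "pcmfrap_too_few_samples")
})

test_that("per-pair and ratio-of-means reductions differ as constructed", {
  pairs <- data.frame(control_rate = c(1, 2),
                      experimental_rate = c(0.9, 0.2))
  rom <- suppressWarnings(paired_rate_comparison(pairs))
  pp <- suppressWarnings(paired_rate_comparison(pairs, per_pair = TRUE))
  expect_equal(rom$percent_reduction, 100 * (1 - 1.1 / 3))
  expect_equal(pp$percent_reduction, 100 * (1 - mean(c(0.9, 0.1))))
})

test_that("aster percentages are simple per-group proportions", {
  tab <- data.frame(
    genotype = c(rep("wt", 11), rep("mutA", 15), rep("mutB", 58)),
    positive = c(rep(TRUE, 11), rep(FALSE, 15),
                 rep(c(TRUE, FALSE), c(32, 26))))
  res <- aster_percentage(tab)
  expect_equal(res$percent[res$genotype == "wt"], 100)
  expect_equal(res$percent[res$genotype == "mutA"], 0)
  expect_equal(res$percent[res$genotype == "mutB"], 55.2, tolerance = 1e-3)
  expect_equal(res$n[res$genotype == "mutB"], 58L)
  expect_error(aster_percentage(tab[0, ]),
               class = "pcmfrap_invalid_argument")
})
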