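## Fixed-cell and paired-rate population statistics.

#' Background-corrected centrosome intensity in a boxed region
#'
#' Sums intensity over a rectangular box around a centrosome and subtracts
#' the local cytoplasmic background (mean of a disjoint background region)
#' scaled by the box area.
#'
#' @param img An [image_stack()].
#' @param box Pixel rectangle `c(row1, row2, col1, col2)` (inclusive).
#' @param bg_region Either a pixel rectangle like `box`, or an annulus
#'   `list(center = c(x, y) um, inner_r, outer_r)`.
#' @return Background-corrected integrated intensity (counts).
#' @export
quantify_centrosome_box <- function(img, box, bg_region) {
  if (!inherits(img, "image_stack"))
    pcm_stop("invalid_argument", "'img' must be an image_stack")
  p <- img$pixels
  if (length(dim(p)) == 3L) p <- central_plane(p)
  check_rect <- function(b, what) {
    if (length(b) != 4L || any(b != round(b)))
      pcm_stop("invalid_argument",
               "'%s' must be c(row1, row2, col1, col2)", what)
    if (b[1] > b[2] || b[3] > b[4] || b[1] < 1 || b[3] < 1 ||
        b[2] > nrow(p) || b[4] > ncol(p))
      pcm_stop("region_out_of_bounds", "'%s' outside the image", what)
    b
  }
  box <- check_rect(box, "box")
  box_px <- p[box[1]:box[2], box[3]:box[4], drop = FALSE]
  if (is.list(bg_region)) {
    px <- img$pixel_size
    dx <- pixel_centers(ncol(p), px) - bg_region$center[[1]]
    dy <- pixel_centers(nrow(p), px) - bg_region$center[[2]]
    d <- sqrt(outer(dy^2, dx^2, `+`))
    sel <- d >= bg_region$inner_r & d < bg_region$outer_r
    if (!any(sel))
      pcm_stop("region_out_of_bounds", "background annulus is empty")
    rows <- row(p)[sel]; cols <- col(p)[sel]
    if (any(rows >= box[1] & rows <= box[2] & cols >= box[3] &
            cols <= box[4]))
      pcm_stop("invalid_argument", "background region overlaps the box")
    bg_mean <- mean(p[sel])
  } else {
    bg <- check_rect(bg_region, "bg_region")
    if (bg[1] <= box[2] && bg[2] >= box[1] && bg[3] <= box[4] &&
        bg[4] >= box[3])
      pcm_stop("invalid_argument", "background region overlaps the box")
    bg_mean <- mean(p[bg[1]:bg[2], bg[3]:bg[4]])
  }
  sum(box_px) - bg_mean * length(box_px)
}

#' Per-brain average centrosome intensities
#'
#' Collapses a per-centrosome table to one mean per (brain, genotype,
#' phase, marker): brains, not centrosomes, are the unit of analysis in
#' downstream group comparisons.
#'
#' @param table Data frame with columns `brain_id`, `genotype`, `phase`,
#'   `marker` (optional) and `intensity`, e.g. from
#'   [simulate_fixed_cell_table()].
#' @return Data frame of group means with centrosome counts `n`.
#' @export
brain_averages <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    pcm_stop("invalid_argument", "empty table")
  need <- c("brain_id", "genotype", "phase", "intensity")
  if (!all(need %in% names(table)))
    pcm_stop("missing_column", "table needs columns %s",
             paste(setdiff(need, names(table)), collapse = ", "))
  by <- table[, intersect(c("brain_id", "genotype", "phase", "marker"),
                          names(table)), drop = FALSE]
  ag <- aggregate(table$intensity, by = by, FUN = mean)
  names(ag)[ncol(ag)] <- "mean_intensity"
  ag$n <- aggregate(table$intensity, by = by, FUN = length)$x
  ag[order(ag$genotype, ag$phase, ag$brain_id), , drop = FALSE]
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. The statistic is
#' `U = sum over pairs of [a > b] + [a == b]/2` (midrank ties). The
#' two-sided p value is exact (doubled tail of the enumerated null
#' distribution, capped at 1) when `n1 + n2 <= 12` and the data contain no
#' ties, and otherwise uses the normal approximation with tie correction
#' and continuity correction.
#'
#' @param a,b Numeric vectors.
#' @return A list of class `"group_comparison"`: `statistic` (U of group
#'   `a`), `p_value`, `method`, `n` (group sizes), `exact`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value  # 1/3
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b))
    pcm_stop("invalid_argument", "both groups must be non-empty")
  if (any(!is.finite(c(a, b))))
    pcm_stop("invalid_argument", "values must be finite")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- (n1 + n2 <= 12L) && !ties
  if (exact) {
    lower <- pwilcox(U, n1, n2)                   # P(U <= u); U integral
    upper <- 1 - pwilcox(U - 1, n1, n2)           # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "Mann-Whitney U (exact)"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(c(a, b))
    sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) /
                              (nn * (nn - 1)))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)         # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  structure(list(statistic = U, p_value = p, method = method,
                 n = c(n1 = n1, n2 = n2), exact = exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, n = (%s), p = %.4g\n", x$method,
              x$statistic, paste(x$n, collapse = ", "), x$p_value))
  invisible(x)
}

#' Paired control/experimental rate comparison
#'
#' Summarizes a paired bleaching design: the percent reduction of the
#' experimental rates relative to the controls, and a paired two-sided
#' Student's t test on the per-pair differences.
#'
#' The reduction is computed from the ratio of group means by default
#' (`per_pair = FALSE`) or as the mean of per-pair ratios.
#'
#' @param pairs Data frame with columns `control_rate` and
#'   `experimental_rate` (e.g. from [simulate_paired_rates()]).
#' @param per_pair Average per-pair ratios instead of taking the ratio of
#'   means.
#' @return List of class `"paired_rate_comparison"`: `percent_reduction`,
#'   `t`, `df`, `p_value`, `n_pairs`, `degenerate` (TRUE when the
#'   differences have zero variance, in which case `t` and `p_value` are
#'   `NA` and a warning of class `pcmfrap_degenerate_variance` is issued).
#' @export
paired_rate_comparison <- function(pairs, per_pair = FALSE) {
  need <- c("control_rate", "experimental_rate")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs)))
    pcm_stop("invalid_argument",
             "'pairs' needs columns control_rate and experimental_rate")
  ctrl <- pairs$control_rate
  expt <- pairs$experimental_rate
  if (any(!is.finite(c(ctrl, expt))))
    pcm_stop("invalid_argument", "rates must be finite")
  if (mean(ctrl) <= 0)
    pcm_stop("invalid_argument", "mean control rate must be > 0")
  n <- nrow(pairs)
  reduction <- if (per_pair) 100 * (1 - mean(expt / ctrl))
  else 100 * (1 - mean(expt) / mean(ctrl))
  if (n < 2L)
    pcm_stop("too_few_samples", "need at least 2 pairs for the t test")
  d <- ctrl - expt
  s <- sd(d)
  degenerate <- s <= max(abs(d), 1) * .Machine$double.eps * 64
  if (degenerate) {
    out <- structure(list(percent_reduction = reduction, t = NA_real_,
                          df = n - 1L, p_value = NA_real_, n_pairs = n,
                          degenerate = TRUE),
                     class = "paired_rate_comparison")
    pcm_warn("degenerate_variance",
             "pair differences have zero variance; t test undefined")
    return(out)
  }
  tval <- mean(d) / (s / sqrt(n))
  structure(list(percent_reduction = reduction, t = tval, df = n - 1L,
                 p_value = 2 * pt(-abs(tval), n - 1L), n_pairs = n,
                 degenerate = FALSE),
            class = "paired_rate_comparison")
}

#' @export
print.paired_rate_comparison <- function(x, ...) {
  cat(sprintf("Paired rates (%d pairs): %.1f%% reduction", x$n_pairs,
              x$percent_reduction))
  if (x$degenerate) cat(" [degenerate variance; t undefined]\n")
  else cat(sprintf(", paired t = %.3g (df %d), p = %.4g\n", x$t, x$df,
                   x$p_value))
  invisible(x)
}

#' Percentage of cells with centrosomal asters, by group
#'
#' A cell counts as positive when at least one of its centrosomes shows a
#' detectable astral microtubule array.
#'
#' @param table Data frame with a grouping column `genotype` and a logical
#'   column `positive`.
#' @return Data frame with `genotype`, `n`, `n_positive`, `percent`.
#' @export
#' @examples
#' aster_percentage(data.frame(genotype = "wt",
#'                             positive = rep(TRUE, 11)))
aster_percentage <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    pcm_stop("invalid_argument", "empty table")
  if (!all(c("genotype", "positive") %in% names(table)))
    pcm_stop("missing_column", "table needs 'genotype' and 'positive'")
  ag <- aggregate(table$positive,
                  by = list(genotype = table$genotype),
                  FUN = function(x) c(n = length(x), pos = sum(x)))
  data.frame(genotype = ag$genotype, n = ag$x[, "n"],
             n_positive = ag$x[, "pos"],
             percent = 100 * ag$x[, "pos"] / ag$x[, "n"])
}
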