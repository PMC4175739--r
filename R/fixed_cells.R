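## Synthetic fixed-cell quantification tables.

#' Simulate a per-centrosome fixed-cell quantification table
#'
#' Fabricates background-corrected centrosome intensities for groups defined
#' by (genotype, phase, marker), emulating the population structure of a
#' fixed-brain experiment in which several centrosomes are measured per
#' brain and brains are later the unit of analysis (see [brain_averages()]).
#' Intensities are drawn from a normal distribution truncated at zero with
#' the per-group mean and standard deviation.
#'
#' @param group_specs Data frame with columns `genotype`, `phase`, `mean`,
#'   `sd` and optionally `marker` (default `"marker"`). One row per group.
#' @param n_brains Brains per group.
#' @param cells_per_brain Centrosomes measured per brain.
#' @param seed Integer seed, or `NULL`.
#' @return A data frame with columns `centrosome_id`, `brain_id`,
#'   `genotype`, `phase`, `marker`, `intensity`; exactly
#'   `n_brains * cells_per_brain` rows per group.
#' @export
#' @examples
#' specs <- data.frame(genotype = "wt", phase = c("interphase", "mitotic"),
#'                     mean = c(40, 200), sd = c(10, 50))
#' tab <- simulate_fixed_cell_table(specs, n_brains = 5,
#'                                  cells_per_brain = 40, seed = 1)
#' table(tab$phase)
simulate_fixed_cell_table <- function(group_specs, n_brains,
                                      cells_per_brain, seed = NULL) {
  if (!is.data.frame(group_specs) || nrow(group_specs) == 0L)
    pcm_stop("invalid_argument", "no groups specified")
  need <- c("genotype", "phase", "mean", "sd")
  if (!all(need %in% names(group_specs)))
    pcm_stop("invalid_argument", "'group_specs' needs columns %s",
             paste(need, collapse = ", "))
  if (any(group_specs$sd < 0))
    pcm_stop("invalid_argument", "group sds must be >= 0")
  if (n_brains < 0 || cells_per_brain < 0)
    pcm_stop("invalid_argument", "counts must be >= 0")
  if (!"marker" %in% names(group_specs)) group_specs$marker <- "marker"
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483629L)

  n_per_group <- n_brains * cells_per_brain
  out <- lapply(seq_len(nrow(group_specs)), function(g) {
    spec <- group_specs[g, ]
    vals <- numeric(0)
    while (length(vals) < n_per_group) {       # truncate at 0 by rejection
      draw <- rnorm(max(n_per_group, 16L), spec$mean, spec$sd)
      vals <- c(vals, draw[draw >= 0])
    }
    if (n_per_group == 0L)
      return(data.frame(centrosome_id = character(0),
                        brain_id = character(0), genotype = character(0),
                        phase = character(0), marker = character(0),
                        intensity = numeric(0)))
    data.frame(
      centrosome_id = sprintf("%s_%s_b%02d_c%03d", spec$genotype,
                              spec$phase, rep(seq_len(n_brains),
                                              each = cells_per_brain),
                              rep(seq_len(cells_per_brain), n_brains)),
      brain_id = sprintf("%s_%s_b%02d", spec$genotype, spec$phase,
                         rep(seq_len(n_brains), each = cells_per_brain)),
      genotype = spec$genotype, phase = spec$phase, marker = spec$marker,
      intensity = vals[seq_len(n_per_group)])
  })
  do.call(rbind, out)
}

#' Simulate paired control/experimental recovery rates
#'
#' Emulates a paired photobleaching design in which, within each embryo, one
#' centrosome near a perturbation (experimental) and one far from it
#' (control) are bleached and their initial recovery rates measured. Control
#' rates vary between pairs; experimental rates are the control rate scaled
#' by `1 - reduction` with multiplicative noise.
#'
#' @param n_pairs Number of centrosome pairs.
#' @param control_mean Mean control rate (intensity/s).
#' @param control_cv Between-pair coefficient of variation of the control
#'   rate.
#' @param reduction Implanted fractional rate reduction (0.75 = 75%).
#' @param noise_cv Multiplicative noise on the experimental/control ratio.
#' @param seed Integer seed, or `NULL`.
#' @return Data frame with `embryo_id`, `control_rate`, `experimental_rate`.
#' @seealso [paired_rate_comparison()]
#' @export
simulate_paired_rates <- function(n_pairs = 10, control_mean = 1,
                                  control_cv = 0.1, reduction = 0.75,
                                  noise_cv = 0.1, seed = NULL) {
  if (n_pairs < 1) pcm_stop("invalid_argument", "'n_pairs' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483629L)
  ctrl <- pmax(control_mean * (1 + rnorm(n_pairs, 0, control_cv)), 1e-8)
  expt <- pmax(ctrl * (1 - reduction) * (1 + rnorm(n_pairs, 0, noise_cv)), 0)
  data.frame(embryo_id = sprintf("embryo%02d", seq_len(n_pairs)),
             control_rate = ctrl, experimental_rate = expt)
}
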