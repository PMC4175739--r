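## Orchestration: configuration, seeds, manifests, end-to-end runs.

## strict config merging: unknown keys are errors, not warnings
merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    pcm_stop("config_error", "'%s' must be a mapping", path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    pcm_stop("config_error", "unknown %s key(s): %s", path,
             paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.data.frame(defaults[[k]]))
      defaults[[k]] <- user[[k]]
    else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste(path, k, sep = "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

frap_config_defaults <- function() {
  list(
    seed = 1L,
    model = list(kind = "flux", n_rings = 15L, ring_width = 0.1,
                 J = 1, a = 0.08, k_loss = 0.002, k_ex = 0.02,
                 rho = NULL),
    optics = list(psf_sigma = 0.25, camera_pixel = 0.14, gain = 16000,
                  background = 100, read_noise_sd = 3,
                  poisson_noise = TRUE),
    movie = list(frame_times = default_frame_times(),
                 n_centrosomes = 10L, spacing_um = 7),
    bleach = list(times = 0, radius = 1.6, efficiency = 0.95),
    grid = list(spacing = 0.028, span = 3.02),
    roi = list(central = c(0.028, 0.14), peripheral = c(0.62, 0.73)),
    profiling = list(upsample = 5L, threshold_frac = 0.5,
                     bg_annulus = c(2.0, 2.8), crop_halfwidth = 3.1,
                     min_n = 10L, normalize_first = TRUE),
    thresholds = list(fwhm_ratio = 0.8, shape_dev = 0.05, t_stat = 2),
    kinetics = list(rate_window = 60, accel_window = 120),
    output = list(dir = NULL, write_movie = TRUE, prefix = "frap"))
}

#' Read a pipeline configuration file
#'
#' YAML or JSON, validated strictly against the pipeline defaults: unknown
#' keys raise a configuration error.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`), or `NULL` for
#'   the defaults.
#' @param defaults Default tree the file is merged into.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL,
                            defaults = frap_config_defaults()) {
  if (is.null(path)) return(defaults)
  if (!file.exists(path))
    pcm_stop("missing_file", "no such config: %s", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  merge_config(defaults, user)
}

config_params <- function(cfg) {
  m <- cfg$model
  if (identical(m$kind, "flux"))
    mechanistic_params("flux", n_rings = m$n_rings,
                       ring_width = m$ring_width, J = m$J, a = m$a,
                       k_loss = m$k_loss)
  else if (identical(m$kind, "distributed"))
    mechanistic_params("distributed", n_rings = m$n_rings,
                       ring_width = m$ring_width, k_ex = m$k_ex,
                       rho = if (is.null(m$rho)) NULL else
                         as.numeric(m$rho))
  else pcm_stop("config_error", "model.kind must be flux or distributed")
}

config_bleaches <- function(cfg) {
  lapply(as.numeric(cfg$bleach$times), function(tt)
    bleach_event(tt, radius = cfg$bleach$radius,
                 efficiency = cfg$bleach$efficiency))
}

## manifest: config echo plus md5 checksums of every output file
build_manifest <- function(cfg, files) {
  files <- files[file.exists(files)]
  list(config = cfg,
       package_version = as.character(utils::packageVersion("pcmfrap")),
       checksums = as.list(tools::md5sum(files)))
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the simulate-profile-kinetics pipeline
#'
#' Simulates a movie under the configured mechanism (or reads one from
#' `input`), analyses it with [analyze_frap()], and writes the movie
#' (TIFF + sidecar), profile CSV, a kinetics report (JSON, with every
#' threshold and seed echoed) and a run manifest with per-file checksums.
#' Reruns with identical configuration and seed produce byte-identical
#' outputs.
#'
#' @param config A configuration list (see [read_run_config()]) or a path
#'   to a YAML/JSON config file.
#' @param input Optional path prefix of an existing movie (from
#'   [write_frap_movie()]); when given, simulation is skipped.
#' @return A list of class `"frap_report"`: the analysis, report list,
#'   manifest and output paths.
#' @export
run_frap_pipeline <- function(config = NULL, input = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
  else merge_config(frap_config_defaults(), config)
  if (is.null(cfg$optics$camera_pixel) ||
      !is.numeric(cfg$optics$camera_pixel))
    pcm_stop("config_error", "optics.camera_pixel is required")
  seed <- as.integer(cfg$seed)

  movie <- if (!is.null(input)) read_frap_movie(input)
  else {
    params <- config_params(cfg)
    optics <- do.call(optics_params, cfg$optics)
    simulate_frap_movie(
      params, frame_times = as.numeric(cfg$movie$frame_times),
      bleaches = config_bleaches(cfg),
      n_centrosomes = cfg$movie$n_centrosomes, optics = optics,
      spacing_um = cfg$movie$spacing_um,
      seed = stage_seed(seed, "simulate"))
  }

  ana <- analyze_frap(
    movie,
    grid = ring_grid(cfg$grid$spacing, cfg$grid$span),
    roi = roi_spec(cfg$roi$central, cfg$roi$peripheral),
    opts = do.call(profiling_options, cfg$profiling),
    thresholds = do.call(mode_thresholds, cfg$thresholds),
    rate_window = cfg$kinetics$rate_window,
    accel_window = cfg$kinetics$accel_window)

  report <- list(
    mode_call = ana$mode$call,
    evidence = ana$mode$evidence,
    thresholds = ana$thresholds,
    central_rate = ana$central_rate$slope %||% NA,
    peripheral_rate = ana$peripheral_rate$slope %||% NA,
    rate_ratio = ana$rate_ratio,
    peripheral_acceleration = ana$peripheral_acceleration,
    fwhm_slope = if (is.null(ana$spread)) NA else ana$spread$slope,
    double_bleach = if (!is.null(ana$double_bleach)) list(
      central_ratio = ana$double_bleach$central$ratio,
      peripheral_ratio = ana$double_bleach$peripheral$ratio),
    seed = seed,
    n_centrosomes = ana$profiles$n_centrosomes)

  paths <- character(0)
  if (!is.null(cfg$output$dir)) {
    dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
    prefix <- file.path(cfg$output$dir, cfg$output$prefix)
    if (isTRUE(cfg$output$write_movie) && is.null(input))
      paths <- c(paths, write_frap_movie(movie, prefix))
    paths <- c(paths, write_profile_csv(ana$profiles,
                                        paste0(prefix,
                                               "_profiles.csv")))
    paths <- c(paths, write_report(report,
                                   paste0(prefix, "_kinetics.json")))
  }
  manifest <- build_manifest(cfg, paths)
  if (!is.null(cfg$output$dir))
    paths <- c(paths, write_report(
      manifest, file.path(cfg$output$dir,
                          paste0(cfg$output$prefix,
                                 "_manifest.json"))))
  structure(list(analysis = ana, report = report, manifest = manifest,
                 paths = paths, config = cfg),
            class = "frap_report")
}

#' @export
print.frap_report <- function(x, ...) {
  cat("FRAP pipeline report\n")
  print(x$analysis$mode)
  if (length(x$paths)) cat("  outputs:", paste(basename(x$paths),
                                               collapse = ", "), "\n")
  invisible(x)
}

fixed_config_defaults <- function() {
  list(
    seed = 1L,
    table = list(path = NULL,
                 groups = data.frame(
                   genotype = "wt", phase = c("interphase", "mitotic"),
                   mean = c(40, 200), sd = c(10, 50)),
                 n_brains = 5L, cells_per_brain = 40L),
    comparison = list(phases = c("interphase", "mitotic")),
    output = list(dir = NULL, prefix = "fixed"))
}

#' Run the fixed-cell statistics pipeline
#'
#' Loads (or simulates) a per-centrosome quantification table, reduces it
#' to per-brain averages, and compares phases within each
#' (genotype, marker) using the Mann-Whitney U test on brain means.
#'
#' @param config Configuration list or YAML/JSON path; see
#'   `pcmfrap:::fixed_config_defaults()` for the schema.
#' @return List of class `"fixed_report"`: the table, per-brain averages,
#'   comparisons, manifest and output paths.
#' @export
run_fixed_pipeline <- function(config = NULL) {
  cfg <- if (is.character(config))
    read_run_config(config, fixed_config_defaults())
  else merge_config(fixed_config_defaults(), config)
  tab <- if (!is.null(cfg$table$path)) read_cellquant_csv(cfg$table$path)
  else {
    gr <- as.data.frame(cfg$table$groups)
    simulate_fixed_cell_table(gr, cfg$table$n_brains,
                              cfg$table$cells_per_brain,
                              seed = stage_seed(as.integer(cfg$seed),
                                                "table"))
  }
  if (!"phase" %in% names(tab) || any(!nzchar(tab$phase)))
    pcm_stop("missing_column", "table lacks phase labels")
  br <- brain_averages(tab)
  ph <- cfg$comparison$phases
  keys <- unique(br[, intersect(c("genotype", "marker"), names(br)),
                    drop = FALSE])
  comparisons <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rep(TRUE, nrow(br))
    for (k in names(keys)) sel <- sel & br[[k]] == keys[i, k]
    x <- br$mean_intensity[sel & br$phase == ph[1]]
    y <- br$mean_intensity[sel & br$phase == ph[2]]
    cmp <- if (length(x) && length(y)) mann_whitney_u(x, y) else NULL
    c(as.list(keys[i, , drop = FALSE]),
      list(n1 = length(x), n2 = length(y),
           mean1 = mean(x), mean2 = mean(y),
           statistic = cmp$statistic %||% NA,
           p_value = cmp$p_value %||% NA,
           method = cmp$method %||% NA))
  })
  report <- list(comparison_phases = ph, comparisons = comparisons,
                 seed = cfg$seed)
  paths <- character(0)
  if (!is.null(cfg$output$dir)) {
    dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
    prefix <- file.path(cfg$output$dir, cfg$output$prefix)
    paths <- c(paths,
               write_cellquant_csv(tab, paste0(prefix, "_table.csv")))
    bpath <- paste0(prefix, "_brain_averages.csv")
    write.csv(br, bpath, row.names = FALSE)
    paths <- c(paths, bpath,
               write_report(report, paste0(prefix, "_stats.json")))
  }
  manifest <- build_manifest(cfg, paths)
  if (!is.null(cfg$output$dir))
    paths <- c(paths, write_report(
      manifest, file.path(cfg$output$dir,
                          paste0(cfg$output$prefix,
                                 "_manifest.json"))))
  structure(list(table = tab, brain_averages = br, report = report,
                 manifest = manifest, paths = paths, config = cfg),
            class = "fixed_report")
}

#' @export
print.fixed_report <- function(x, ...) {
  cat(sprintf("Fixed-cell report: %d centrosomes, %d brain averages\n",
              nrow(x$table), nrow(x$brain_averages)))
  for (cmp in x$report$comparisons)
    cat(sprintf("  %s: %s %.4g vs %s %.4g, p = %.4g\n",
                paste(unlist(cmp[setdiff(names(cmp),
                                         c("n1", "n2", "mean1", "mean2",
                                           "statistic", "p_value",
                                           "method"))]),
                      collapse = "/"),
                x$report$comparison_phases[1], cmp$mean1,
                x$report$comparison_phases[2], cmp$mean2, cmp$p_value))
  invisible(x)
}
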