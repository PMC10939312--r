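#' Run configuration presets
#'
#' Bundles everything an end-to-end run needs. Two named presets are
#' provided: `"desk"` (a reduced grid of about 200 points per local/remote
#' family, 10 simulated participants x 2 repetitions) for interactive work
#' and testing, and `"paper"` (the full 7820-point default grid, 56
#' participants x 10 repetitions) matching the full-scale analysis; the
#' latter is compute-heavy and intended for batch use.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param space_kind `"circular"` or `"linear"`.
#' @param design an [experiment_design()].
#' @param ... overrides for any config field.
#' @return A list of class `esfm_config`.
#' @export
esfm_config <- function(profile = c("desk", "paper"),
                        space_kind = c("circular", "linear"),
                        design = design_6x6(), ...) {
  profile <- match.arg(profile)
  space_kind <- match.arg(space_kind)
  base <- if (profile == "desk") {
    list(grid = build_grid(sigma = c(0.3, 0.5, 0.8),
                           a = seq(0.2, 0.9, by = 0.1),
                           b = c(0.1, 0.3, 0.5, 0.8, 1.2, 1.7, 2.3)),
         n_participants = 10L, n_repetitions = 2L, n_voxels = 200L)
  } else {
    list(grid = build_grid(), n_participants = 56L, n_repetitions = 10L,
         n_voxels = 200L)
  }
  cfg <- utils::modifyList(
    c(base, list(profile = profile, space_kind = space_kind, design = design,
                 families = esfm_families(), target_accuracy = 0.4,
                 gain = 100, seed = 1L, positions = NULL, noise = NULL,
                 workers = 1L, output_dir = NULL)),
    list(...))
  class(cfg) <- "esfm_config"
  cfg
}

#' End-to-end run
#'
#' Orchestrates a full run from a config: builds the feature space, fits all
#' configured families to the supplied empirical summary (or to
#' pseudo-empirical data generated from a ground-truth spec), and optionally
#' writes the fit table, ranking and a run manifest to `output_dir`. Grid
#' tasks carry pre-derived seeds, so results are identical for any worker
#' count.
#'
#' @param config an [esfm_config()].
#' @param empirical an [esfm_summary()]; or `NULL` when `ground_truth` given.
#' @param ground_truth optional list `(model, sigma)` — a
#'   [modulation_model()] plus generating width — to run a recovery instead.
#' @return The [esfm()] object (or [run_recovery()] result), invisibly when
#'   outputs are written.
#' @export
run_full <- function(config, empirical = NULL, ground_truth = NULL) {
  stopifnot(inherits(config, "esfm_config"))
  if (is.null(empirical) && is.null(ground_truth))
    stop("either an empirical summary or a ground-truth spec is required")
  t0 <- Sys.time()
  space <- feature_space(config$space_kind)
  positions <- config$positions
  if (is.null(positions))
    positions <- make_synthetic_stimuli(config$design$n_trailing, space,
                                        seed = config$seed)$position
  res <- if (!is.null(ground_truth)) {
    run_recovery(ground_truth$model, ground_truth$sigma, space,
                 config$design, positions = positions, grid = config$grid,
                 families = config$families, n_voxels = config$n_voxels,
                 noise = config$noise,
                 target_accuracy = config$target_accuracy,
                 gain = config$gain, n_participants = config$n_participants,
                 n_repetitions = config$n_repetitions, seed = config$seed,
                 workers = config$workers)
  } else {
    esfm(empirical, space, config$design, positions, grid = config$grid,
         families = config$families, n_voxels = config$n_voxels,
         noise = config$noise, target_accuracy = config$target_accuracy,
         gain = config$gain, n_participants = config$n_participants,
         n_repetitions = config$n_repetitions, seed = config$seed,
         workers = config$workers)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    fit <- if (inherits(res, "esfm_recovery")) res$fit else res
    files <- c(fit_table = "fit_table.csv", ranking = "ranking.csv")
    utils::write.csv(fit$fit_table,
                     file.path(config$output_dir, files["fit_table"]),
                     row.names = FALSE)
    utils::write.csv(fit$ranking$summary,
                     file.path(config$output_dir, files["ranking"]),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      paths <- file.path(config$output_dir, files)
      manifest <- list(
        package_version = as.character(utils::packageVersion("esfm")),
        profile = config$profile, space_kind = config$space_kind,
        seed = config$seed,
        config_hash = sum(utf8ToInt(paste(deparse(
          config[setdiff(names(config), "output_dir")]), collapse = ""))),
        elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
        files = lapply(seq_along(paths), function(i) list(
          name = unname(files[i]), bytes = file.size(paths[i]),
          checksum = sum(utf8ToInt(paste(readLines(paths[i]),
                                         collapse = "\n"))))))
      jsonlite::write_json(manifest,
                           file.path(config$output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    return(invisible(res))
  }
  res
}
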