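#' Read and validate a run configuration
#'
#' A single YAML file drives the whole pipeline. Recognised sections (all
#' optional except `paths` for disk-based runs): `seed`; `paths`
#' (`tracks_csv`, `field_dir`, `output_dir`); `dates` (field-stack days in
#' order from departure); `preprocess` (fields of [preprocess_params()]);
#' `kernel` (`n_len_bins`, `n_ang_bins`); `simulation` (fields of
#' [simulation_config()] except the per-animal geometry); `strategies`
#' (list of `{strategy, cues, extreme}`; defaults to the full 19-model
#' design); `evaluation` (`fraction`, `reference_measure`).
#'
#' @param path YAML file path.
#' @return an object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  y$seed <- as.integer(y$seed %||% 1)
  y$preprocess <- do.call(preprocess_params, y$preprocess %||% list())
  y$kernel <- utils::modifyList(list(n_len_bins = 30, n_ang_bins = 24),
                                y$kernel %||% list())
  sim <- utils::modifyList(
    list(mode = "CRW", alpha = 0.5, beta = 1, heading_error = pi / 12,
         steps_per_day = 24, n_replicates = 100, jitter = "uniform"),
    y$simulation %||% list())
  y$simulation <- sim
  y$strategies <- if (is.null(y$strategies)) enumerate_model_configs()
    else lapply(y$strategies, function(s)
      strategy_spec(toupper(s$strategy), s$cues %||% character(0),
                    extreme = s$extreme))
  y$evaluation <- utils::modifyList(
    list(fraction = 0.10, reference_measure = "mean_distance"),
    y$evaluation %||% list())
  if (!is.null(y$paths)) {
    for (k in c("tracks_csv", "field_dir")) {
      if (!is.null(y$paths[[k]]) && !file.exists(y$paths[[k]]))
        stop("configured path does not exist: ", y$paths[[k]])
    }
  }
  structure(y, class = "run_config")
}

#' @keywords internal
config_hash <- function(cfg) {
  hash31(utils::capture.output(utils::str(unclass(cfg))))
}

#' @keywords internal
write_manifest <- function(out_dir, cfg, stage) {
  yaml::write_yaml(list(stage = stage,
                        config_hash = config_hash(cfg),
                        seed = cfg$seed,
                        package_version = as.character(
                          utils::packageVersion("magnav")),
                        written = format(Sys.time(), tz = "UTC")),
                   file.path(out_dir, paste0("manifest_", stage, ".yaml")))
}

#' Run the full pipeline from a configuration
#'
#' Loads tracks and daily field stacks from the configured paths,
#' preprocesses, estimates the movement kernel, simulates every configured
#' strategy for every animal, scores the simulations against the empirical
#' tracks, and runs the mixed-model evaluation with top-decile counting.
#' Writes per-stage CSV outputs and manifests into
#' `paths$output_dir`.
#'
#' @param cfg a `run_config` (or path to one).
#' @return invisibly, a list with `kernel`, `scores`, `evaluation`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- cfg$paths$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  raw <- read_tracks(cfg$paths$tracks_csv)
  tracks <- preprocess_tracks(raw, cfg$preprocess)
  if (length(tracks) == 0) stop("no track survived preprocessing")
  write_tracks(tracks, file.path(out_dir, "tracks_clean.csv"))

  fields <- lapply(cfg$dates, function(d)
    read_field_stack(cfg$paths$field_dir, d))
  kernel <- estimate_kernel(lapply(tracks, to_steps),
                            cfg$kernel$n_len_bins, cfg$kernel$n_ang_bins)
  write_kernel(kernel, file.path(out_dir, "kernel"))

  animals <- make_animals(tracks, fields)
  sim <- cfg$simulation
  scfg <- simulation_config(sim$mode,
                            n_steps = n_fixes(tracks[[1]]) - 1,
                            start_xy = c(0, 0), target_xy = c(1, 1),
                            alpha = sim$alpha, beta = sim$beta,
                            heading_error = sim$heading_error,
                            steps_per_day = sim$steps_per_day,
                            n_replicates = sim$n_replicates,
                            seed = cfg$seed, jitter = sim$jitter)
  batch <- run_batch(kernel, cfg$strategies, animals, fields, scfg)
  utils::write.csv(as.data.frame(batch),
                   file.path(out_dir, "simulations.csv"),
                   row.names = FALSE)

  scores <- score_batch(batch, tracks)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)

  ev <- evaluate_strategies(scores, cfg$evaluation$reference_measure,
                            cfg$evaluation$fraction)
  for (m in names(ev$fits))
    utils::write.csv(ev$fits[[m]]$estimates,
                     file.path(out_dir, paste0("lmm_", m, ".csv")),
                     row.names = FALSE)
  for (m in names(ev$counts))
    utils::write.csv(as.data.frame(ev$counts[[m]]),
                     file.path(out_dir, paste0("counts_", m, ".csv")),
                     row.names = FALSE)
  write_manifest(out_dir, cfg, "run_all")
  invisible(list(kernel = kernel, scores = scores, evaluation = ev))
}

#' Write a fixture scenario to disk in the standard exchange formats
#'
#' Emits the daily cue rasters as float TIFF + world-file pairs named
#' `<cue>_<YYYY-MM-DD>.tif` and the tracks as a `tracks.csv` in the dialect
#' of [read_tracks()], so that the on-disk readers are exercised end to
#' end.
#'
#' @param name scenario name for [fixture_scenario()].
#' @param dir output directory.
#' @param seed integer seed.
#' @return invisibly, the scenario bundle.
#' @export
write_fixture <- function(name, dir, seed = 1) {
  fx <- fixture_scenario(name, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in fx$fields) {
    for (cue in c("F", "I", "H")) {
      write_field_grid(st[[cue]],
                       file.path(dir, sprintf("%s_%s.tif", cue,
                                              format(st$date))))
    }
  }
  write_tracks(fx$tracks, file.path(dir, "tracks.csv"))
  yaml::write_yaml(list(scenario = name, seed = seed,
                        dates = vapply(fx$fields,
                                       function(s) format(s$date),
                                       character(1))),
                   file.path(dir, "fixture.yaml"))
  invisible(fx)
}
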