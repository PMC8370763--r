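known_keys <- function(section) {
  switch(section,
    top = c("simulation", "detection", "matching", "calibration", "psf",
            "io", "seed", "benchmark"),
    simulation = names(formals(simulation_params)),
    detection = names(formals(detection_params)),
    matching = names(formals(matching_params)),
    psf = names(formals(psf_model)),
    calibration = c("slope", "intercept", "standards_csv"),
    benchmark = c("n_replicates", "seeds", "target_tp_percent", "calibrate",
                  "sweep"),
    io = c("movie", "truth", "events", "out_dir"))
}

check_keys <- function(x, section) {
  unknown <- setdiff(names(x), known_keys(section))
  if (length(unknown))
    stop(sprintf("unknown key(s) in config section '%s': %s", section,
                 paste(unknown, collapse = ", ")))
  x
}

#' Read and validate a pipeline configuration
#'
#' Configuration lives in YAML (JSON is also accepted) with sections
#' `simulation`, `detection`, `matching`, `psf`, `calibration`,
#' `benchmark`, `io` and a global `seed`. Unknown keys anywhere are
#' rejected with a field-level message; all nested parameter invariants are
#' checked by the respective constructors.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list of class `pipeline_config` with fully constructed
#'   parameter objects.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, "top")
  for (s in c("simulation", "detection", "matching", "psf", "calibration",
              "benchmark", "io"))
    if (!is.null(raw[[s]])) check_keys(raw[[s]], s)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  sim_args <- raw$simulation %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  cal <- raw$calibration %||% list()
  calibration <- if (!is.null(cal$standards_csv)) {
    fit_calibration(tibble::as_tibble(utils::read.csv(cal$standards_csv)))
  } else {
    do.call(calibration_model,
            cal[intersect(names(cal), c("slope", "intercept"))])
  }
  structure(list(
    simulation = do.call(simulation_params, sim_args),
    detection = do.call(detection_params, raw$detection %||% list()),
    matching = do.call(matching_params, raw$matching %||% list()),
    psf = do.call(psf_model, raw$psf %||% list()),
    calibration = calibration,
    benchmark = raw$benchmark %||% list(),
    io = raw$io %||% list(),
    seed = seed), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(lapply(unclass(config), unclass), f)
  unname(tools::md5sum(f))
}

log_msg <- function(...) message(sprintf(...))

#' Pipeline command: simulate a benchmark movie
#'
#' Simulates a movie from the config and writes the TIFF + JSON sidecar and
#' the ground-truth CSV. The seed and a config hash are logged to stderr.
#'
#' @param config A [read_pipeline_config()] object (or path to one).
#' @param out_prefix Output path prefix; writes `<prefix>.tif`,
#'   `<prefix>.json`, `<prefix>_truth.csv`.
#' @return Invisibly, a list with the written paths and the truth tibble.
#' @export
pipeline_simulate <- function(config, out_prefix) {
  if (is.character(config)) config <- read_pipeline_config(config)
  log_msg("simulate: seed %d, config %s", config$simulation$seed,
          config_hash(config))
  sim <- simulate_movie(config$simulation, config$psf)
  movie_path <- paste0(out_prefix, ".tif")
  write_movie(sim$movie, movie_path)
  truth_path <- paste0(out_prefix, "_truth.csv")
  write_events_csv(sim$truth, truth_path)
  invisible(list(movie = movie_path, truth = truth_path,
                 events = sim$truth))
}

#' Pipeline command: detect and fit landing events in a movie
#'
#' Reads a movie (preprocessing it with the metadata's residual
#' `frame_avg`/`bin_px` is the caller's responsibility for raw stacks),
#' runs the ratiometric transform, two-filter detection and PSF fitting,
#' and writes candidate and fitted-event CSVs.
#'
#' @param movie_path Path to a movie readable by [read_movie()], or an
#'   `mp_movie`.
#' @param config A [read_pipeline_config()] object (or path).
#' @param out_prefix Output prefix; writes `<prefix>_candidates.csv`,
#'   `<prefix>_events.csv`.
#' @return Invisibly, the fitted-event tibble.
#' @export
pipeline_detect <- function(movie_path, config, out_prefix) {
  if (is.character(config)) config <- read_pipeline_config(config)
  movie <- if (inherits(movie_path, "mp_movie")) movie_path
           else read_movie(movie_path)
  log_msg("detect: navg %d, t1 %g, t2 %g, config %s", config$detection$navg,
          config$detection$t1, config$detection$t2, config_hash(config))
  res <- analyze_movie(movie, config$detection, config$psf)
  utils::write.csv(as.data.frame(res$candidates),
                   paste0(out_prefix, "_candidates.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$events),
                   paste0(out_prefix, "_events.csv"), row.names = FALSE)
  invisible(res$events)
}

#' Pipeline command: convert fitted events to a mass distribution
#'
#' @param events Fitted-event tibble or path to an events CSV.
#' @param config A [read_pipeline_config()] object (or path); supplies the
#'   calibration.
#' @param out_prefix Output prefix; writes `<prefix>_masses.csv`,
#'   `<prefix>_histogram.csv`, `<prefix>_species.csv`.
#' @param monomer_mass_kda Monomer mass for n-mer assignment.
#' @return Invisibly, the `mass_distribution`.
#' @export
pipeline_mass <- function(events, config, out_prefix,
                          monomer_mass_kda = 42) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.character(events)) {
    if (!file.exists(events)) stop("events file not found: ", events)
    events <- tibble::as_tibble(utils::read.csv(events))
  }
  if (nrow(events) == 0L) stop("events table is empty")
  md <- build_mass_distribution(events, config$calibration,
                                monomer_mass_kda = monomer_mass_kda)
  utils::write.csv(data.frame(mass_kda = md$masses_kda),
                   paste0(out_prefix, "_masses.csv"), row.names = FALSE)
  utils::write.csv(data.frame(bin_lo = utils::head(md$breaks, -1),
                              bin_hi = md$breaks[-1], count = md$counts),
                   paste0(out_prefix, "_histogram.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(md$species),
                   paste0(out_prefix, "_species.csv"), row.names = FALSE)
  invisible(md)
}

#' Pipeline command: run the semi-synthetic benchmark
#'
#' Optionally calibrates `noise_sigma` to the target monomer operating
#' point first (config `benchmark$calibrate = TRUE`), then runs the
#' replicate benchmark and writes a JSON + CSV report.
#'
#' @param config A [read_pipeline_config()] object (or path).
#' @param out_prefix Output prefix; writes `<prefix>_benchmark.json`,
#'   `<prefix>_benchmark.csv`.
#' @return Invisibly, the `benchmark_result`.
#' @export
pipeline_benchmark <- function(config, out_prefix) {
  if (is.character(config)) config <- read_pipeline_config(config)
  bc <- config$benchmark
  params <- config$simulation
  if (isTRUE(bc$calibrate)) {
    sig <- calibrate_noise(bc$target_tp_percent %||% 57.2, params,
                           config$detection, config$matching,
                           model = config$psf)
    params$noise_sigma <- as.numeric(sig)
    log_msg("benchmark: calibrated noise_sigma = %.4g", params$noise_sigma)
  }
  seeds <- bc$seeds %||% 1:5
  res <- run_benchmark(params, config$detection, config$matching,
                       n_replicates = length(seeds), seeds = seeds,
                       model = config$psf)
  rep <- list(tp_percent = res$tp_percent, fp_percent = res$fp_percent,
              tp_sd = res$tp_sd, fp_sd = res$fp_sd,
              n_replicates = res$n_replicates, seeds = res$seeds,
              noise_sigma = params$noise_sigma,
              config_hash = config_hash(config))
  jsonlite::write_json(rep, paste0(out_prefix, "_benchmark.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(res$per_replicate),
                   paste0(out_prefix, "_benchmark.csv"), row.names = FALSE)
  invisible(res)
}
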