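# Run configuration, persistence and the experiment driver.
#
# A run configuration is a plain named list (YAML on disk) that fully
# determines every output: model parameters, grid, protocol, duration and
# seeds. Results persist as plain text: per-run trace CSV (t, x), onset
# logs, and a JSON metadata snapshot embedding the configuration.

default_config <- function() {
  list(
    params = list(),                    # overrides of nft_params() defaults
    grid = list(nx = 16, ny = 16, side_length = 0.5, dt = 1e-4,
                store_rate = 100),
    protocol = list(mode = "periodic", shape = "decreasing_ramp",
                    duration = 0.1, energy = 40, rate = 0.85,
                    lambda = 1 / 0.85, f0 = 0.85, target_phase = 0,
                    hysteresis = 9),
    duration = 910,
    seeds = 1:5,
    out_dir = "nftsws-results",
    store_fields = FALSE)
}

#' Experiment fixtures
#'
#' `"quick"` is a reduced setup (16 x 16 grid, 60 s, 2 seeds) that runs the
#' full pipeline in minutes on one CPU; `"standard"` is the reference setup
#' (910 s, 5 seeds, periodic stimulation at 0.85 Hz with the decreasing
#' ramp pulse).
#'
#' @param profile `"quick"` or `"standard"`.
#' @return A run configuration list, see [run_experiment()].
#' @export
make_fixture <- function(profile = c("quick", "standard")) {
  profile <- match.arg(profile)
  cfg <- default_config()
  if (profile == "quick") {
    cfg$duration <- 60
    cfg$seeds <- 1:2
  }
  cfg
}

#' Read or write a run configuration
#'
#' @param path File path (YAML).
#' @param config A configuration list.
#' @return `read_run_config()` returns the configuration list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (f in c("grid", "protocol", "duration", "seeds"))
    if (is.null(cfg[[f]]))
      stop(sprintf("config field `%s` is required", f), call. = FALSE)
  if (!cfg$protocol$mode %in% c("sham", "periodic", "poisson", "closed_loop"))
    stop("protocol.mode must be sham/periodic/poisson/closed_loop",
         call. = FALSE)
  if (cfg$protocol$mode != "sham" &&
      !cfg$protocol$shape %in% pulse_shapes())
    stop("protocol.shape must be one of: ",
         paste(pulse_shapes(), collapse = ", "), call. = FALSE)
  if (!is.numeric(cfg$duration) || cfg$duration <= 0)
    stop("duration must be a positive number of seconds", call. = FALSE)
  invisible(cfg)
}

config_objects <- function(cfg) {
  params <- do.call(nft_params, cfg$params)
  grid <- do.call(grid_spec, cfg$grid)
  pr <- cfg$protocol
  protocol <- if (pr$mode == "sham") stim_protocol("sham") else
    stim_protocol(pr$mode,
                  pulse = pulse_spec(pr$shape, pr$duration, pr$energy),
                  rate = pr$rate %||% 0.85,
                  lambda = pr$lambda %||% (1 / 0.85),
                  f0 = pr$f0 %||% 0.85,
                  target_phase = pr$target_phase %||% 0,
                  hysteresis = pr$hysteresis %||% 9)
  list(params = params, grid = grid, protocol = protocol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a simulation result as plain text
#'
#' Writes the trace as a two-column CSV (`t`, `x`), the stimulus onsets as a
#' single-column CSV, and a JSON metadata file holding the full
#' configuration snapshot and seed.
#'
#' @param sim An `nft_sim` object.
#' @param stem Output path stem (files `<stem>.csv`, `<stem>_onsets.csv`,
#'   `<stem>.json`).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, stem) {
  stopifnot(inherits(sim, "nft_sim"))
  trace_path <- paste0(stem, ".csv")
  utils::write.csv(sim$trace, trace_path, row.names = FALSE)
  onset_path <- paste0(stem, "_onsets.csv")
  utils::write.csv(data.frame(onset = sim$stim_onsets), onset_path,
                   row.names = FALSE)
  meta_path <- paste0(stem, ".json")
  proto <- unclass(sim$protocol)
  proto <- proto[!vapply(proto, is.null, logical(1))]
  proto <- lapply(proto, function(el) if (is.object(el)) unclass(el) else el)
  params <- unclass(sim$params)
  params$nu <- as.list(params$nu)
  meta <- list(seed = sim$seed, duration = sim$duration,
               x_mean = sim$x_mean,
               params = params,
               grid = unclass(sim$grid),
               protocol = proto)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(trace_path, onset_path, meta_path))
}

#' Run a full experiment from a configuration
#'
#' Executes, for every seed, a SHAM run and (unless the configured mode is
#' `"sham"`) a stimulated run sharing its noise stream, then the detection,
#' spectral and summary stages. All results are written under
#' `config$out_dir`: per-run CSV traces and onset logs, JSON metadata, and
#' a per-seed summary CSV.
#'
#' @param config A run configuration (see [make_fixture()]).
#' @param quiet Suppress progress messages.
#' @return The [summarize_condition()] result, invisibly, with the output
#'   directory in attribute `"out_dir"`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  validate_config(config)
  obj <- config_objects(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  sham_runs <- list(); stim_runs <- list()
  for (seed in config$seeds) {
    say("seed %d: SHAM run (%g s)", seed, config$duration)
    sham <- simulate_nft(obj$params, obj$grid, stim_protocol("sham"),
                         duration = config$duration, seed = seed)
    write_sim(sham, file.path(config$out_dir, sprintf("sham_seed%d", seed)))
    sham_runs[[length(sham_runs) + 1]] <- sham
    if (obj$protocol$mode != "sham") {
      say("seed %d: %s run", seed, toupper(obj$protocol$mode))
      stim <- simulate_nft(obj$params, obj$grid, obj$protocol,
                           duration = config$duration, seed = seed)
      write_sim(stim, file.path(config$out_dir,
                                sprintf("%s_seed%d", obj$protocol$mode, seed)))
      stim_runs[[length(stim_runs) + 1]] <- stim
    }
  }
  if (obj$protocol$mode == "sham") stim_runs <- sham_runs
  summary <- summarize_condition(stim_runs, sham_runs)
  utils::write.csv(summary$per_seed,
                   file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  say("results written to %s", config$out_dir)
  attr(summary, "out_dir") <- config$out_dir
  invisible(summary)
}

#' Read an event table or trace written by [write_sim()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_trace <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
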