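# End-to-end orchestration: config handling, the run_study() pipeline and
# a small command-line dispatcher.

#' Default run configuration
#'
#' @param out_dir Output directory.
#' @return Named list understood by [run_study()]: paths, geometry
#'   settings, grid, smoothing window, isopleth levels, fidelity scheme,
#'   screening and classifier options, and the simulation seed.
#' @export
default_config <- function(out_dir = "barnspace_out") {
  list(
    mode = "simulate",              # "simulate" or "files"
    locations = NULL, metadata = NULL,
    out_dir = out_dir,
    seed = 1,
    sim = list(n_cows = 20, n_days = 5, rate = 0.125),
    smoothing_window = 15,
    isopleth_levels = c(0.95, 0.50),
    fidelity_scheme = "consecutive",
    max_gap = 40,
    milking_starts = c("05:00", "13:00", "21:00"),
    milking_duration = 90,
    screen = list(max_removals = 2, alpha = 0.05),
    classifier = list(max_size = 3),
    tz = "UTC"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return Config list merged over [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  out <- utils::modifyList(default_config(), cfg)
  out
}

config_geometry <- function(config) {
  barn_geometry(milking = milking_schedule(config$milking_starts,
                                           config$milking_duration))
}

#' Run the full study pipeline
#'
#' Executes: input acquisition (simulation or file reading), smoothing,
#' cleaning, daily partition, utilisation distributions, space-use and
#' site-fidelity measures, the linear-model screen, and the logistic
#' lameness classifier. All artefacts are written under
#' `config$out_dir` together with a JSON manifest capturing the config,
#' stage record counts and the seed, so that a rerun with identical
#' config and seed reproduces the outputs exactly.
#'
#' @param config List as from [default_config()] / [read_config()].
#' @return Invisibly, list with `features`, `screen`, `ranking`,
#'   `manifest`.
#' @export
run_study <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- config_geometry(config)
  stage <- "input"
  res <- tryCatch({
    if (identical(config$mode, "simulate")) {
      params <- do.call(sim_params, c(config$sim, list(
        seed = config$seed, milking = geometry$milking)))
      herd <- generate_herd(params, geometry)
      locations <- herd$locations
      metadata <- herd$metadata
      write_locations(locations, file.path(config$out_dir, "locations.csv"))
      write_metadata(metadata, file.path(config$out_dir, "metadata.csv"))
    } else {
      if (is.null(config$locations) || is.null(config$metadata))
        stop("mode 'files' needs 'locations' and 'metadata' paths")
      locations <- read_locations(config$locations, tz = config$tz)
      metadata <- read_metadata(config$metadata)
    }
    stage <- "trajectory_prep"
    n_in <- nrow(locations)

    stage <- "features"
    features <- build_feature_table(
      locations, geometry, grid_spec(),
      window = config$smoothing_window,
      levels = config$isopleth_levels,
      max_gap = config$max_gap,
      scheme = config$fidelity_scheme,
      tz = config$tz)
    write_features(features, file.path(config$out_dir, "features.csv"))

    stage <- "screen"
    screen <- screen_all(features, metadata,
                         max_removals = config$screen$max_removals,
                         alpha = config$screen$alpha)
    write_screen_report(screen, file.path(config$out_dir, "screen.csv"))

    stage <- "classify"
    pool <- candidate_features(screen, config$screen$alpha)
    ranking <- select_logistic(features, metadata, pool,
                               max_size = config$classifier$max_size)
    if (!is.null(ranking$table))
      utils::write.table(ranking$table,
                         file.path(config$out_dir, "classifier.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)

    manifest <- list(
      config = config[setdiff(names(config), "out_dir")],
      seed = config$seed,
      counts = list(
        input = n_in,
        retained = sum(features$days_used > 0),
        exclusions = as.list(attr(features, "exclusions")),
        cows = nrow(features)),
      package_version = as.character(utils::packageVersion("barnspace")),
      completed = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    list(features = features, screen = screen, ranking = ranking,
         manifest = manifest)
  }, error = function(e) {
    manifest <- list(completed = FALSE, failed_stage = stage,
                     error = conditionMessage(e))
    try(jsonlite::write_json(manifest,
                             file.path(config$out_dir, "manifest.json"),
                             auto_unbox = TRUE, force = TRUE), silent = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `features`, `screen`, `classify`
#' and `run`, reading options of the form `--name value`. Used by the
#' `barnspace` script installed under `inst/scripts/`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return Invisibly, the subcommand result.
#' @export
barnspace_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: barnspace <simulate|features|screen|classify|run> [--config f] ",
         "[--out-dir d] [--seed n] [--features f] [--metadata f] [--locations f]")
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else default_config()
  if (!is.null(opts$`out-dir`)) cfg$out_dir <- opts$`out-dir`
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$locations)) { cfg$locations <- opts$locations; cfg$mode <- "files" }
  if (!is.null(opts$metadata)) cfg$metadata <- opts$metadata
  switch(cmd,
    simulate = {
      geometry <- config_geometry(cfg)
      params <- do.call(sim_params, c(cfg$sim, list(seed = cfg$seed,
                                                    milking = geometry$milking)))
      herd <- generate_herd(params, geometry)
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_locations(herd$locations, file.path(cfg$out_dir, "locations.csv"))
      write_metadata(herd$metadata, file.path(cfg$out_dir, "metadata.csv"))
      message("wrote ", nrow(herd$locations), " locations for ",
              nrow(herd$metadata), " cows to ", cfg$out_dir)
      invisible(herd)
    },
    features = {
      locations <- read_locations(cfg$locations, tz = cfg$tz)
      feats <- build_feature_table(locations, config_geometry(cfg), grid_spec(),
                                   window = cfg$smoothing_window,
                                   levels = cfg$isopleth_levels,
                                   max_gap = cfg$max_gap,
                                   scheme = cfg$fidelity_scheme, tz = cfg$tz)
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_features(feats, file.path(cfg$out_dir, "features.csv"))
      invisible(feats)
    },
    screen = {
      feats <- read_features(if (!is.null(opts$features)) opts$features else
        file.path(cfg$out_dir, "features.csv"))
      meta <- read_metadata(cfg$metadata)
      rep <- screen_all(feats, meta, max_removals = cfg$screen$max_removals,
                        alpha = cfg$screen$alpha)
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_screen_report(rep, file.path(cfg$out_dir, "screen.csv"))
      print(rep)
      invisible(rep)
    },
    classify = {
      feats <- read_features(if (!is.null(opts$features)) opts$features else
        file.path(cfg$out_dir, "features.csv"))
      meta <- read_metadata(cfg$metadata)
      rep <- screen_all(feats, meta, max_removals = cfg$screen$max_removals,
                        alpha = cfg$screen$alpha)
      rk <- select_logistic(feats, meta, candidate_features(rep, cfg$screen$alpha),
                            max_size = cfg$classifier$max_size)
      print(rk)
      invisible(rk)
    },
    run = run_study(cfg),
    stop("unknown subcommand: ", cmd)
  )
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    nm <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("option --", nm, " needs a value")
    opts[[nm]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
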