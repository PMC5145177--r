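#' Parse and validate a run configuration file
#'
#' Reads a YAML configuration describing one dispersal run: habitat path or
#' synthetic-archipelago block, flow file(s) or analytic-flow block,
#' release schedule, tracker parameters and analysis toggles. Unknown keys
#' are rejected by name; defaults equal the package's study conditions
#' (50 particles/pixel/day, K = 250 m^2/s, PLD 45 d, settlement radius
#' 5 km, 3 replicates, daily releases 2009-05-02..2014-04-10).
#'
#' @param path YAML file path.
#' @return A validated list of class `"run_config"` with elements `habitat`,
#'   `flow`, `schedule`, `params`, `months`, `analysis`, `out_dir`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  known <- c("habitat", "flow", "schedule", "params", "months", "analysis",
             "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))

  pk <- cfg$params %||% list()
  known_p <- c("pld_days", "settle_radius_km", "eddy_diffusivity",
               "dt_seconds", "particles_per_pixel_per_day", "integrator",
               "replicates", "seed")
  unknown <- setdiff(names(pk), known_p)
  if (length(unknown))
    stopf("unknown params key(s): %s", paste(unknown, collapse = ", "))
  params <- do.call(run_params, pk)

  sk <- cfg$schedule %||% list()
  schedule <- release_schedule(sk$start %||% "2009-05-02",
                               sk$end %||% "2014-04-10",
                               months = sk$months)

  habitat <- if (is.character(cfg$habitat)) {
    load_habitat_table(cfg$habitat)
  } else if (is.list(cfg$habitat)) {
    do.call(make_archipelago, cfg$habitat)
  } else stopf("config needs a 'habitat' path or archipelago block")

  flow <- if (is.null(cfg$flow)) {
    stopf("config needs a 'flow' block or path")
  } else if (is.character(cfg$flow)) {
    read_gridded_flow(cfg$flow)
  } else if (!is.null(cfg$flow$kind)) {
    dom <- cfg$flow$domain
    domain <- if (is.null(dom)) scenario_domain(habitat, pad_deg = 15)
    else flow_domain(dom$lon_min, dom$lon_max, dom$lat_min, dom$lat_max)
    make_analytic_flow(cfg$flow$kind, cfg$flow$params %||% list(), domain)
  } else if (!is.null(cfg$flow$paths)) {
    read_gridded_flow(cfg$flow$paths, times = cfg$flow$times)
  } else stopf("flow block needs 'kind' (analytic) or 'paths' (gridded)")

  structure(list(habitat = habitat, flow = flow, schedule = schedule,
                 params = params, months = cfg$months,
                 analysis = cfg$analysis %||% list(),
                 out_dir = cfg$out_dir %||% "."),
            class = "run_config")
}

cli_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, used by the
#' `inst/scripts/reefconn` launcher. Subcommands:
#' \describe{
#'   \item{simulate}{`simulate <config.yml>` — run the experiment and write
#'     `events.csv` plus a provenance copy of the resolved configuration.}
#'   \item{connectivity}{`connectivity <config.yml> <events.csv>` — compute
#'     all matrices and per-island metrics from saved events.}
#'   \item{compare}{`compare <A.csv> <B.csv> [n_perm] [seed]` — difference
#'     matrix and permutation Mantel r/p between two matrix files.}
#'   \item{scenario}{`scenario <name> <out_dir>` — materialize a named
#'     synthetic scenario (habitat CSV + flow/config YAML).}
#' }
#'
#' @param argv Character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv) {
  status <- tryCatch({
    if (!length(argv)) stopf(
      "usage: reefconn <simulate|connectivity|compare|scenario> ...")
    cmd <- argv[1]; rest <- argv[-1]
    switch(cmd,
      simulate = cli_simulate(rest),
      connectivity = cli_connectivity(rest),
      compare = cli_compare(rest),
      scenario = cli_scenario(rest),
      stopf("unknown subcommand '%s'", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_simulate <- function(args) {
  if (length(args) < 1) stopf("simulate: config path required")
  cfg <- parse_config(args[1])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.copy(args[1], file.path(cfg$out_dir, "resolved-config.yml"),
            overwrite = TRUE)
  cli_log("simulate: %d pixels, %d islands, %d release days, %d replicate(s), seed %d",
          nrow(cfg$habitat), n_islands(cfg$habitat), length(cfg$schedule),
          cfg$params$replicates, cfg$params$seed)
  sched <- if (is.null(cfg$months)) cfg$schedule
           else filter_by_release_months(cfg$schedule, cfg$months)
  ev <- run_experiment(cfg$habitat, cfg$flow, sched, cfg$params)
  out <- file.path(cfg$out_dir, "events.csv")
  write_events_csv(ev, out)
  cli_log("simulate: wrote %d records to %s", nrow(ev), out)
}

cli_connectivity <- function(args) {
  if (length(args) < 2) stopf("connectivity: config and events paths required")
  cfg <- parse_config(args[1])
  ev <- read_events_csv(args[2])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- cfg$habitat
  S <- settlement_matrix(ev, grid)
  SI <- bin_by_island(S, grid)
  write_matrix_csv(SI, file.path(cfg$out_dir, "island-settlement.csv"))
  write_matrix_csv(rearward_probability(SI),
                   file.path(cfg$out_dir, "rearward.csv"))
  write_matrix_csv(forward_probability(SI),
                   file.path(cfg$out_dir, "forward.csv"))
  utils::write.csv(connectivity_summary(ev, grid),
                   file.path(cfg$out_dir, "island-summary.csv"),
                   row.names = FALSE)
  sched <- if (is.null(cfg$months)) cfg$schedule
           else filter_by_release_months(cfg$schedule, cfg$months)
  utils::write.csv(settlement_time_series(ev, sched),
                   file.path(cfg$out_dir, "settlement-series.csv"),
                   row.names = FALSE)
  cli_log("connectivity: wrote matrices and summaries to %s", cfg$out_dir)
}

cli_compare <- function(args) {
  if (length(args) < 2) stopf("compare: two matrix paths required")
  A <- read_matrix_csv(args[1]); B <- read_matrix_csv(args[2])
  n_perm <- if (length(args) >= 3) as.integer(args[3]) else 999L
  seed <- if (length(args) >= 4) as.integer(args[4]) else 1L
  D <- matrix_difference(A, B)
  mt <- mantel_test(A, B, n_perm = n_perm, seed = seed)
  cli_log("compare: Mantel r = %.4f, p = %.4f (%d permutations)",
          mt$r, mt$p, mt$n_perm)
  out <- sub("\\.csv$", "-minus-B.csv", args[1])
  write_matrix_csv(D, out)
  cli_log("compare: wrote difference matrix to %s", out)
}

cli_scenario <- function(args) {
  if (length(args) < 2) stopf("scenario: name and output dir required")
  sc <- scenario(args[1])
  dir.create(args[2], showWarnings = FALSE, recursive = TRUE)
  write_habitat_table(sc$grid, file.path(args[2], "habitat.csv"))
  yaml::write_yaml(list(
    habitat = file.path(args[2], "habitat.csv"),
    flow = list(kind = sc$flow$form, params = sc$flow$params,
                domain = sc$flow$domain[c("lon_min", "lon_max",
                                          "lat_min", "lat_max")]),
    schedule = list(start = as.character(min(sc$schedule)),
                    end = as.character(max(sc$schedule))),
    params = unclass(sc$params)[c("pld_days", "settle_radius_km",
                                  "eddy_diffusivity", "dt_seconds",
                                  "particles_per_pixel_per_day",
                                  "integrator", "replicates", "seed")],
    out_dir = args[2]),
    file.path(args[2], "config.yml"))
  cli_log("scenario '%s': wrote habitat.csv and config.yml to %s",
          sc$name, args[2])
}
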