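#' Pipeline configuration
#'
#' Reads or builds the configuration driving [run_pipeline()]. Config files
#' are JSON with (all optional) fields: `synthetic` (logical; generate data
#' rather than read it), `params` (overrides for [synthetic_params()]),
#' `input_dir` (inventory CSVs when not synthetic), `registry_path`,
#' `decay_table_path`, `scenarios` (character ids), `horizon`, `n_sims`,
#' `out_dir`, `seed`.
#'
#' @param config a file path, a named list, or `NULL` for defaults.
#' @param ... overrides applied on top.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL, ...) {
  defaults <- list(
    synthetic = TRUE,
    params = list(),
    input_dir = NULL,
    registry_path = system.file("extdata", "allometric_equations.csv",
                                package = "swidcarbon"),
    decay_table_path = system.file("extdata", "decay_density.csv",
                                   package = "swidcarbon"),
    scenarios = c("baseline", "OF", "1.1", "1.2", "1.3",
                  "2.1", "2.2", "2.3", "3.1", "3.2", "3.3"),
    horizon = 30, n_sims = 1000,
    out_dir = "swidcarbon-output", seed = 1L)
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- modifyList(defaults, c(config %||% list(), list(...)))
  for (field in c("registry_path", "decay_table_path"))
    if (!file.exists(cfg[[field]]))
      stop("config error: ", field, " does not exist: ", cfg[[field]],
           call. = FALSE)
  if (!isTRUE(cfg$synthetic) && is.null(cfg$input_dir))
    stop("config error: non-synthetic runs need `input_dir`", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Four stages: (1) *generate* a synthetic inventory (or read one from
#' `input_dir`); (2) *estimate* per-plot carbon pools via the allometric
#' ensembles; (3) *fit* the habitat and fallow-age recovery models with the
#' AICc subset ranking; (4) *simulate* the configured landscape scenarios,
#' with farmland and old-growth parcels resampling observed plot values and
#' fallow parcels drawing from the fitted growth curve. Each stage gets a
#' child seed derived from the master seed, so stages are independently
#' reproducible. Outputs under `out_dir`: the inventory CSVs,
#' `plot_carbon.csv`, `model_report.json`, `scenario_totals.csv`,
#' `scenario_summary.csv` and `manifest.json` (package version, seed,
#' config hash).
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return Invisibly, a list with the dataset, plot table, fits, scenario
#'   table and manifest.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- read_equation_registry(cfg$registry_path)
  decay <- read_decay_density(cfg$decay_table_path)
  stage <- function(name, expr) {
    message(sprintf("[swidcarbon] stage %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ds <- stage("generate/read", {
    if (isTRUE(cfg$synthetic)) {
      params <- do.call(synthetic_params, cfg$params)
      inv <- generate_inventory(params, seed = child_seed(cfg$seed, 1),
                                registry = registry, decay_table = decay)
      write_field_dataset(inv$dataset, file.path(cfg$out_dir, "inventory"))
      inv$dataset
    } else read_field_dataset(cfg$input_dir)
  })
  message(sprintf("[swidcarbon]   %d plots, %d stems, %d lianas, %d deadwood, %d litter",
                  nrow(ds$plots), nrow(ds$stems), nrow(ds$lianas),
                  nrow(ds$deadwood), nrow(ds$litter)))

  ptab <- stage("estimate", plot_carbon_table(ds, registry, decay))
  write_plot_carbon_table(ptab, file.path(cfg$out_dir, "plot_carbon.csv"))

  fits <- stage("fit", {
    growth <- fit_model(ptab, "total", fixed = "fallow_age")
    ranks <- rank_all_subsets(ptab, "total",
                              c("fallow_age", "elevation_z", "interaction"))
    habitat <- fit_model(ptab, "total", fixed = c("habitat", "elevation_z"))
    list(growth = growth, ranks = ranks, habitat = habitat)
  })
  report <- list(
    growth = list(coefficients = as.list(fits$growth$coefficients),
                  vcov = fits$growth$vcov,
                  resid_sd = fits$growth$resid_sd,
                  ranef_var = as.list(fits$growth$ranef_var),
                  n = fits$growth$n, AICc = fits$growth$AICc,
                  converged = fits$growth$converged,
                  degenerate = fits$growth$degenerate),
    habitat = list(coefficients = as.list(fits$habitat$coefficients),
                   AICc = fits$habitat$AICc),
    ranks = as.data.frame(fits$ranks))
  jsonlite::write_json(report, file.path(cfg$out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  scen <- stage("simulate", {
    samplers <- list(
      farmland = make_empirical_sampler(
        ptab$total_carbon[ptab$habitat == "farmland"]),
      old_growth = make_empirical_sampler(
        ptab$total_carbon[ptab$habitat == "old_growth"]),
      fallow = make_model_sampler(fits$growth, mode = "draw"))
    simulate_scenarios(cfg$scenarios, samplers, horizon = cfg$horizon,
                       n_sims = cfg$n_sims, seed = child_seed(cfg$seed, 4))
  })
  write.csv(scen, file.path(cfg$out_dir, "scenario_summary.csv"),
            row.names = FALSE)
  totals <- do.call(cbind, lapply(attr(scen, "summaries"),
                                  function(s) s$totals))
  colnames(totals) <- scen$id
  write.csv(totals, file.path(cfg$out_dir, "scenario_totals.csv"),
            row.names = FALSE)

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  # hash the config without the output location, so reruns into different
  # directories compare equal when the science inputs are identical
  norm <- unclass(cfg)
  norm$out_dir <- NULL
  norm_path <- tempfile(fileext = ".json")
  jsonlite::write_json(norm, norm_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  hash <- unname(tools::md5sum(norm_path))
  unlink(norm_path)
  manifest <- list(package = "swidcarbon",
                   version = as.character(packageVersion("swidcarbon")),
                   seed = cfg$seed,
                   config_hash = hash,
                   outputs = c("plot_carbon.csv", "model_report.json",
                               "scenario_summary.csv",
                               "scenario_totals.csv"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = ds, plot_table = ptab, fits = fits,
                 scenarios = scen, manifest = manifest, config = cfg))
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write a synthetic inventory), `estimate`
#' (inventory CSVs to `plot_carbon.csv`), `fit` (models from a plot-carbon
#' table), `simulate` (scenario summaries from a plot-carbon table), `all`
#' (the full [run_pipeline()]). Common flags: `--seed <int>`,
#' `--config <path>`, `--out <dir>`; `estimate`/`fit`/`simulate` take
#' `--in <path>`. An executable wrapper ships at
#' `system.file("scripts", "swidcarbon", package = "swidcarbon")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the subcommand's result.
#' @export
swidcarbon_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: swidcarbon <generate|estimate|fit|simulate|all> [--seed <int>] [--config <path>] [--in <path>] [--out <dir>]"
  if (length(args) == 0) stop(usage, call. = FALSE)
  cmd <- args[1]
  if (!cmd %in% c("generate", "estimate", "fit", "simulate", "all"))
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
  opts <- parse_cli_flags(args[-1], usage)
  seed <- as.integer(opts$seed %||% 1L)
  out <- opts$out %||% "swidcarbon-output"

  switch(cmd,
    generate = {
      params <- do.call(synthetic_params,
                        if (is.null(opts$config)) list()
                        else pipeline_config(opts$config)$params)
      inv <- generate_inventory(params, seed = seed)
      paths <- write_field_dataset(inv$dataset, out)
      write_plot_carbon_table(inv$targets, file.path(out, "targets.csv"))
      message("wrote synthetic inventory to ", out)
      invisible(inv)
    },
    estimate = {
      ds <- read_field_dataset(opts$`in` %||% stop("estimate needs --in <dir>",
                                                   call. = FALSE))
      ptab <- plot_carbon_table(ds, read_equation_registry(),
                                read_decay_density())
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_plot_carbon_table(ptab, file.path(out, "plot_carbon.csv"))
      message("wrote ", file.path(out, "plot_carbon.csv"))
      invisible(ptab)
    },
    fit = {
      ptab <- read_plot_carbon_table(opts$`in` %||%
                                       stop("fit needs --in <plot_carbon.csv>",
                                            call. = FALSE))
      ranks <- rank_all_subsets(ptab, "total",
                                c("fallow_age", "elevation_z", "interaction"))
      print(as.data.frame(ranks))
      invisible(ranks)
    },
    simulate = {
      ptab <- read_plot_carbon_table(opts$`in` %||%
                                       stop("simulate needs --in <plot_carbon.csv>",
                                            call. = FALSE))
      growth <- fit_model(ptab, "total", fixed = "fallow_age")
      samplers <- list(
        farmland = make_empirical_sampler(
          ptab$total_carbon[ptab$habitat == "farmland"]),
        old_growth = make_empirical_sampler(
          ptab$total_carbon[ptab$habitat == "old_growth"]),
        fallow = make_model_sampler(growth, mode = "draw"))
      scen <- simulate_scenarios(pipeline_config(opts$config)$scenarios,
                                 samplers, seed = seed)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write.csv(scen, file.path(out, "scenario_summary.csv"),
                row.names = FALSE)
      print(scen)
      invisible(scen)
    },
    all = {
      cfg <- pipeline_config(opts$config, seed = seed, out_dir = out)
      run_pipeline(cfg)
    })
}

parse_cli_flags <- function(args, usage) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    flag <- args[i]
    if (!flag %in% c("--seed", "--config", "--in", "--out"))
      stop("unknown flag '", flag, "'\n", usage, call. = FALSE)
    if (i == length(args))
      stop("flag ", flag, " needs a value\n", usage, call. = FALSE)
    opts[[sub("^--", "", flag)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
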