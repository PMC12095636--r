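#' @name pipeline
#' @title End-to-end pipeline orchestration
#'
#' @description
#' Runs the full analysis — simulate (or load), tessellate, standardize,
#' fit, assess, and optionally the year-comparison permutation test — from
#' a single YAML configuration, writing all artifacts plus a run manifest
#' that records seeds, stage outputs and timings so a rerun with the same
#' config reproduces the outputs.
NULL

.read_trial_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

.config_to_trial_config <- function(sim) {
  scheme <- if (!is.null(sim$scheme))
    period_scheme(sim$scheme$start_date, unlist(sim$scheme$period_lengths))
  else spain_scheme()
  args <- sim[setdiff(names(sim), "scheme")]
  args$scheme <- scheme
  args <- args[names(args) %in% names(formals(trial_config))]
  if (!is.null(args$lambda)) args$lambda <- unlist(args$lambda)
  if (!is.null(args$theta_true)) args$theta_true <- unlist(args$theta_true)
  do.call(trial_config, args)
}

#' Run the suppression-analysis pipeline
#'
#' @param config path to a YAML file, or an equivalent nested list, with
#'   entries: `simulation` (a [trial_config()] block) or `data` (paths to
#'   trap-record/release CSVs plus a `scheme` block and trap coordinates),
#'   `species`, `stage`, `baseline_multiplier`, `threshold`, `mcmc`
#'   (`chains`, `iter`, `warmup`, `seed`), and optional `permutation`.
#' @param out_dir directory for artifacts.
#' @return the run manifest (list of class `"run_manifest"`), invisibly
#'   written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- .read_trial_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- list()
  t_stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3),
                            outputs = attr(res, "outputs") %||% character(0))
    res
  }
  with_out <- function(x, paths) { attr(x, "outputs") <- paths; x }

  # --- simulate / load ------------------------------------------------
  sim <- t_stage("simulate", function() {
    if (!is.null(cfg$simulation)) {
      tc <- .config_to_trial_config(cfg$simulation)
      trial <- simulate_trial(tc)
      rec_path <- file.path(out_dir, "trap_records.csv")
      rel_path <- file.path(out_dir, "releases.csv")
      write_trap_records(trial$records, rec_path)
      write_release_events(trial$releases, rel_path)
      jsonlite::write_json(list(theta_true = trial$truth$theta_true,
                                u = trial$truth$u, seeds = trial$truth$seeds),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      with_out(trial, c(rec_path, rel_path, file.path(out_dir, "truth.json")))
    } else if (!is.null(cfg$data)) {
      records <- read_trap_records(cfg$data$trap_records)
      traps <- utils::read.csv(cfg$data$treated_traps)
      scheme <- period_scheme(cfg$data$scheme$start_date,
                              unlist(cfg$data$scheme$period_lengths))
      net <- build_trap_network(traps)
      list(records = records, network_treated = net,
           truth = NULL, scheme_override = scheme)
    } else stop("config must contain a 'simulation' or a 'data' block")
  })
  scheme <- sim$scheme_override %||% sim$truth$config$scheme %||% spain_scheme()
  species <- cfg$species %||% sim$truth$config$species %||% "albopictus"
  stage <- cfg$stage %||% sim$truth$config$stage %||% "egg"

  # --- tessellate -----------------------------------------------------
  net <- t_stage("tessellate", function() {
    net <- sim$network_treated
    path <- file.path(out_dir, "cells.geojson")
    write_choropleth(net$cells, data.frame(trap_id = net$traps$trap_id), path)
    write_edge_list(net$adjacency, file.path(out_dir, "graph_edges.txt"))
    with_out(net, c(path, file.path(out_dir, "graph_edges.txt")))
  })

  # --- standardize ----------------------------------------------------
  obs <- t_stage("standardize", function() {
    o <- standardize_observations(sim$records, scheme, species, stage,
                                  baseline_multiplier = cfg$baseline_multiplier %||% 1)
    path <- file.path(out_dir, "standardized.csv")
    utils::write.csv(as.data.frame(o), path, row.names = FALSE)
    with_out(o, path)
  })

  # --- fit ------------------------------------------------------------
  mcmc <- cfg$mcmc %||% list()
  fit <- t_stage("fit", function() {
    spec <- sit_model_spec(obs, net, threshold = cfg$threshold %||% 0.20)
    f <- fit_spatial_model(spec,
                           chains = mcmc$chains %||% 2,
                           iter = mcmc$iter %||% 8000,
                           warmup = mcmc$warmup %||% 2000,
                           seed = mcmc$seed %||% cfg$seed %||% 1)
    path <- file.path(out_dir, "draws.csv")
    write_draws(f, path)
    theta <- fitted_theta(f)
    utils::write.csv(theta, file.path(out_dir, "theta_site.csv"), row.names = FALSE)
    with_out(f, c(path, paste0(path, ".json"), file.path(out_dir, "theta_site.csv")))
  })

  # --- assess ---------------------------------------------------------
  assessment <- t_stage("assess", function() {
    a <- assess_success(fit, threshold = cfg$threshold %||% 0.20,
                        alpha = cfg$alpha %||% 0.95,
                        seed = mcmc$seed %||% cfg$seed %||% 1)
    paths <- export_success_maps(net, a, out_dir)
    utils::write.csv(a$by_period, file.path(out_dir, "success_rates.csv"),
                     row.names = FALSE)
    with_out(a, c(paths, file.path(out_dir, "success_rates.csv")))
  })

  # --- permtest (optional) -------------------------------------------
  if (!is.null(cfg$permutation)) {
    t_stage("permtest", function() {
      ds <- permutation_dataset(utils::read.csv(cfg$permutation$dataset))
      res <- block_permutation_test(ds, cfg$permutation$year_a,
                                    cfg$permutation$year_b,
                                    n_perm = cfg$permutation$n_perm %||% 9999,
                                    seed = cfg$permutation$seed %||% 1)
      path <- file.path(out_dir, "permutation.json")
      write_permutation_result(res, path)
      with_out(res, path)
    })
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("boostsit")),
    config = cfg, seed = mcmc$seed %||% cfg$seed %||% 1,
    stages = stages,
    summary = list(theta_site = fitted_theta(fit),
                   success_rates = assessment$by_period)
  ), class = "run_manifest")
  jsonlite::write_json(
    list(package_version = manifest$package_version, seed = manifest$seed,
         stages = stages,
         theta_site = fitted_theta(fit),
         success_rates = assessment$by_period),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
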