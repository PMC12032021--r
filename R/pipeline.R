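# Pipeline plumbing: run configuration, multi-run execution with per-run
# output files and a manifest, reloading saved results, and the end-to-end
# simulate -> summarise -> economics driver.

#' Build a simulation configuration
#'
#' @param scenarios character vector of scenario short names.
#' @param n_pop model population size.
#' @param ratio model-to-real population ratio.
#' @param start_year,end_year simulation window.
#' @param runs number of paired runs per scenario (>= 1).
#' @param base_seed integer; run r uses seed `base_seed + r`.
#' @param out_dir optional output directory for per-run CSV files.
#' @param parameters an `msim_parameters` set.
#' @return list of class `msim_config`.
#' @export
simulation_config <- function(scenarios = c("SQ"), n_pop = 7000, ratio = 2000,
                              start_year = 2018, end_year = 2031, runs = 4,
                              base_seed = 1L, out_dir = NULL,
                              parameters = generate_default_parameters()) {
  if (runs < 1) stop("runs must be at least 1")
  if (end_year <= start_year) stop("end_year must exceed start_year")
  structure(list(scenarios = scenarios, n_pop = n_pop, ratio = ratio,
                 start_year = start_year, end_year = end_year, runs = runs,
                 base_seed = as.integer(base_seed), out_dir = out_dir,
                 parameters = parameters),
            class = "msim_config")
}

run_filename <- function(scenario, run_index)
  sprintf("run_%s_%02d.csv", gsub("[^A-Za-z0-9]+", "_", scenario), run_index)

#' Execute all runs of a configuration
#'
#' Runs every scenario `runs` times with seeds `base_seed + run_index`, so run
#' r of every scenario shares a seed (paired, common random numbers). If
#' `out_dir` is set, writes one annual-results CSV per run plus a
#' `manifest.json` (configuration, seeds, file list). Identical configurations
#' produce identical outputs.
#'
#' @param config an `msim_config`.
#' @param progress print per-run progress lines.
#' @return (invisibly) list of `msim_run`.
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "msim_config"))
  runs <- list()
  for (s in config$scenarios) {
    scen <- build_scenario(s)
    for (r in seq_len(config$runs)) {
      if (progress) message("running ", s, " [", r, "/", config$runs, "]")
      run <- simulate_run(scen, ps = config$parameters,
                          n_pop = config$n_pop, ratio = config$ratio,
                          start_year = config$start_year,
                          end_year = config$end_year,
                          seed = config$base_seed + r, run_index = r)
      runs[[length(runs) + 1L]] <- run
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (run in runs) {
      f <- run_filename(run$scenario, run$run_index)
      a <- run$annual
      a$scenario <- run$scenario
      a$run_index <- run$run_index
      a$seed <- run$seed
      a$ratio <- run$ratio
      utils::write.csv(a, file.path(config$out_dir, f), row.names = FALSE)
      files <- c(files, f)
    }
    manifest <- list(scenarios = config$scenarios, n_pop = config$n_pop,
                     ratio = config$ratio, start_year = config$start_year,
                     end_year = config$end_year, runs = config$runs,
                     base_seed = config$base_seed,
                     seeds = config$base_seed + seq_len(config$runs),
                     files = files)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(runs)
}

#' Reload per-run results written by [run_simulation()]
#'
#' @param dir directory containing the run CSV files and manifest.
#' @return list of `msim_run` (annual tables only; logs are not persisted).
#' @export
load_run_results <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(man$files, function(f) {
    a <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    meta <- a[1, c("scenario", "run_index", "seed", "ratio")]
    a <- a[, setdiff(names(a), c("scenario", "run_index", "seed", "ratio"))]
    structure(list(scenario = meta$scenario, run_index = meta$run_index,
                   seed = meta$seed, ratio = meta$ratio, annual = a),
              class = "msim_run")
  })
}

#' End-to-end pipeline: simulate, summarise, economics
#'
#' @param config an `msim_config`; must include the comparator scenario.
#' @param comparator comparator short name (default `"SQ"`).
#' @param years reporting period.
#' @param outcomes outcomes to summarise.
#' @param progress print progress.
#' @return list: `runs`, `summary` (msim_summary), `economics`.
#' @export
pipeline_end_to_end <- function(config, comparator = "SQ",
                                years = 2023:2030,
                                outcomes = c("mmr", "nmr", "sbr",
                                             "maternal_deaths",
                                             "neonatal_deaths",
                                             "maternal_dalys",
                                             "neonatal_dalys"),
                                progress = FALSE) {
  if (!comparator %in% config$scenarios)
    stop("comparator scenario missing from configuration: ", comparator)
  t0 <- Sys.time()
  runs <- run_simulation(config, progress = progress)
  if (progress)
    message("simulation: ", round(difftime(Sys.time(), t0, units = "secs")),
            "s")
  smry <- summarise_runs(runs, outcomes = outcomes, years = years,
                         comparator = comparator)
  econ <- if (length(config$scenarios) > 1)
    economics_report(smry, cet = config$parameters$scalars$cet_usd) else NULL
  list(runs = runs, summary = smry, economics = econ)
}
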