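#' Pipeline configuration presets
#'
#' `paper_defaults` encodes the full estimation schedule (2,000,000
#' post-burn-in iterations, 200,000 burn-in, thinning 2,000; one chain) and
#' is intended for real analyses; `ci` is a reduced schedule
#' (50,000/5,000/50) for tests and demonstrations.
#'
#' @param preset `"paper_defaults"` or `"ci"`.
#' @param ... Overrides merged into the preset (any field of the returned
#'   list, e.g. `seed`, `n_chains`, `design_scale`, `psrf_threshold`).
#' @return A named configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(preset = c("paper_defaults", "ci"), ...) {
  preset <- match.arg(preset)
  base <- list(
    input = NULL,              # CSV path; NULL -> simulate
    design_scale = 1,
    seed = 1L,
    n_iter = 2e6, burn_in = 2e5, thin = 2000,
    n_chains = 1L,
    diagnostics_chains = 0L,   # >= 2 to run a Gelman-Rubin pass
    pairing_seed = 1L,
    per_block = FALSE,
    w_self = 1,
    psrf_threshold = 1.1,
    force = FALSE
  )
  if (preset == "ci") {
    base$n_iter <- 5e4; base$burn_in <- 5e3; base$thin <- 50
  }
  over <- list(...)
  base[names(over)] <- over
  base
}

#' Read a pipeline configuration from JSON
#'
#' The file may name a `preset` (`paper_defaults` or `ci`); remaining keys
#' override preset fields.
#'
#' @param path JSON file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- cfg$preset %||% "paper_defaults"
  cfg$preset <- NULL
  do.call(pipeline_config, c(list(preset = preset), cfg))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> standardize -> fit -> diagnose ->
#' derive -> report. Outputs written under `out_dir`: the standardized
#' observation table, posterior draw tables, a PSRF table (when a
#' diagnostics pass is requested), the derived-statistics report (CSV and
#' JSON mirror), an H-matrix summary, and a reproducibility manifest
#' recording the configuration, seeds, package version, input digests,
#' timings and output files. Fails (unless `force`) when any monitored
#' PSRF exceeds the threshold.
#'
#' @param config A list from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a JSON config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `draws`, `derived`, `h_summary`, `psrf`
#'   (or NULL) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config("ci"), out_dir = tempfile("diallelh_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_digest <- NULL
  if (is.null(config$input)) {
    design <- scale_design(default_design(seed = config$seed), config$design_scale)
    sim <- simulate_diallel(default_truth(), design, seed = config$seed)
    obs <- sim$observations
    write_sim(sim, file.path(out_dir, "simulated"))
  } else {
    obs <- read_fitness_table(config$input)
    input_digest <- unname(tools::md5sum(config$input))
  }
  obs <- standardize_relative_fitness(obs, per_block = config$per_block)
  write_fitness_table(obs, file.path(out_dir, "observations_standardized.csv"))
  design_obs <- derive_design(obs)

  cfg <- mcmc_config(n_iter = config$n_iter, burn_in = config$burn_in,
                     thin = config$thin, n_chains = 1L,
                     seed = config$seed, w_self = config$w_self)
  draws <- fit_gibbs(obs, design_obs, cfg)
  write_draws(draws, file.path(out_dir, "draws"))

  psrf <- NULL
  if (config$diagnostics_chains >= 2) {
    dcfg <- cfg
    dcfg$n_chains <- as.integer(config$diagnostics_chains)
    chains <- fit_gibbs(obs, design_obs, dcfg)
    psrf <- gelman_rubin(chains)
    utils::write.csv(data.frame(parameter = names(psrf), psrf = as.numeric(psrf)),
                     file.path(out_dir, "psrf.csv"), row.names = FALSE)
    bad <- psrf[!is.na(psrf) & psrf > config$psrf_threshold]
    if (length(bad) && !isTRUE(config$force))
      stop("convergence failure: PSRF > ", config$psrf_threshold, " for ",
           paste(names(bad), collapse = ", "), " (use force = TRUE to override)")
  }

  derived <- derive_statistics(draws, pairing_seed = config$pairing_seed)
  utils::write.csv(derived$report, file.path(out_dir, "derived_statistics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(statistics = derived$report,
         sex_differences = as.list(derived$sex_differences)),
    file.path(out_dir, "derived_statistics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  hsum <- summarize_H(draws)
  utils::write.csv(as.data.frame(hsum$matrix),
                   file.path(out_dir, "H_summary.csv"))
  utils::write.csv(data.frame(class = OBSERVATION_CLASSES,
                              residual_variance_mode = unname(hsum$residual)),
                   file.path(out_dir, "H_residuals.csv"), row.names = FALSE)

  outputs <- list.files(out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("diallelh")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = config[!vapply(config, is.null, TRUE)],
    input_digest = input_digest,
    outputs = setdiff(outputs, "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(draws = draws, derived = derived, h_summary = hsum,
                 psrf = psrf, manifest = manifest, out_dir = out_dir))
}
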