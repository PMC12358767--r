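#' Pipeline configuration
#'
#' Bundles everything one screening run needs. Exactly one input mode must
#' be supplied: `input_dir` (a directory of persons/diagnoses/claims CSVs)
#' or `sim` (a [sim_config()] to generate them).
#'
#' @param outcome An [outcome_definition()].
#' @param policy A [screening_policy()].
#' @param input_dir Directory with claims-style CSV tables, or `NULL`.
#' @param sim A [sim_config()], or `NULL`.
#' @param window_days Exposure window length in days (default 30).
#' @param seed Integer seed recorded in all outputs; overrides `sim$seed`
#'   when simulating.
#' @param outdir Output directory for run artifacts.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outcome, policy, input_dir = NULL, sim = NULL,
                            window_days = 30, seed = 1L,
                            outdir = tempfile("triplerx_run_")) {
  if (is.null(input_dir) == is.null(sim)) {
    stop_config("supply exactly one of input_dir or sim")
  }
  stopifnot(inherits(outcome, "outcome_definition"),
            inherits(policy, "screening_policy"))
  structure(list(outcome = outcome, policy = policy, input_dir = input_dir,
                 sim = sim, window_days = window_days,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Bundled demonstration configuration
#'
#' A small simulated screen with one strongly planted adverse triplet
#' (drugs 1-3; per-drug high-dose main effects of 0.5 on the log-odds scale
#' plus a positive three-way interaction, so the log-OR at (2,2,2) far
#' exceeds `log 3`) among five drugs. Used by the examples and the
#' end-to-end tests.
#'
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L, outdir = tempfile("triplerx_demo_")) {
  sim <- sim_config(
    n_persons = 6000L,
    n_drugs = 5L,
    drug_exposure_probs = c(0.55, 0.55, 0.55, 0.35, 0.35),
    ads_logmean = log(c(20, 25, 40, 10, 50)),
    ads_logsd = 0.6,
    planted_effects = list(list(drugs = 1:3,
                                beta = c(0.5, 0.5, 0.5, 0, 0, 0, 0.05))),
    nuisance_main_effects = 0,
    risk_factor_prevalences = c(0.15, 0.10),
    outcome_prevalence = 0.08,
    stratum_sd = 0.3,
    seed = seed)
  outcome <- outcome_definition(
    ade_name = "demo_ade", ade_codes = "ADE01",
    risk_factor_map = c(RF01 = "rf1", RF02 = "rf2"))
  policy <- screening_policy(required_drug_set = "drug_01|mg",
                             min_case_count = 50L, top_k = 5L)
  pipeline_config(outcome = outcome, policy = policy, sim = sim,
                  seed = seed, outdir = outdir)
}

write_run_csv <- function(df, outdir, name) {
  fwrite(df, file.path(outdir, paste0(name, ".csv")))
}

#' Run the full screening pipeline
#'
#' Sequences simulate/ingest, cohort construction, exposure coding,
#' triplet screening, signal profiling and reporting, persisting every
#' stage's tables plus a machine-readable run manifest (seed, stage filter
#' counts, package version) under `config$outdir`. Re-running with the same
#' configuration reproduces identical outputs. A stage failure aborts the
#' run with the failing stage named and leaves partial outputs beside a
#' `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_run` list: `outdir`, `manifest`, `pairs`,
#'   `exposures`, `screen` (the [screen_combinations()] result), `profiles`,
#'   `medians`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))  # stale marker from a previous attempt
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste("stage:", name), conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop_data("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  tables <- stage("ingest", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      pop <- generate_population(sim)
      write_fixture(pop, file.path(outdir, "tables"), config = sim)
      pop
    } else {
      read_claims_tables(config$input_dir)
    }
  })
  counts$persons <- nrow(tables$persons)

  cohort <- stage("cohort", {
    cases <- identify_cases(tables$persons, tables$diagnoses, config$outcome)
    controls <- eligible_controls(tables$persons, tables$diagnoses,
                                  config$outcome, cases = cases)
    m <- match_controls(cases, controls)
    counts$cases <- nrow(cases)
    counts$control_pool <- nrow(controls)
    counts$pairs_matched <- nrow(m$pairs)
    counts$cases_unmatched <- nrow(m$unmatched)
    m
  })
  pairs <- cohort$pairs
  if (!is.null(config$policy$subgroup_min_age)) {
    pairs <- subgroup_filter(pairs, config$policy$subgroup_min_age)
    counts$pairs_in_subgroup <- nrow(pairs)
  }
  if (nrow(pairs) > 0L) {
    write_run_csv(pair_members(pairs), outdir, "pairs")
    write_run_csv(cohort$unmatched, outdir, "unmatched_cases")
  }

  exposures <- stage("exposure", {
    if (nrow(pairs) == 0L) stop_data("no matched pairs")
    code_exposures(pairs, tables$claims, top_k = config$policy$top_k,
                   window_days = config$window_days)
  })
  counts$drug_units <- nrow(exposures$thresholds)
  write_run_csv(exposures$thresholds, outdir, "thresholds")
  write_run_csv(exposures$dose_matrix, outdir, "dose_matrix")

  screen <- stage("screen", {
    screen_combinations(exposures$dose_matrix, config$policy)
  })
  counts$triplets_tested <- nrow(screen$results)
  counts$triplets_quarantined <- nrow(screen$quarantine)
  counts$signals <- if (nrow(screen$results)) sum(screen$results$signal) else 0L
  if (nrow(screen$results) > 0L) {
    write_run_csv(screen$results, outdir, "screening_results")
    sig <- screen$results[screen$results$signal, , drop = FALSE]
    jsonlite::write_json(sig, file.path(outdir, "signals.json"),
                         auto_unbox = TRUE, digits = NA)
    write_fits_json(screen$fits, file.path(outdir, "fits.json"))
  }
  if (nrow(screen$quarantine) > 0L) {
    write_run_csv(screen$quarantine, outdir, "quarantine")
  }

  prof <- stage("profile", {
    profiles <- profile_signals(screen)
    medians <- summarize_medians(profiles)
    if (length(profiles) > 0L) {
      write_run_csv(profile_table(profiles), outdir, "profiles")
      write_run_csv(medians, outdir, "medians")
    }
    list(profiles = profiles, medians = medians)
  })

  manifest <- list(
    package = "triplerx",
    version = as.character(utils::packageVersion("triplerx")),
    seed = config$seed,
    window_days = config$window_days,
    outcome = config$outcome$ade_name,
    policy = unclass(config$policy),
    input_mode = if (is.null(config$sim)) "tables" else "simulation",
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  run <- structure(list(outdir = outdir, manifest = manifest, pairs = pairs,
                        exposures = exposures, screen = screen,
                        profiles = prof$profiles, medians = prof$medians),
                   class = "pipeline_run")
  stage("report", render_report(outdir))
  invisible(run)
}

#' Read a YAML pipeline configuration
#'
#' Maps a YAML document with `outcome`, `policy`, `input_dir`/`sim`,
#' `window_days`, `seed` and `outdir` blocks onto [pipeline_config()].
#'
#' @param path YAML file path.
#' @param seed,outdir Optional overrides.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL, outdir = NULL) {
  y <- yaml::read_yaml(path)
  outcome <- do.call(outcome_definition, y$outcome)
  policy <- do.call(screening_policy, y$policy)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  pipeline_config(outcome = outcome, policy = policy,
                  input_dir = y$input_dir, sim = sim,
                  window_days = y$window_days %||% 30,
                  seed = seed %||% y$seed %||% 1L,
                  outdir = outdir %||% y$outdir %||% tempfile("triplerx_run_"))
}
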