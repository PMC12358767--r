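#' Configuration for the synthetic claims generator
#'
#' Defines a seeded synthetic population of claims-style tables: persons with
#' enrollment intervals, diagnosis records (including emergency-department
#' visits with diagnosis positions), and pharmacy claims whose fills decompose
#' a right-skewed lognormal average daily dose (ADS) into dose-per-unit,
#' quantity and days of supply. The adverse-event outcome at each person's
#' candidate ED visit follows a logistic model with configurable per-drug
#' nuisance main effects and planted triplet dose-interaction effects on the
#' ternary dose codes, plus a normal random intercept shared by persons in
#' the same matching cell (the stratum effect that matching later absorbs).
#'
#' @param n_persons Positive number of persons.
#' @param n_drugs Positive number of drug ingredient-unit combinations.
#' @param drug_exposure_probs Per-drug exposure probability in the 30-day
#'   pre-index window (recycled to `n_drugs`).
#' @param ads_logmean,ads_logsd Per-drug lognormal parameters of ADS
#'   (unit/day); `ads_logsd > 0` (recycled).
#' @param planted_effects List of planted triplet effects, each a list with
#'   `drugs` (three drug indices) and `beta` (length-7 log-OR vector on the
#'   interaction design of [design_row()]).
#' @param nuisance_main_effects Per-drug log-OR applied to the drug's dose
#'   code in the outcome model (recycled).
#' @param risk_factor_prevalences Per-risk-factor prevalence probabilities.
#' @param outcome_prevalence Baseline outcome probability at no exposure.
#' @param stratum_sd Standard deviation of the shared matching-cell random
#'   intercept.
#' @param seed Integer seed; a fixed seed makes the output byte-identical
#'   across runs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_persons,
                       n_drugs = 6L,
                       drug_exposure_probs = 0.4,
                       ads_logmean = log(20),
                       ads_logsd = 0.6,
                       planted_effects = list(),
                       nuisance_main_effects = 0,
                       risk_factor_prevalences = c(0.15, 0.10),
                       outcome_prevalence = 0.10,
                       stratum_sd = 0.3,
                       seed = 1L) {
  if (!is.numeric(n_persons) || length(n_persons) != 1L || n_persons < 1) {
    stop_config("n_persons must be a positive integer")
  }
  if (!is.numeric(n_drugs) || n_drugs < 1) {
    stop_config("n_drugs must be a positive integer")
  }
  n_drugs <- as.integer(n_drugs)
  cfg <- list(
    n_persons = as.integer(n_persons),
    n_drugs = n_drugs,
    drug_exposure_probs = rep_len(drug_exposure_probs, n_drugs),
    ads_logmean = rep_len(ads_logmean, n_drugs),
    ads_logsd = rep_len(ads_logsd, n_drugs),
    planted_effects = planted_effects,
    nuisance_main_effects = rep_len(nuisance_main_effects, n_drugs),
    risk_factor_prevalences = risk_factor_prevalences,
    outcome_prevalence = outcome_prevalence,
    stratum_sd = stratum_sd,
    seed = as.integer(seed)
  )
  probs <- c(cfg$drug_exposure_probs, cfg$risk_factor_prevalences,
             cfg$outcome_prevalence)
  if (any(probs < 0 | probs > 1)) {
    stop_config("all probabilities must lie in [0, 1]")
  }
  if (any(cfg$ads_logsd <= 0)) stop_config("ads_logsd must be > 0")
  cfg$planted_effects <- lapply(planted_effects, function(pe) {
    pe$drugs <- as.integer(unlist(pe$drugs))
    pe$beta <- as.numeric(unlist(pe$beta))
    if (length(pe$drugs) != 3L || anyDuplicated(pe$drugs) ||
        any(pe$drugs < 1) || any(pe$drugs > n_drugs) ||
        length(pe$beta) != 7L || anyNA(pe$beta)) {
      stop_config("each planted effect needs 3 distinct drug indices ",
                  "within 1..n_drugs and a length-7 beta vector")
    }
    pe
  })
  class(cfg) <- "sim_config"
  cfg
}

sim_drug_names <- function(n_drugs) sprintf("drug_%02d", seq_len(n_drugs))

#' Generate a synthetic claims population
#'
#' Simulates the three relational tables of a claims extract — persons,
#' diagnoses and pharmacy claims — with referential integrity. Every person
#' gets one candidate ED visit; the adverse-event outcome at that visit is
#' drawn from the logistic model in [sim_config()] applied to ternary dose
#' codes (coded against each drug's theoretical lognormal median). Small
#' fractions of persons carry short enrollment, a recent prior ED visit, or
#' a prior outcome diagnosis so cohort exclusion rules are exercised, and
#' some fills fall outside the 30-day exposure window.
#'
#' @param config A [sim_config()].
#' @return A list of three data.frames: `persons` (person_id, gender, race,
#'   birth_year, enroll_start, enroll_end), `diagnoses` (person_id, date,
#'   code, position, ed_flag) and `claims` (person_id, fill_date, ingredient,
#'   unit, dose_per_unit, quantity, days_supply). Attribute `truth` carries
#'   the per-person latent dose codes and outcome for diagnostics.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "population"))
  n <- config$n_persons
  nd <- config$n_drugs
  drugs <- sim_drug_names(nd)

  person_id <- sprintf("P%06d", seq_len(n))
  gender <- sample(c("F", "M"), n, replace = TRUE)
  race <- sample(c("white", "black"), n, replace = TRUE, prob = c(0.75, 0.25))
  birth_year <- sample(1935:1980, n, replace = TRUE)
  index_date <- as.Date("2018-01-01") + sample(0:364, n, replace = TRUE)

  # enrollment: ~5% too short to satisfy the >365-day rule
  enroll_days <- ifelse(runif(n) < 0.05,
                        sample(60:300, n, replace = TRUE),
                        sample(500:3000, n, replace = TRUE))
  enroll_start <- index_date - enroll_days
  enroll_end <- index_date + sample(30:365, n, replace = TRUE)

  # risk factors
  nrf <- length(config$risk_factor_prevalences)
  rf <- matrix(0L, n, nrf)
  for (r in seq_len(nrf)) {
    rf[, r] <- rbinom(n, 1L, config$risk_factor_prevalences[r])
  }

  # drug exposure and latent dose codes (vs theoretical lognormal median)
  exposed <- matrix(0L, n, nd)
  ads <- matrix(0, n, nd)
  xcode <- matrix(0L, n, nd)
  for (j in seq_len(nd)) {
    exposed[, j] <- rbinom(n, 1L, config$drug_exposure_probs[j])
    a <- rlnorm(n, config$ads_logmean[j], config$ads_logsd[j])
    ads[, j] <- a * exposed[, j]
    xcode[, j] <- exposed[, j] *
      ifelse(a <= exp(config$ads_logmean[j]), 1L, 2L)
  }

  # outcome model: baseline + nuisance mains + planted triplet effects +
  # shared matching-cell intercept
  lp <- qlogis(config$outcome_prevalence) +
    drop(xcode %*% config$nuisance_main_effects)
  for (pe in config$planted_effects) {
    Z <- dose_design(xcode[, pe$drugs, drop = FALSE])
    lp <- lp + drop(Z %*% pe$beta)
  }
  cell <- interaction(gender, race,
                      apply(rf, 1L, paste, collapse = ""),
                      (birth_year %/% 5L),
                      month_index_of(index_date) %/% 3L,
                      drop = TRUE)
  alpha <- rnorm(nlevels(cell), 0, config$stratum_sd)
  lp <- lp + alpha[as.integer(cell)]
  ade <- rbinom(n, 1L, plogis(lp))

  persons <- data.frame(person_id = person_id, gender = gender, race = race,
                        birth_year = birth_year, enroll_start = enroll_start,
                        enroll_end = enroll_end, stringsAsFactors = FALSE)

  # diagnoses -----------------------------------------------------------
  dx <- list()
  # index ED visit: outcome code in position 1 or 2 for events, generic
  # complaint otherwise
  ade_pos <- sample(1:2, n, replace = TRUE)
  dx[[1L]] <- data.frame(person_id = person_id[ade == 1L],
                         date = index_date[ade == 1L],
                         code = "ADE01",
                         position = ade_pos[ade == 1L],
                         ed_flag = 1L, stringsAsFactors = FALSE)
  dx[[2L]] <- data.frame(person_id = person_id,
                         date = index_date,
                         code = "GEN01",
                         position = ifelse(ade == 1L, 3L - ade_pos, 1L),
                         ed_flag = 1L, stringsAsFactors = FALSE)
  # risk-factor history
  for (r in seq_len(nrf)) {
    idx <- which(rf[, r] == 1L)
    if (length(idx)) {
      dx[[length(dx) + 1L]] <- data.frame(
        person_id = person_id[idx],
        date = index_date[idx] - sample(200:900, length(idx), replace = TRUE),
        code = sprintf("RF%02d", r), position = 1L, ed_flag = 0L,
        stringsAsFactors = FALSE)
    }
  }
  # ~5% recent prior ED visit (violates the 180-day washout)
  idx <- which(runif(n) < 0.05)
  if (length(idx)) {
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = person_id[idx],
      date = index_date[idx] - sample(30:179, length(idx), replace = TRUE),
      code = "GEN01", position = 1L, ed_flag = 1L, stringsAsFactors = FALSE)
  }
  # ~8% distant prior ED visit (allowed)
  idx <- which(runif(n) < 0.08)
  if (length(idx)) {
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = person_id[idx],
      date = index_date[idx] - sample(200:400, length(idx), replace = TRUE),
      code = "GEN01", position = 1L, ed_flag = 1L, stringsAsFactors = FALSE)
  }
  # ~3% prior outcome diagnosis (excluded from cases and controls)
  idx <- which(runif(n) < 0.03)
  if (length(idx)) {
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = person_id[idx],
      date = index_date[idx] - sample(400:800, length(idx), replace = TRUE),
      code = "ADE01", position = 1L, ed_flag = 0L, stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, dx)
  diagnoses <- diagnoses[order(diagnoses$person_id, diagnoses$date,
                               diagnoses$position), ]
  rownames(diagnoses) <- NULL

  # pharmacy claims -----------------------------------------------------
  cl <- list()
  dpu_choices <- c(5, 10, 25, 50)
  for (j in seq_len(nd)) {
    idx <- which(exposed[, j] == 1L)
    if (!length(idx)) next
    n_fills <- sample(1:2, length(idx), replace = TRUE)
    rows <- rep(idx, n_fills)
    days <- sample(c(7L, 14L, 30L), length(rows), replace = TRUE)
    dpu <- sample(dpu_choices, length(rows), replace = TRUE)
    # quantity chosen so pooled ADS over in-window fills equals the latent ADS
    qty <- ads[rows, j] * days / dpu
    cl[[length(cl) + 1L]] <- data.frame(
      person_id = person_id[rows],
      fill_date = index_date[rows] - sample(1:30, length(rows), replace = TRUE),
      ingredient = drugs[j], unit = "mg",
      dose_per_unit = dpu, quantity = qty, days_supply = days,
      stringsAsFactors = FALSE)
  }
  # out-of-window noise fills for ~20% of persons
  idx <- which(runif(n) < 0.20)
  if (length(idx)) {
    j <- sample(seq_len(nd), length(idx), replace = TRUE)
    cl[[length(cl) + 1L]] <- data.frame(
      person_id = person_id[idx],
      fill_date = index_date[idx] - sample(40:120, length(idx), replace = TRUE),
      ingredient = drugs[j], unit = "mg",
      dose_per_unit = 10, quantity = 30, days_supply = 30L,
      stringsAsFactors = FALSE)
  }
  claims <- do.call(rbind, cl)
  claims <- claims[order(claims$person_id, claims$fill_date,
                         claims$ingredient), ]
  rownames(claims) <- NULL

  truth <- data.frame(person_id = person_id, index_date = index_date,
                      ade = ade, stringsAsFactors = FALSE)
  truth <- cbind(truth, setNames(as.data.frame(xcode),
                                 paste0("x_", drugs)))
  out <- list(persons = persons, diagnoses = diagnoses, claims = claims)
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}

#' Configuration for exact conditional-model pair simulation
#'
#' @param n_pairs Number of matched pairs (`>= 1`).
#' @param beta Length-7 log-OR vector (`b1..b7`) of the dose-interaction
#'   model.
#' @param dose_level_probs 3 x 3 matrix: row j is the `{0, 1, 2}` dose-level
#'   distribution of drug j for each pair member (rows must sum to 1).
#' @param seed Integer seed.
#' @return A validated `pair_sim_config` list.
#' @export
pair_sim_config <- function(n_pairs, beta,
                            dose_level_probs = matrix(1 / 3, 3, 3),
                            seed = 1L) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1) {
    stop_config("n_pairs must be >= 1")
  }
  if (length(beta) != 7L || anyNA(beta)) {
    stop_config("beta must be a length-7 numeric vector")
  }
  dose_level_probs <- as.matrix(dose_level_probs)
  if (!identical(dim(dose_level_probs), c(3L, 3L)) ||
      any(dose_level_probs < 0) ||
      any(abs(rowSums(dose_level_probs) - 1) > 1e-8)) {
    stop_config("dose_level_probs must be a 3x3 matrix with rows summing to 1")
  }
  structure(list(n_pairs = as.integer(n_pairs), beta = as.numeric(beta),
                 dose_level_probs = dose_level_probs,
                 seed = as.integer(seed)),
            class = "pair_sim_config")
}

#' Simulate matched pairs from the exact conditional model
#'
#' Draws, for each pair, two dose-triples in `{0, 1, 2}^3` from the
#' configured per-drug level distribution, then assigns the case label
#' within the pair from the conditional probability that remains after the
#' stratum intercept is conditioned out: with linear predictors `eta_a`,
#' `eta_b`, member A is the case with probability
#' `exp(eta_a) / (exp(eta_a) + exp(eta_b))`. Pairs with identical dose
#' triples are concordant and get a fair-coin case label for any `beta`.
#'
#' @param config A [pair_sim_config()].
#' @return A data.frame with one row per pair: `pair_id`, member A and B
#'   dose codes (`x1_a` ... `x3_b`) and `case` (`"a"` or `"b"`).
#' @export
generate_matched_pairs <- function(config) {
  stopifnot(inherits(config, "pair_sim_config"))
  set.seed(derive_seed(config$seed, "pairs"))
  n <- config$n_pairs
  draw <- function(j) {
    sample(0:2, n, replace = TRUE, prob = config$dose_level_probs[j, ])
  }
  A <- cbind(draw(1), draw(2), draw(3))
  B <- cbind(draw(1), draw(2), draw(3))
  eta_a <- drop(dose_design(A) %*% config$beta)
  eta_b <- drop(dose_design(B) %*% config$beta)
  p_a_case <- plogis(eta_a - eta_b)
  a_is_case <- rbinom(n, 1L, p_a_case) == 1L
  data.frame(pair_id = seq_len(n),
             x1_a = A[, 1L], x2_a = A[, 2L], x3_a = A[, 3L],
             x1_b = B[, 1L], x2_b = B[, 2L], x3_b = B[, 3L],
             case = ifelse(a_is_case, "a", "b"),
             stringsAsFactors = FALSE)
}

#' Build a triplet design from simulated pairs
#'
#' @param pairs Output of [generate_matched_pairs()].
#' @param triplet Optional drug-unit labels.
#' @return A [triplet_design()].
#' @export
pairs_design <- function(pairs, triplet = c("drug_01|mg", "drug_02|mg",
                                            "drug_03|mg")) {
  assert_columns(pairs, c("x1_a", "x2_a", "x3_a", "x1_b", "x2_b", "x3_b",
                          "case"), "pairs")
  A <- as.matrix(pairs[, c("x1_a", "x2_a", "x3_a")])
  B <- as.matrix(pairs[, c("x1_b", "x2_b", "x3_b")])
  a_case <- pairs$case == "a"
  case_d <- ifelse(matrix(a_case, nrow(A), 3L), A, B)
  ctrl_d <- ifelse(matrix(a_case, nrow(A), 3L), B, A)
  triplet_design(triplet, case_d, ctrl_d)
}

#' Write simulated tables to a fixture directory
#'
#' Writes each table as an RFC-4180 CSV (ISO-8601 dates) plus a
#' `manifest.json` recording the generating configuration and seed.
#'
#' @param tables Named list of data.frames (e.g. the output of
#'   [generate_population()], or `list(pairs = ...)`).
#' @param directory Target directory (created if absent).
#' @param config Optional configuration recorded in the manifest; defaults
#'   to `attr(tables, "config")`.
#' @return Character vector of file paths written.
#' @export
write_fixture <- function(tables, directory, config = NULL) {
  config <- config %||% attr(tables, "config")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_data("cannot create directory ", directory)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(directory, paste0(nm, ".csv"))
    fwrite(tables[[nm]], p)
    paths <- c(paths, p)
  }
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   tables = names(tables),
                   seed = config$seed,
                   config = unclass(config))
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  c(paths, mp)
}

#' Read claims tables from a fixture directory
#'
#' @param directory Directory holding `persons.csv`, `diagnoses.csv`,
#'   `claims.csv` as written by [write_fixture()].
#' @return A list of data.frames with Date columns restored.
#' @export
read_claims_tables <- function(directory) {
  rd <- function(nm, date_cols) {
    p <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(p)) stop_data("missing table file: ", p)
    df <- as.data.frame(fread(p))
    for (dc in date_cols) df[[dc]] <- as_iso_date(df[[dc]])
    df
  }
  list(persons = rd("persons", c("enroll_start", "enroll_end")),
       diagnoses = rd("diagnoses", "date"),
       claims = rd("claims", "fill_date"))
}
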