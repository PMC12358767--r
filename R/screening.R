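#' Screening policy for three-drug combinations
#'
#' @param required_drug_set Character vector of drug-unit keys
#'   (`"ingredient|unit"`); every tested triplet must contain at least one.
#'   For outcome-specific screens this is the list of outcome-related drugs
#'   (e.g. antidiabetics for hypoglycemia, opioids for opioid-related
#'   events). Must be non-empty.
#' @param min_case_count Minimum number of cases co-exposed (all three dose
#'   codes > 0) for a triplet to be tested (default 500).
#' @param top_k Number of drug-units retained upstream (default 200).
#' @param fdr_level Benjamini-Hochberg false-discovery-rate level for
#'   signal selection (default 0.05).
#' @param or_min Minimum odds ratio at the highest dose configuration
#'   (2,2,2) for a signal (default 1.3).
#' @param subgroup_min_age Optional minimum case age for subgroup screens
#'   (e.g. 65).
#' @param pool_by_test_type If `TRUE`, run BH separately per test label
#'   instead of one pooled family over all eight p-values of all triplets
#'   (pooled is the default and standard behaviour).
#' @param strict_or_all_configs If `TRUE`, require OR `>= or_min` at every
#'   exposed dose configuration, not only (2,2,2).
#' @return A validated `screening_policy` list.
#' @export
screening_policy <- function(required_drug_set,
                             min_case_count = 500L,
                             top_k = 200L,
                             fdr_level = 0.05,
                             or_min = 1.3,
                             subgroup_min_age = NULL,
                             pool_by_test_type = FALSE,
                             strict_or_all_configs = FALSE) {
  if (missing(required_drug_set) || length(required_drug_set) == 0L) {
    stop_config("required_drug_set must be non-empty: every tested triplet ",
                "must include at least one outcome-related drug")
  }
  if (min_case_count < 1) stop_config("min_case_count must be >= 1")
  if (fdr_level <= 0 || fdr_level >= 1) stop_config("fdr_level must be in (0,1)")
  if (or_min < 1) stop_config("or_min must be >= 1")
  structure(list(required_drug_set = as.character(required_drug_set),
                 min_case_count = as.integer(min_case_count),
                 top_k = as.integer(top_k),
                 fdr_level = fdr_level, or_min = or_min,
                 subgroup_min_age = subgroup_min_age,
                 pool_by_test_type = isTRUE(pool_by_test_type),
                 strict_or_all_configs = isTRUE(strict_or_all_configs)),
            class = "screening_policy")
}

battery_labels <- function() {
  c(clrm_term_names(), "or222")
}

#' Enumerate testable drug triplets
#'
#' Candidate triplets are all unordered sets of three distinct drug-unit
#' columns of the dose matrix for which at least `min_case_count` cases are
#' co-exposed (all three dose codes > 0) and which intersect the policy's
#' required drug set. Output order is canonical: lexicographic within each
#' triplet, then across triplets.
#'
#' @param dose_matrix Dose matrix from [build_dose_matrix()].
#' @param policy A [screening_policy()].
#' @return A data.frame `(drug1, drug2, drug3, n_co_exposed_cases)`.
#' @export
enumerate_triplets <- function(dose_matrix, policy) {
  stopifnot(inherits(policy, "screening_policy"))
  drug_cols <- setdiff(names(dose_matrix), c("pair_id", "role"))
  drug_cols <- sort(drug_cols)
  cases <- dose_matrix[dose_matrix$role == "case", drug_cols, drop = FALSE]
  E <- as.matrix(cases) > 0L
  if (length(drug_cols) < 3L) {
    return(data.frame(drug1 = character(0), drug2 = character(0),
                      drug3 = character(0),
                      n_co_exposed_cases = integer(0)))
  }
  combos <- combn(drug_cols, 3L)
  n_co <- apply(combos, 2L, function(tr) {
    sum(E[, tr[1L]] & E[, tr[2L]] & E[, tr[3L]])
  })
  keep <- n_co >= policy$min_case_count &
    apply(combos, 2L, function(tr) any(tr %in% policy$required_drug_set))
  out <- data.frame(drug1 = combos[1L, keep], drug2 = combos[2L, keep],
                    drug3 = combos[3L, keep],
                    n_co_exposed_cases = as.integer(n_co[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$drug1, out$drug2, out$drug3), , drop = FALSE]
}

# Build the triplet design for three dose-matrix columns.
design_from_dose_matrix <- function(dose_matrix, triplet) {
  dm <- dose_matrix[order(dose_matrix$pair_id, dose_matrix$role), ,
                    drop = FALSE]
  cases <- dm[dm$role == "case", , drop = FALSE]
  ctrls <- dm[dm$role == "control", , drop = FALSE]
  stopifnot(identical(cases$pair_id, ctrls$pair_id))
  triplet_design(triplet,
                 as.matrix(cases[, triplet, drop = FALSE]),
                 as.matrix(ctrls[, triplet, drop = FALSE]))
}

#' Eight-test one-sided Wald battery for one triplet
#'
#' Tests `beta_j <= 0` for each of the seven model coefficients plus the
#' highest-dose composite `2b1+2b2+2b3+4b4+4b5+4b6+8b7 <= 0` (the log-OR at
#' dose configuration (2,2,2)).
#'
#' @param design The triplet's [triplet_design()] (unused beyond validation;
#'   kept so batteries are self-describing).
#' @param fit The triplet's [fit_clrm()] result.
#' @return A data.frame with 8 rows: `label`, `estimate`, `se`, `z`,
#'   `p_one_sided`. For separated or unconverged fits all test fields are
#'   `NA` (an "untested" sentinel record excluded from FDR pooling).
#' @export
run_battery <- function(design, fit) {
  labels <- battery_labels()
  if (!isTRUE(fit$converged) || isTRUE(fit$separated)) {
    return(data.frame(label = labels, estimate = NA_real_, se = NA_real_,
                      z = NA_real_, p_one_sided = NA_real_,
                      stringsAsFactors = FALSE))
  }
  contrasts <- c(lapply(seq_len(7L), function(j) as.numeric(seq_len(7L) == j)),
                 list(unname(design_row(2L, 2L, 2L))))
  res <- mapply(function(cv, lb) wald_contrast(fit, cv, label = lb),
                contrasts, labels, SIMPLIFY = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled Benjamini-Hochberg q-values
#'
#' Standard step-up BH with monotonicity enforcement, applied to one pooled
#' family (all eight p-values of all tested triplets).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed for
#'   untested entries; they are ignored and returned as `NA`).
#' @return q-values of the same length.
#' @export
apply_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Screen all eligible triplets of a dose matrix
#'
#' Runs the full screening stage: triplet enumeration, per-triplet model fit
#' and eight-test battery, pooled BH-FDR over every tested triplet's eight
#' p-values, and signal selection. Triplets whose fit fails, separates or
#' does not converge are quarantined (reported, excluded from pooling).
#'
#' @param dose_matrix Dose matrix from [build_dose_matrix()].
#' @param policy A [screening_policy()].
#' @return A `screening_run` list: `results` (one row per tested triplet
#'   with coefficient estimates, 8 p-values, 8 q-values, `or_222`, `signal`,
#'   `reason_codes`), `fits` (named list of `triplet_fit`s), `quarantine`
#'   (triplets not tested, with reasons), `policy`.
#' @export
screen_combinations <- function(dose_matrix, policy) {
  triplets <- enumerate_triplets(dose_matrix, policy)
  fits <- list()
  rows <- list()
  quarantine <- list()
  for (i in seq_len(nrow(triplets))) {
    tr <- unlist(triplets[i, c("drug1", "drug2", "drug3")], use.names = FALSE)
    key <- paste(tr, collapse = " + ")
    design <- design_from_dose_matrix(dose_matrix, tr)
    fit <- tryCatch(fit_clrm(design), error = function(e) e)
    if (inherits(fit, "error")) {
      quarantine[[key]] <- data.frame(drug1 = tr[1L], drug2 = tr[2L],
                                      drug3 = tr[3L],
                                      reason = conditionMessage(fit),
                                      stringsAsFactors = FALSE)
      next
    }
    if (!fit$converged || fit$separated) {
      quarantine[[key]] <- data.frame(drug1 = tr[1L], drug2 = tr[2L],
                                      drug3 = tr[3L],
                                      reason = if (fit$separated)
                                        "separation" else "no convergence",
                                      stringsAsFactors = FALSE)
      next
    }
    fits[[key]] <- fit
    bat <- run_battery(design, fit)
    row <- data.frame(drug1 = tr[1L], drug2 = tr[2L], drug3 = tr[3L],
                      n_pairs = fit$n_pairs,
                      n_discordant = fit$n_discordant,
                      n_co_exposed_cases = triplets$n_co_exposed_cases[i],
                      stringsAsFactors = FALSE)
    for (j in seq_len(7L)) row[[paste0("b", j)]] <- unname(fit$beta[j])
    for (j in seq_len(8L)) {
      row[[paste0("p_", bat$label[j])]] <- bat$p_one_sided[j]
    }
    row$or_222 <- exp(log_or_at(fit, 2L, 2L, 2L)$estimate)
    rows[[key]] <- row
  }
  results <- if (length(rows)) {
    as.data.frame(rbindlist(rows))
  } else {
    data.frame()
  }
  quarantine <- if (length(quarantine)) {
    as.data.frame(rbindlist(quarantine))
  } else {
    data.frame(drug1 = character(0), drug2 = character(0),
               drug3 = character(0), reason = character(0))
  }
  if (nrow(results) > 0L) {
    pcols <- paste0("p_", battery_labels())
    qcols <- paste0("q_", battery_labels())
    P <- as.matrix(results[, pcols])
    Q <- if (policy$pool_by_test_type) {
      apply(P, 2L, apply_bh)
    } else {
      matrix(apply_bh(as.vector(P)), nrow = nrow(P), ncol = ncol(P))
    }
    colnames(Q) <- qcols
    results <- cbind(results, as.data.frame(Q))
    results <- select_signals(results, policy)
  }
  structure(list(results = results, fits = fits, quarantine = quarantine,
                 policy = policy),
            class = "screening_run")
}

# interaction terms each drug participates in (b4 = x1x2, b5 = x1x3,
# b6 = x2x3, b7 = x1x2x3)
drug_interaction_terms <- list(c("x1x2", "x1x3", "x1x2x3"),
                               c("x1x2", "x2x3", "x1x2x3"),
                               c("x1x3", "x2x3", "x1x2x3"))

#' Flag adverse-combination signals
#'
#' A tested triplet is a signal when (a) the highest-dose composite test has
#' q-value below the FDR level, (b) the odds ratio at (2,2,2) is at least
#' `or_min`, and (c) each of the three drugs is individually "risky": its
#' main-effect estimate is positive, or it participates in an interaction
#' term whose q-value is below the FDR level. `reason_codes` records every
#' failed criterion for non-signals so alternative readings can be audited.
#'
#' @param results Screening results table with `q_*`, `b*` and `or_222`
#'   columns.
#' @param policy A [screening_policy()].
#' @return `results` with `signal` (logical) and `reason_codes` (character)
#'   columns filled in.
#' @export
select_signals <- function(results, policy) {
  if (nrow(results) == 0L) {
    results$signal <- logical(0)
    results$reason_codes <- character(0)
    return(results)
  }
  lvl <- policy$fdr_level
  ok_fdr <- results$q_or222 < lvl
  ok_or <- results$or_222 >= policy$or_min
  pattern_ok <- rep(TRUE, nrow(results))
  for (d in 1:3) {
    main_pos <- results[[paste0("b", d)]] > 0
    inter_q <- sapply(drug_interaction_terms[[d]], function(tm)
      results[[paste0("q_", tm)]] < lvl)
    inter_q <- matrix(inter_q, nrow = nrow(results))
    pattern_ok <- pattern_ok & (main_pos | rowSums(inter_q) > 0)
  }
  reasons <- character(nrow(results))
  reasons <- ifelse(!ok_fdr, paste0(reasons, "composite_fdr;"), reasons)
  reasons <- ifelse(!ok_or, paste0(reasons, "or_below_min;"), reasons)
  reasons <- ifelse(!pattern_ok, paste0(reasons, "effect_pattern;"), reasons)
  results$signal <- ok_fdr & ok_or & pattern_ok
  results$reason_codes <- sub(";$", "", reasons)
  results
}

#' Restrict a matched cohort to older cases
#'
#' Keeps pairs whose case age at index is at least `min_age`; pairs are
#' dropped whole so matching is preserved. Thresholds and fits must be
#' recomputed on the subgroup afterwards.
#'
#' @param pairs Matched-pair table from [match_controls()].
#' @param min_age Minimum case age in years (e.g. 65).
#' @return The retained pair rows.
#' @export
subgroup_filter <- function(pairs, min_age) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs[pairs$case_age >= min_age, , drop = FALSE]
}
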