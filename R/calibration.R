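#' Wald confidence-interval coverage study
#'
#' Repeatedly simulates matched pairs from the exact conditional model at a
#' fixed coefficient vector, fits the seven-term model, and records whether
#' each nominal 95% Wald interval covers its true coefficient.
#'
#' @param beta True length-7 coefficient vector.
#' @param n_pairs Pairs per replicate.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param conf_level Nominal coverage.
#' @return A data.frame with one row per coefficient: `term`, `coverage`,
#'   `n_reps` (converged replicates used) and `mc_se` (binomial simulation
#'   standard error at the nominal level).
#' @export
coverage_study <- function(beta, n_pairs = 5000L, n_reps = 1000L, seed = 1L,
                           conf_level = 0.95) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  cover <- matrix(NA, n_reps, 7L)
  for (r in seq_len(n_reps)) {
    cfg <- pair_sim_config(n_pairs, beta = beta,
                           seed = derive_seed(seed, paste0("cov", r)))
    fit <- fit_clrm(pairs_design(generate_matched_pairs(cfg)))
    if (!fit$converged || fit$separated) next
    se <- sqrt(diag(fit$cov))
    cover[r, ] <- abs(fit$beta - beta) <= zq * se
  }
  used <- colSums(!is.na(cover))
  data.frame(term = clrm_term_names(),
             coverage = colMeans(cover, na.rm = TRUE),
             n_reps = used,
             mc_se = sqrt(conf_level * (1 - conf_level) / used))
}

#' Type-I error of the highest-dose composite test
#'
#' Under the global null (`beta = 0`) the one-sided composite Wald test of
#' the log-OR at (2,2,2) should reject at its nominal level.
#'
#' @param n_pairs Pairs per replicate.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param alpha Nominal one-sided level.
#' @return A list: `rejection_rate`, `n_reps` (converged), `mc_se`.
#' @export
type1_error_study <- function(n_pairs = 5000L, n_reps = 3000L, seed = 1L,
                              alpha = 0.05) {
  comp <- unname(design_row(2L, 2L, 2L))
  rej <- rep(NA, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- pair_sim_config(n_pairs, beta = rep(0, 7),
                           seed = derive_seed(seed, paste0("t1e", r)))
    fit <- fit_clrm(pairs_design(generate_matched_pairs(cfg)))
    if (!fit$converged || fit$separated) next
    rej[r] <- wald_contrast(fit, comp, "or222")$p_one_sided < alpha
  }
  used <- sum(!is.na(rej))
  list(rejection_rate = mean(rej, na.rm = TRUE), n_reps = used,
       mc_se = sqrt(alpha * (1 - alpha) / used))
}

#' False-signal rate of the screen under a global null
#'
#' Simulates replicate screens of independent null triplets (`beta = 0`),
#' runs the eight-test battery per triplet, pools all p-values of each
#' screen into one Benjamini-Hochberg family and applies the full signal
#' selection rule. Reports the proportion of tested triplets falsely
#' flagged as signals.
#'
#' @param n_screens Number of replicate screens.
#' @param n_triplets Triplets per screen.
#' @param n_pairs Pairs per triplet.
#' @param seed Integer seed.
#' @param policy Selection policy (drug-set/frequency filters do not apply
#'   here; FDR, OR and pattern criteria do).
#' @return A list: `false_signal_rate`, `n_triplets_total`, `mc_se` (at the
#'   policy's FDR level), `per_screen` (false signals per screen).
#' @export
fdr_calibration_study <- function(n_screens = 500L, n_triplets = 50L,
                                  n_pairs = 150L, seed = 1L,
                                  policy = screening_policy("any")) {
  per_screen <- integer(n_screens)
  tested <- integer(n_screens)
  for (s in seq_len(n_screens)) {
    rows <- vector("list", n_triplets)
    for (k in seq_len(n_triplets)) {
      cfg <- pair_sim_config(
        n_pairs, beta = rep(0, 7),
        seed = derive_seed(seed, sprintf("fdr%d_%d", s, k)))
      fit <- fit_clrm(pairs_design(generate_matched_pairs(cfg)))
      if (!fit$converged || fit$separated) next
      bat <- run_battery(NULL, fit)
      row <- data.frame(drug1 = "d1", drug2 = "d2", drug3 = "d3")
      for (j in seq_len(7L)) row[[paste0("b", j)]] <- unname(fit$beta[j])
      for (j in seq_len(8L)) {
        row[[paste0("p_", bat$label[j])]] <- bat$p_one_sided[j]
      }
      row$or_222 <- exp(sum(design_row(2, 2, 2) * fit$beta))
      rows[[k]] <- row
    }
    results <- as.data.frame(rbindlist(rows))
    pcols <- paste0("p_", battery_labels())
    P <- as.matrix(results[, pcols])
    Q <- matrix(apply_bh(as.vector(P)), nrow = nrow(P))
    colnames(Q) <- paste0("q_", battery_labels())
    results <- cbind(results, as.data.frame(Q))
    results <- select_signals(results, policy)
    per_screen[s] <- sum(results$signal)
    tested[s] <- nrow(results)
  }
  total <- sum(tested)
  lvl <- policy$fdr_level
  list(false_signal_rate = sum(per_screen) / total,
       n_triplets_total = total,
       mc_se = sqrt(lvl * (1 - lvl) / total),
       per_screen = per_screen)
}

#' Detection study for the bundled demonstration screen
#'
#' Runs the demonstration pipeline under several seeds and checks, per run,
#' that the planted triplet is flagged as a signal and that its estimated
#' odds ratios increase along the no/low/high diagonal of the dose grid.
#'
#' @param n_runs Number of seeded runs.
#' @param seed Base seed; run r uses a seed derived from it.
#' @return A data.frame with one row per run: `seed`, `signal`, `monotone`,
#'   `or_111`, `or_222`.
#' @export
demo_detection_study <- function(n_runs = 20L, seed = 1L) {
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, paste0("demo", r))
    dir <- tempfile("triplerx_det_")
    run <- run_pipeline(demo_pipeline_config(seed = run_seed, outdir = dir))
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    res <- run$screen$results
    planted <- which(res$drug1 == "drug_01|mg" & res$drug2 == "drug_02|mg" &
                       res$drug3 == "drug_03|mg")
    sig <- length(planted) == 1L && res$signal[planted]
    mono <- FALSE
    or111 <- or222 <- NA_real_
    key <- "drug_01|mg + drug_02|mg + drug_03|mg"
    if (!is.null(run$screen$fits[[key]])) {
      pr <- build_profile(run$screen$fits[[key]])
      g <- setNames(pr$or_grid$log_or, pr$or_grid$label)
      or111 <- exp(g[["111"]]); or222 <- exp(g[["222"]])
      mono <- g[["111"]] > 0 && g[["222"]] > g[["111"]]
    }
    out[[r]] <- data.frame(seed = run_seed, signal = sig, monotone = mono,
                           or_111 = or111, or_222 = or222)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
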