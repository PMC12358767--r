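#' Render a human-readable run report
#'
#' Summarises a completed pipeline run directory as Markdown: stage filter
#' counts, matched-cohort demographics, tested/signal triplet counts, and
#' one dose-profile table per signal (rows ordered by configuration label).
#' Every number is read back from the run's own CSV/JSON artifacts, so the
#' report cannot drift from them.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @param path Output file (default `report.md` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
render_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (file.exists(file.path(run_dir, "FAILED"))) {
    stop_data("run directory is marked FAILED; no report rendered")
  }
  if (!file.exists(mf_path)) stop_data("incomplete run: manifest.json missing")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  lines <- c(
    paste0("# Three-drug combination screen: ", mf$outcome),
    "",
    sprintf("Package triplerx %s, seed %d, %d-day exposure window.",
            mf$version, mf$seed, mf$window_days),
    "",
    "## Stage counts",
    "")
  cn <- names(mf$counts)
  lines <- c(lines, sprintf("- %s: %s", cn, unlist(mf$counts)), "")

  pairs_path <- file.path(run_dir, "pairs.csv")
  if (file.exists(pairs_path)) {
    members <- as.data.frame(fread(pairs_path))
    cases <- members[members$role == "case", , drop = FALSE]
    lines <- c(lines, "## Matched cohort", "",
               sprintf("- matched pairs: %d", nrow(cases)),
               sprintf("- case age: median %.0f (range %d-%d)",
                       median(cases$age), min(cases$age), max(cases$age)),
               "")
  }

  res_path <- file.path(run_dir, "screening_results.csv")
  n_sig <- 0L
  if (file.exists(res_path)) {
    res <- as.data.frame(fread(res_path))
    n_sig <- sum(res$signal)
    lines <- c(lines, "## Screening", "",
               sprintf("- triplets tested: %d", nrow(res)),
               sprintf("- signals: %d", n_sig), "")
  } else {
    lines <- c(lines, "## Screening", "", "- triplets tested: 0",
               "- signals: 0", "")
  }

  prof_path <- file.path(run_dir, "profiles.csv")
  if (n_sig > 0L && file.exists(prof_path)) {
    prof <- as.data.frame(fread(prof_path))
    med_path <- file.path(run_dir, "medians.csv")
    if (file.exists(med_path)) {
      med <- as.data.frame(fread(med_path))
      lines <- c(lines, "## Median ORs across signals", "",
                 sprintf("- %s: %.2f (n = %d)", med$stratum, med$median_or,
                         med$n),
                 "")
    }
    for (tp in unique(prof$triplet)) {
      sub <- prof[prof$triplet == tp, , drop = FALSE]
      sub <- sub[order(sub$label), , drop = FALSE]
      lines <- c(lines, paste0("## Dose profile: ", tp), "",
                 "| config | OR | 95% CI | p (vs 222) |",
                 "|---|---|---|---|",
                 sprintf("| %s | %.2f | %.2f-%.2f | %s |",
                         sub$label, sub$or, sub$ci_low, sub$ci_high,
                         ifelse(is.na(sub$p_reduction), "",
                                sprintf("%.3g", sub$p_reduction))),
                 "")
    }
  } else {
    lines <- c(lines, "No signals; no dose profiles to report.", "")
  }
  writeLines(lines, path)
  invisible(path)
}
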