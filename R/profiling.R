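#' Dose-reduction and discontinuation contrasts
#'
#' The ten comparisons of the highest dose configuration (2,2,2) against a
#' reduced configuration, labelled by the reduced configuration: one-drug
#' dose reductions (122, 212, 221), two-drug (112, 121, 211), all-three
#' (111), and one-drug discontinuations (022, 202, 220). Each contrast
#' vector is the design-row difference `design_row(2,2,2) -
#' design_row(config)`.
#'
#' @return Named list of length-10: contrast coefficient vectors keyed by
#'   configuration label.
#' @export
reduction_contrasts <- function() {
  labels <- c("221", "212", "122", "211", "121", "112", "111",
              "220", "202", "022")
  high <- design_row(2L, 2L, 2L)
  out <- lapply(labels, function(lb) {
    x <- as.integer(strsplit(lb, "")[[1L]])
    unname(high - design_row(x[1L], x[2L], x[3L]))
  })
  names(out) <- labels
  out
}

all_dose_configs <- function() {
  g <- expand.grid(x3 = 0:2, x2 = 0:2, x1 = 0:2)
  g <- g[, c("x1", "x2", "x3")]
  g$label <- paste0(g$x1, g$x2, g$x3)
  g[order(g$label), , drop = FALSE]
}

#' Full dose-grid odds-ratio profile for one triplet
#'
#' Estimates the OR (with 95% Wald CI) of every configuration in `{0,1,2}^3`
#' relative to no exposure, and runs the ten dose-reduction /
#' discontinuation z-tests of the highest dose level against each reduced
#' configuration (one-sided, `H0:` no risk reduction). A reduction is
#' flagged significant at p < 0.05.
#'
#' @param fit A converged [fit_clrm()] result.
#' @param conf_level Confidence level of the OR intervals.
#' @return A `dose_profile` list: `triplet`, `or_grid` (27 rows: label, or,
#'   ci_low, ci_high), `reduction_tests` (10 rows: label, estimate, se, z,
#'   p_one_sided, or, percent_reduction, significant).
#' @export
build_profile <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "triplet_fit"))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  grid <- all_dose_configs()
  est <- vapply(seq_len(nrow(grid)), function(i) {
    lo <- log_or_at(fit, grid$x1[i], grid$x2[i], grid$x3[i])
    c(lo$estimate, lo$se)
  }, numeric(2L))
  or_grid <- data.frame(label = grid$label,
                        log_or = est[1L, ], se = est[2L, ],
                        or = exp(est[1L, ]),
                        ci_low = exp(est[1L, ] - zq * est[2L, ]),
                        ci_high = exp(est[1L, ] + zq * est[2L, ]),
                        stringsAsFactors = FALSE)
  or222 <- or_grid$or[or_grid$label == "222"]
  cons <- reduction_contrasts()
  tests <- lapply(names(cons), function(lb) {
    res <- wald_contrast(fit, cons[[lb]], label = lb)
    or_low <- or_grid$or[or_grid$label == lb]
    data.frame(label = lb, estimate = res$estimate, se = res$se, z = res$z,
               p_one_sided = res$p_one_sided, or = or_low,
               percent_reduction = percent_reduction(or222, or_low),
               significant = res$p_one_sided < 0.05,
               stringsAsFactors = FALSE)
  })
  structure(list(triplet = fit$triplet, or_grid = or_grid,
                 reduction_tests = do.call(rbind, tests)),
            class = "dose_profile")
}

#' Percentage decrement of an odds ratio
#'
#' `100 * (1 - or_low / or_high)`: the percent reduction of the OR at a
#' lower dose configuration relative to the highest dose level.
#'
#' @param or_high,or_low Positive odds ratios.
#' @return Percentage (vectorised).
#' @export
percent_reduction <- function(or_high, or_low) {
  if (any(or_high <= 0) || any(or_low <= 0)) {
    stop_data("odds ratios must be positive")
  }
  100 * (1 - or_low / or_high)
}

reduction_strata <- list(
  "highest dose" = "222",
  "lower dose for one drug" = c("122", "212", "221"),
  "lower doses for two drugs" = c("112", "121", "211"),
  "lower doses for three drugs" = "111")

#' Median ORs by dose-reduction stratum across profiles
#'
#' Pools, across the supplied profiles, the ORs of the configurations in
#' each stratum — highest dose (222), a lower dose for one drug
#' (122/212/221, three ORs per profile), lower doses for two drugs
#' (112/121/211) and lower doses for all three (111) — and reports the
#' sample median per stratum. Pooling is over all contributing ORs, not
#' per-profile medians; `per_profile = TRUE` aggregates each profile to its
#' stratum median first.
#'
#' @param profiles List of [build_profile()] results (e.g. the signal set).
#' @param per_profile Aggregate within profile before taking the median.
#' @return A data.frame `(stratum, median_or, n)`; empty for an empty
#'   profile list.
#' @export
summarize_medians <- function(profiles, per_profile = FALSE) {
  if (length(profiles) == 0L) {
    return(data.frame(stratum = character(0), median_or = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(reduction_strata), function(st) {
    labels <- reduction_strata[[st]]
    ors <- unlist(lapply(profiles, function(pr) {
      v <- pr$or_grid$or[pr$or_grid$label %in% labels]
      if (per_profile) median(v) else v
    }))
    data.frame(stratum = st, median_or = median(ors), n = length(ors),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Profiles for every signal of a screening run
#'
#' @param run A [screen_combinations()] result.
#' @param signals_only Profile only flagged signals (default) or all tested
#'   triplets.
#' @return Named list of `dose_profile`s.
#' @export
profile_signals <- function(run, signals_only = TRUE) {
  stopifnot(inherits(run, "screening_run"))
  res <- run$results
  if (nrow(res) == 0L) return(list())
  keep <- if (signals_only) which(res$signal) else seq_len(nrow(res))
  keys <- paste(res$drug1[keep], res$drug2[keep], res$drug3[keep],
                sep = " + ")
  out <- lapply(keys, function(k) build_profile(run$fits[[k]]))
  names(out) <- keys
  out
}

profile_table <- function(profiles) {
  if (length(profiles) == 0L) {
    return(data.frame(triplet = character(0), label = character(0),
                      or = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_reduction = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(profiles), function(k) {
    pr <- profiles[[k]]
    g <- pr$or_grid
    rt <- pr$reduction_tests
    data.frame(triplet = k, label = g$label, or = g$or, ci_low = g$ci_low,
               ci_high = g$ci_high,
               p_reduction = rt$p_one_sided[match(g$label, rt$label)],
               significant = rt$significant[match(g$label, rt$label)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
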