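#' Average daily dose per drug-unit in the pre-index window
#'
#' For each drug ingredient-unit combination with at least one fill dated in
#' `[index_date - window_days, index_date)`, the average daily dose (ADS) is
#' the total dispensed dose mass divided by the total days of supply over
#' those fills: `sum(dose_per_unit * quantity) / sum(days_supply)`. For a
#' single fill this is the familiar `(dose x quantity) / days of supply`.
#' In-window fills with non-positive `days_supply` are rejected with a
#' warning and do not contribute.
#'
#' @param claims Pharmacy-claims table (`person_id`, `fill_date`,
#'   `ingredient`, `unit`, `dose_per_unit`, `quantity`, `days_supply`).
#' @param person_id Person identifier.
#' @param index_date Index date anchoring the window.
#' @param window_days Positive window length in days (default 30).
#' @return A data.frame `(ingredient, unit, ads)` with one row per exposed
#'   drug-unit; drug-units without in-window fills are absent (ADS 0).
#' @export
compute_ads <- function(claims, person_id, index_date, window_days = 30) {
  members <- data.frame(pair_id = NA_integer_, role = NA_character_,
                        person_id = person_id,
                        index_date = as_iso_date(index_date),
                        stringsAsFactors = FALSE)
  out <- member_ads(claims, members, window_days = window_days)
  out[, c("ingredient", "unit", "ads")]
}

#' ADS table for all members of a matched cohort
#'
#' @param claims Pharmacy-claims table.
#' @param members Member table (`pair_id`, `role`, `person_id`,
#'   `index_date`), e.g. from [pair_members()].
#' @inheritParams compute_ads
#' @return A data.frame `(pair_id, role, person_id, ingredient, unit, ads)`
#'   restricted to exposed drug-units (`ads > 0` support).
#' @export
member_ads <- function(claims, members, window_days = 30) {
  assert_columns(claims, c("person_id", "fill_date", "ingredient", "unit",
                           "dose_per_unit", "quantity", "days_supply"),
                 "claims")
  if (window_days <= 0) stop_config("window_days must be > 0")
  cl <- as.data.table(claims)
  cl[, fill_date := as_iso_date(fill_date)]
  mb <- as.data.table(members)
  mb[, index_date := as_iso_date(index_date)]
  j <- merge(mb, cl, by = "person_id", allow.cartesian = TRUE)
  j <- j[fill_date >= index_date - window_days & fill_date < index_date]
  bad <- j[days_supply <= 0]
  if (nrow(bad) > 0L) {
    warning(sprintf(
      "rejected %d in-window fill(s) with non-positive days_supply", nrow(bad)),
      call. = FALSE)
    j <- j[days_supply > 0]
  }
  if (nrow(j) == 0L) {
    return(data.frame(pair_id = integer(0), role = character(0),
                      person_id = character(0), ingredient = character(0),
                      unit = character(0), ads = numeric(0),
                      stringsAsFactors = FALSE))
  }
  agg <- j[, .(ads = sum(dose_per_unit * quantity) / sum(days_supply)),
           by = .(pair_id, role, person_id, ingredient, unit)]
  setorder(agg, pair_id, role, ingredient, unit)
  as.data.frame(agg)
}

drug_unit_key <- function(ingredient, unit) paste(ingredient, unit, sep = "|")

#' Select the most frequent drug-units among exposed cases
#'
#' Ranks drug ingredient-unit combinations by the number of distinct exposed
#' cases (ADS > 0) and keeps the top `k`; an ingredient dispensed in two
#' units (e.g. milligram and percent) forms two distinct drug-units. Ties
#' are broken lexicographically on `(ingredient, unit)` so the selection is
#' deterministic.
#'
#' @param case_ads_table ADS table restricted to cases (see [member_ads()]).
#' @param k Number of drug-units to retain (default 200).
#' @return A data.frame `(ingredient, unit, n_exposed_cases)` in rank order.
#' @export
select_top_drug_units <- function(case_ads_table, k = 200L) {
  if (k < 1) stop_config("k must be >= 1")
  tab <- as.data.table(case_ads_table)[ads > 0]
  counts <- tab[, .(n_exposed_cases = uniqueN(person_id)),
                by = .(ingredient, unit)]
  setorder(counts, -n_exposed_cases, ingredient, unit)
  as.data.frame(head(counts, k))
}

#' Median-ADS dose thresholds from exposed cases
#'
#' The low/high dose cutoff of each drug-unit is the sample median ADS among
#' exposed cases only (ADS > 0); for an even number of exposed cases the
#' mean of the two middle order statistics is used. Controls never influence
#' thresholds. Drug-units with no exposed case are dropped with a warning.
#'
#' @param case_ads_table ADS table restricted to cases.
#' @param drug_units Data.frame `(ingredient, unit)` of drug-units to
#'   threshold (e.g. from [select_top_drug_units()]).
#' @return A data.frame `(ingredient, unit, median_ads, n_exposed_cases)`.
#' @export
compute_thresholds <- function(case_ads_table, drug_units) {
  tab <- as.data.table(case_ads_table)[ads > 0]
  du <- as.data.table(drug_units)[, .(ingredient, unit)]
  med <- tab[du, on = c("ingredient", "unit"), nomatch = NULL][
    , .(median_ads = median(ads), n_exposed_cases = uniqueN(person_id)),
    by = .(ingredient, unit)]
  missing <- du[!med, on = c("ingredient", "unit")]
  if (nrow(missing) > 0L) {
    warning(sprintf(
      "dropped %d drug-unit(s) with no exposed case (no threshold defined)",
      nrow(missing)), call. = FALSE)
  }
  setorder(med, ingredient, unit)
  as.data.frame(med)
}

#' Ternary dose code for an ADS value
#'
#' Codes exposure as 0 (no exposure, ADS = 0), 1 (low dose,
#' `0 < ADS <= median_ads`) or 2 (high dose, `ADS > median_ads`). The three
#' classes partition `[0, Inf)`.
#'
#' @param ads Non-negative ADS value(s).
#' @param threshold Either a single positive cutoff or a one-row threshold
#'   record with a `median_ads` field.
#' @return Integer code(s) in `{0, 1, 2}`.
#' @export
code_dose <- function(ads, threshold) {
  cut <- if (is.list(threshold) || is.data.frame(threshold)) {
    threshold$median_ads
  } else {
    threshold
  }
  stopifnot(length(cut) == 1L, cut > 0)
  if (anyNA(ads) || any(ads < 0)) stop_data("ADS must be non-negative")
  ifelse(ads == 0, 0L, ifelse(ads <= cut, 1L, 2L))
}

#' Dose-code matrix for a matched cohort
#'
#' Codes every pair member's ADS against the case-median thresholds,
#' producing one integer column per retained drug-unit (named
#' `"ingredient|unit"`).
#'
#' @param members Member table (`pair_id`, `role`, `person_id`,
#'   `index_date`).
#' @param claims Pharmacy-claims table.
#' @param thresholds Threshold table from [compute_thresholds()].
#' @inheritParams compute_ads
#' @return A `dose_matrix` data.frame: `pair_id`, `role`, then one code
#'   column per drug-unit.
#' @export
build_dose_matrix <- function(members, claims, thresholds, window_days = 30) {
  ads_tab <- as.data.table(member_ads(claims, members,
                                      window_days = window_days))
  th <- as.data.table(thresholds)
  keys <- drug_unit_key(th$ingredient, th$unit)
  mb <- as.data.table(members)[, .(pair_id, role)]
  setorder(mb, pair_id, role)
  out <- as.data.frame(mb)
  codes <- matrix(0L, nrow(mb), nrow(th), dimnames = list(NULL, keys))
  if (nrow(ads_tab) > 0L) {
    ads_tab[, drug_unit := drug_unit_key(ingredient, unit)]
    ads_tab <- ads_tab[drug_unit %in% keys]
    ridx <- match(paste(ads_tab$pair_id, ads_tab$role),
                  paste(mb$pair_id, mb$role))
    cidx <- match(ads_tab$drug_unit, keys)
    cuts <- th$median_ads[cidx]
    codes[cbind(ridx, cidx)] <- code_dose_vec(ads_tab$ads, cuts)
  }
  cbind(out, as.data.frame(codes), stringsAsFactors = FALSE)
}

# vectorised coding with per-element cutoffs
code_dose_vec <- function(ads, cuts) {
  if (anyNA(ads) || any(ads < 0)) stop_data("ADS must be non-negative")
  ifelse(ads == 0, 0L, ifelse(ads <= cuts, 1L, 2L))
}

#' Derive thresholds and dose matrix from a matched cohort in one step
#'
#' Runs the full exposure-coding stage: member ADS, top-`k` drug-unit
#' selection from exposed cases, case-median thresholds, and the coded dose
#' matrix.
#'
#' @param pairs Matched-pair table from [match_controls()].
#' @param claims Pharmacy-claims table.
#' @param top_k Number of drug-units to retain.
#' @inheritParams compute_ads
#' @return A list: `members`, `drug_units`, `thresholds`, `dose_matrix`.
#' @export
code_exposures <- function(pairs, claims, top_k = 200L, window_days = 30) {
  members <- pair_members(pairs)
  ads_tab <- member_ads(claims, members, window_days = window_days)
  case_ads <- ads_tab[ads_tab$role == "case", , drop = FALSE]
  drug_units <- select_top_drug_units(case_ads, k = top_k)
  thresholds <- compute_thresholds(case_ads, drug_units)
  dm <- build_dose_matrix(members, claims, thresholds,
                          window_days = window_days)
  list(members = members, drug_units = drug_units, thresholds = thresholds,
       dose_matrix = dm)
}
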