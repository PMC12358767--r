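#' Define an adverse-event outcome for cohort construction
#'
#' @param ade_name Outcome label (e.g. `"AKI"`).
#' @param ade_codes Non-empty character vector of diagnosis codes defining
#'   the outcome.
#' @param risk_factor_map Named character vector mapping diagnosis code to
#'   risk-factor label; persons are matched exactly on the resulting binary
#'   risk-factor vector.
#' @param study_window Length-2 Date (or coercible) vector bounding eligible
#'   ED-visit dates.
#' @return An `outcome_definition` list with `risk_factor_labels` (sorted
#'   unique labels of `risk_factor_map`).
#' @export
outcome_definition <- function(ade_name, ade_codes,
                               risk_factor_map = character(0),
                               study_window = c("2008-01-01", "2021-12-31")) {
  ade_codes <- as.character(ade_codes)
  if (length(ade_codes) == 0L) stop_config("ade_codes must be non-empty")
  risk_factor_map <- unlist(risk_factor_map)
  labels <- sort(unique(unname(risk_factor_map)))
  structure(list(ade_name = as.character(ade_name),
                 ade_codes = ade_codes,
                 risk_factor_map = risk_factor_map,
                 risk_factor_labels = labels,
                 study_window = as_iso_date(study_window)),
            class = "outcome_definition")
}

# ED visits = distinct (person, date) with any ed_flag == 1 diagnosis row.
ed_visits_of <- function(diagnoses) {
  dx <- as.data.table(diagnoses)
  unique(dx[ed_flag == 1L, .(person_id, date)])
}

# Qualifying ED visits: inside the study window, >365 days of enrollment
# before the visit, visit inside an enrollment interval, and no other ED
# visit in the 180 days before.
qualifying_ed_visits <- function(persons, diagnoses, outcome) {
  persons <- as.data.table(persons)
  visits <- ed_visits_of(diagnoses)
  visits <- merge(visits, persons[, .(person_id, enroll_start, enroll_end)],
                  by = "person_id")
  visits <- visits[date >= outcome$study_window[1L] &
                     date <= outcome$study_window[2L] &
                     date >= enroll_start & date <= enroll_end &
                     as.numeric(date - enroll_start) > 365]
  if (nrow(visits) == 0L) return(visits[, .(person_id, date)])
  all_ed <- ed_visits_of(diagnoses)
  setnames(all_ed, "date", "other_date")
  joined <- merge(visits[, .(person_id, date)], all_ed, by = "person_id",
                  allow.cartesian = TRUE)
  recent <- joined[other_date < date &
                     as.numeric(date - other_date) <= 180,
                   unique(.SD), .SDcols = c("person_id", "date")]
  out <- visits[, .(person_id, date)]
  out[!recent, on = c("person_id", "date")]
}

ade_flags <- function(diagnoses, outcome) {
  dx <- as.data.table(diagnoses)
  dx[, has_ade := code %in% outcome$ade_codes]
  dx
}

person_age_at <- function(birth_year, dates) {
  as.integer(floor(as.numeric(dates -
    as.Date(paste0(birth_year, "-01-01"))) / 365.25))
}

#' Compute a person's binary risk-factor vector at an index date
#'
#' Element `r` is 1 iff any diagnosis strictly before `index_date` maps to
#' risk-factor label `r` under the outcome's `risk_factor_map`. All available
#' history before the index contributes.
#'
#' @param diagnoses Diagnosis table.
#' @param outcome An [outcome_definition()].
#' @param person_id Person identifier.
#' @param index_date Index (ED-visit) date.
#' @return Integer 0/1 vector named by `risk_factor_labels`.
#' @export
compute_risk_factors <- function(diagnoses, outcome, person_id, index_date) {
  labels <- outcome$risk_factor_labels
  out <- setNames(integer(length(labels)), labels)
  if (length(labels) == 0L) return(out)
  dx <- diagnoses[diagnoses$person_id == person_id &
                    diagnoses$date < as_iso_date(index_date), , drop = FALSE]
  hit <- unique(unname(outcome$risk_factor_map[match(dx$code,
                        names(outcome$risk_factor_map))]))
  out[labels %in% hit] <- 1L
  out
}

# Vectorised risk-factor keys for a (person_id, index_date) table.
risk_factor_keys <- function(diagnoses, outcome, members) {
  labels <- outcome$risk_factor_labels
  members <- as.data.table(members)[, .(person_id, index_date)]
  if (length(labels) == 0L || nrow(members) == 0L) {
    return(list(key = rep(strrep("0", length(labels)), nrow(members)),
                matrix = matrix(0L, nrow(members), length(labels),
                                dimnames = list(NULL, labels))))
  }
  dx <- as.data.table(diagnoses)
  dx <- dx[code %in% names(outcome$risk_factor_map)]
  dx[, label := unname(outcome$risk_factor_map[code])]
  members[, rowid := .I]
  m <- merge(members, dx[, .(person_id, date, label)], by = "person_id",
             allow.cartesian = TRUE)
  m <- m[date < index_date, .(rowid, label)]
  rf <- matrix(0L, nrow(members), length(labels),
               dimnames = list(NULL, labels))
  if (nrow(m) > 0L) {
    rf[cbind(m$rowid, match(m$label, labels))] <- 1L
  }
  list(key = apply(rf, 1L, paste, collapse = ""), matrix = rf)
}

#' Identify outcome cases
#'
#' A case is a person's earliest qualifying ED visit carrying an outcome
#' diagnosis code in position 1 or 2, where qualifying means: inside the
#' study window, more than 365 days of enrollment before the visit, and no
#' other ED visit within the prior 180 days. Persons with any outcome
#' diagnosis before that visit are excluded. At most one case per person.
#'
#' @param persons,diagnoses Claims-style tables (see
#'   [generate_population()] for schemas).
#' @param outcome An [outcome_definition()].
#' @return A data.frame of case records: `person_id`, `index_date`, `age`,
#'   `gender`, `race`, `rf_key` (packed risk-factor string) plus one `rf_*`
#'   column per risk-factor label.
#' @export
identify_cases <- function(persons, diagnoses, outcome) {
  assert_columns(persons, c("person_id", "gender", "race", "birth_year",
                            "enroll_start", "enroll_end"), "persons")
  assert_columns(diagnoses, c("person_id", "date", "code", "position",
                              "ed_flag"), "diagnoses")
  qual <- qualifying_ed_visits(persons, diagnoses, outcome)
  dx <- ade_flags(diagnoses, outcome)
  ade_at_visit <- unique(dx[has_ade & ed_flag == 1L & position <= 2L,
                            .(person_id, date)])
  cand <- merge(qual, ade_at_visit, by = c("person_id", "date"))
  if (nrow(cand) == 0L) return(empty_member_frame(outcome))
  # earliest qualifying outcome visit per person
  setorder(cand, person_id, date)
  cand <- cand[, head(.SD, 1L), by = person_id]
  # exclude prior outcome diagnoses (any position, any encounter)
  prior <- merge(cand, dx[has_ade == TRUE, .(person_id, dx_date = date)],
                 by = "person_id", allow.cartesian = TRUE)
  bad <- unique(prior[dx_date < date, person_id])
  cand <- cand[!person_id %in% bad]
  finalize_members(cand, persons, diagnoses, outcome)
}

empty_member_frame <- function(outcome) {
  base <- data.frame(person_id = character(0),
                     index_date = as.Date(character(0)),
                     age = integer(0), gender = character(0),
                     race = character(0), rf_key = character(0),
                     stringsAsFactors = FALSE)
  for (lb in outcome$risk_factor_labels) base[[paste0("rf_", lb)]] <- integer(0)
  base
}

finalize_members <- function(cand, persons, diagnoses, outcome) {
  if (nrow(cand) == 0L) return(empty_member_frame(outcome))
  persons <- as.data.table(persons)
  out <- merge(cand, persons[, .(person_id, gender, race, birth_year)],
               by = "person_id")
  setnames(out, "date", "index_date")
  out[, age := person_age_at(birth_year, index_date)]
  rf <- risk_factor_keys(diagnoses, outcome,
                         out[, .(person_id, index_date)])
  out[, rf_key := rf$key]
  out <- as.data.frame(out[, .(person_id, index_date, age, gender, race,
                               rf_key)])
  if (ncol(rf$matrix) > 0L) {
    colnames(rf$matrix) <- paste0("rf_", colnames(rf$matrix))
    out <- cbind(out, as.data.frame(rf$matrix))
  }
  out[order(out$index_date, out$person_id), , drop = FALSE]
}

#' Build the eligible control pool
#'
#' Returns every qualifying ED visit (same enrollment, study-window and
#' 180-day washout rules as cases) that carries no outcome code in diagnosis
#' position 1-2 at the visit and whose person has no outcome diagnosis at
#' any time before the visit. Case persons are excluded from the pool.
#'
#' @inheritParams identify_cases
#' @param cases Optional case table from [identify_cases()]; its persons are
#'   removed from the pool.
#' @return A data.frame of candidate records shaped like case records
#'   (one row per qualifying visit; a person may appear with several
#'   candidate index dates, matching uses each person at most once).
#' @export
eligible_controls <- function(persons, diagnoses, outcome, cases = NULL) {
  assert_columns(persons, c("person_id", "gender", "race", "birth_year",
                            "enroll_start", "enroll_end"), "persons")
  qual <- qualifying_ed_visits(persons, diagnoses, outcome)
  dx <- ade_flags(diagnoses, outcome)
  ade_at_visit <- unique(dx[has_ade & ed_flag == 1L & position <= 2L,
                            .(person_id, date)])
  cand <- qual[!ade_at_visit, on = c("person_id", "date")]
  if (!is.null(cases) && nrow(cases) > 0L) {
    cand <- cand[!person_id %in% cases$person_id]
  }
  if (nrow(cand) == 0L) return(empty_member_frame(outcome))
  # no prior outcome diagnosis before the candidate visit
  prior <- merge(cand, dx[has_ade == TRUE, .(person_id, dx_date = date)],
                 by = "person_id", allow.cartesian = TRUE)
  bad <- prior[dx_date < date, .(person_id, date)]
  cand <- cand[!bad, on = c("person_id", "date")]
  finalize_members(cand, persons, diagnoses, outcome)
}

#' Greedy 1:1 control matching
#'
#' Matches each case to one control without replacement on gender (exact),
#' race (exact), risk-factor vector (exact), age within +/-2 years and
#' ED-visit calendar month within +/-2 months. Cases are processed in
#' ascending index-date order (ties by person_id); among eligible candidates
#' the one minimising |age difference|, then |month difference|, then
#' person_id is chosen. Each control person is used at most once. Unmatched
#' cases are returned, never silently dropped.
#'
#' @param cases Case table from [identify_cases()].
#' @param candidates Candidate table from [eligible_controls()].
#' @param age_caliper,month_caliper Matching calipers (years / calendar
#'   months).
#' @return A list with `pairs` (data.frame: pair_id, then case_* and
#'   control_* member columns and `age_delta`, `month_delta`) and
#'   `unmatched` (case rows that found no control).
#' @export
match_controls <- function(cases, candidates, age_caliper = 2L,
                           month_caliper = 2L) {
  if (nrow(cases) == 0L) {
    return(list(pairs = data.frame(), unmatched = cases))
  }
  cases <- cases[order(cases$index_date, cases$person_id), , drop = FALSE]
  cand <- candidates
  cand$month_index <- month_index_of(cand$index_date)
  cand$exact_key <- paste(cand$gender, cand$race, cand$rf_key, sep = "|")
  cases$month_index <- month_index_of(cases$index_date)
  cases$exact_key <- paste(cases$gender, cases$race, cases$rf_key, sep = "|")

  # candidate visits grouped by exact-match key; person used at most once
  cand_by_key <- split(seq_len(nrow(cand)), cand$exact_key)
  used_person <- new.env(parent = emptyenv())
  pair_rows <- vector("list", nrow(cases))
  unmatched <- logical(nrow(cases))

  for (i in seq_len(nrow(cases))) {
    pool <- cand_by_key[[cases$exact_key[i]]]
    if (is.null(pool)) { unmatched[i] <- TRUE; next }
    age_d <- abs(cand$age[pool] - cases$age[i])
    mon_d <- abs(cand$month_index[pool] - cases$month_index[i])
    ok <- age_d <= age_caliper & mon_d <= month_caliper &
      !vapply(cand$person_id[pool], function(p)
        !is.null(used_person[[p]]), logical(1L))
    if (!any(ok)) { unmatched[i] <- TRUE; next }
    sel <- pool[ok]
    ord <- order(age_d[ok], mon_d[ok], cand$person_id[sel])
    j <- sel[ord[1L]]
    used_person[[cand$person_id[j]]] <- TRUE
    pair_rows[[i]] <- data.frame(
      case_row = i, control_row = j,
      age_delta = cases$age[i] - cand$age[j],
      month_delta = cases$month_index[i] - cand$month_index[j])
  }

  idx <- rbindlist(pair_rows[!vapply(pair_rows, is.null, logical(1L))])
  if (nrow(idx) == 0L) {
    return(list(pairs = data.frame(), unmatched = cases[unmatched, ,
                                                        drop = FALSE]))
  }
  member_cols <- setdiff(names(cases), c("month_index", "exact_key"))
  case_part <- cases[idx$case_row, member_cols, drop = FALSE]
  names(case_part) <- paste0("case_", member_cols)
  ctrl_part <- cand[idx$control_row, member_cols, drop = FALSE]
  names(ctrl_part) <- paste0("control_", member_cols)
  pairs <- cbind(pair_id = seq_len(nrow(idx)), case_part, ctrl_part,
                 age_delta = idx$age_delta, month_delta = idx$month_delta)
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = cases[unmatched, , drop = FALSE])
}

#' Long member view of a matched-pair table
#'
#' @param pairs `pairs` element of [match_controls()].
#' @return A data.frame with one row per pair member: `pair_id`, `role`
#'   (`"case"`/`"control"`), `person_id`, `index_date`, `age`.
#' @export
pair_members <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(pair_id = integer(0), role = character(0),
                      person_id = character(0),
                      index_date = as.Date(character(0)), age = integer(0),
                      stringsAsFactors = FALSE))
  }
  mk <- function(role) {
    data.frame(pair_id = pairs$pair_id, role = role,
               person_id = pairs[[paste0(role, "_person_id")]],
               index_date = pairs[[paste0(role, "_index_date")]],
               age = pairs[[paste0(role, "_age")]],
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk("case"), mk("control"))
  out[order(out$pair_id, out$role), , drop = FALSE]
}
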