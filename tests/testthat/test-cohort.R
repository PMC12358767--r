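test_that("case definition applies diagnosis-position and washout rules", {
  outcome <- test_outcome()
  persons <- basic_persons(c("A", "B", "C", "D", "E"))
  dx <- rbind(
    # A: qualifying case, outcome code in position 2
    dx_row("A", "2015-06-01", "ADE01", position = 2L),
    dx_row("A", "2015-06-01", "GEN01", position = 1L),
    # B: outcome code only in position 3 at the ED visit -> not a case
    dx_row("B", "2015-06-01", "ADE01", position = 3L),
    dx_row("B", "2015-06-01", "GEN01", position = 1L),
    # C: prior ED visit 100 days before -> excluded by the 180-day washout
    dx_row("C", "2015-02-21", "GEN01"),
    dx_row("C", "2015-06-01", "ADE01"),
    # D: outcome diagnosis 2 years earlier -> prior-outcome exclusion
    dx_row("D", "2013-06-01", "ADE01", ed_flag = 0L),
    dx_row("D", "2015-06-01", "ADE01"),
    # E: enrollment too short
    dx_row("E", "2015-06-01", "ADE01"))
  persons$enroll_start[persons$person_id == "E"] <- as.Date("2015-01-01")
  cases <- identify_cases(persons, dx, outcome)
  expect_identical(cases$person_id, "A")
  expect_identical(cases$index_date, as.Date("2015-06-01"))
  expect_identical(cases$age, 65L)
})

test_that("position filter keeps a spec'd invalid position out silently", {
  # a position-3 outcome row also never counts as 'prior outcome' removal
  # for the same visit date, but does for later visits
  outcome <- test_outcome()
  persons <- basic_persons("A")
  dx <- rbind(dx_row("A", "2014-01-01", "ADE01", position = 3L, ed_flag = 0L),
              dx_row("A", "2015-06-01", "ADE01", position = 1L))
  cases <- identify_cases(persons, dx, outcome)
  expect_identical(nrow(cases), 0L)  # any prior outcome diagnosis excludes
})

test_that("earliest qualifying outcome visit wins and is idempotent", {
  outcome <- test_outcome()
  persons <- basic_persons("A", enroll_start = as.Date("2009-01-01"))
  dx <- rbind(dx_row("A", "2016-03-01", "ADE01"),
              dx_row("A", "2015-06-01", "ADE01"))
  cases <- identify_cases(persons, dx, outcome)
  expect_identical(cases$index_date, as.Date("2015-06-01"))
  # order independence
  cases2 <- identify_cases(persons, dx[2:1, ], outcome)
  expect_equal(cases, cases2)
})

test_that("control pool applies the same rules minus the outcome code", {
  outcome <- test_outcome()
  persons <- basic_persons(c("A", "B", "C", "D"))
  dx <- rbind(
    dx_row("A", "2015-06-01", "ADE01"),            # case
    dx_row("B", "2015-06-10", "GEN01"),            # eligible control visit
    dx_row("C", "2015-06-10", "GEN01"),            # prior outcome -> removed
    dx_row("C", "2012-01-01", "ADE01", ed_flag = 0L),
    dx_row("D", "2015-06-10", "ADE01", position = 3L))  # pos 3: eligible
  cases <- identify_cases(persons, dx, outcome)
  pool <- eligible_controls(persons, dx, outcome, cases = cases)
  expect_setequal(pool$person_id, c("B", "D"))
  # case persons never enter the pool
  expect_false("A" %in% pool$person_id)
  # generic-visit-only diagnoses: everyone with enough enrollment eligible
  dx2 <- rbind(dx_row("A", "2015-06-01", "GEN01"),
               dx_row("B", "2015-06-10", "GEN01"))
  pool2 <- eligible_controls(persons, dx2, outcome)
  expect_setequal(pool2$person_id, c("A", "B"))
})

test_that("risk factors are binary, label-aligned and temporal", {
  outcome <- test_outcome()
  dx <- rbind(dx_row("A", "2014-01-01", "RF01", ed_flag = 0L),
              dx_row("A", "2016-01-01", "RF02", ed_flag = 0L))
  # no diagnoses at all -> zero vector
  none <- compute_risk_factors(dx[0, ], outcome, "A", "2015-06-01")
  expect_identical(unname(none), c(0L, 0L))
  # one mapped code before index -> exactly that element set;
  # the RF02 code dated after index is not counted
  v <- compute_risk_factors(dx, outcome, "A", "2015-06-01")
  expect_identical(v, c(rf1 = 1L, rf2 = 0L))
})

test_that("matching enforces exact keys and calipers", {
  outcome <- test_outcome()
  mk <- function(id, birth_year, index, gender = "F") {
    p <- basic_persons(id, gender = gender, birth_year = birth_year)
    d <- dx_row(id, index, "GEN01")
    list(p = p, d = d)
  }
  persons <- basic_persons("CASE", birth_year = 1950)
  dx <- rbind(dx_row("CASE", "2015-06-01", "ADE01"),
              dx_row("X1", "2015-07-15", "GEN01"),  # match: same covariates
              dx_row("X2", "2015-06-10", "GEN01"),  # 3 years apart -> out
              dx_row("X3", "2015-11-15", "GEN01"))  # 5 months apart -> out
  persons <- rbind(persons,
                   basic_persons("X1", birth_year = 1951),
                   basic_persons("X2", birth_year = 1953),
                   basic_persons("X3", birth_year = 1950))
  cases <- identify_cases(persons, dx, outcome)
  pool <- eligible_controls(persons, dx, outcome, cases = cases)
  m <- match_controls(cases, pool)
  expect_identical(nrow(m$pairs), 1L)
  expect_identical(m$pairs$control_person_id, "X1")
  expect_lte(abs(m$pairs$age_delta), 2)
  expect_lte(abs(m$pairs$month_delta), 2)
})

test_that("controls are used without replacement", {
  outcome <- test_outcome()
  persons <- rbind(basic_persons(c("C1", "C2"), birth_year = 1950),
                   basic_persons("Z", birth_year = 1950))
  dx <- rbind(dx_row("C1", "2015-06-01", "ADE01"),
              dx_row("C2", "2015-06-05", "ADE01"),
              dx_row("Z", "2015-06-10", "GEN01"))
  cases <- identify_cases(persons, dx, outcome)
  pool <- eligible_controls(persons, dx, outcome, cases = cases)
  m <- match_controls(cases, pool)
  expect_identical(nrow(m$pairs), 1L)
  expect_identical(nrow(m$unmatched), 1L)
  # earlier-index case gets the shared control
  expect_identical(m$pairs$case_person_id, "C1")
})

test_that("pair invariants hold on a randomized synthetic cohort", {
  pop <- generate_population(sim_config(n_persons = 1500, seed = 13))
  outcome <- test_outcome()
  outcome$ade_codes <- "ADE01"
  cases <- identify_cases(pop$persons, pop$diagnoses, outcome)
  pool <- eligible_controls(pop$persons, pop$diagnoses, outcome, cases = cases)
  m <- match_controls(cases, pool)
  expect_gt(nrow(m$pairs), 50)
  expect_true(all(abs(m$pairs$age_delta) <= 2))
  expect_true(all(abs(m$pairs$month_delta) <= 2))
  expect_identical(m$pairs$case_gender, m$pairs$control_gender)
  expect_identical(m$pairs$case_race, m$pairs$control_race)
  expect_identical(m$pairs$case_rf_key, m$pairs$control_rf_key)
  # no control reuse, no case doubling as control
  expect_false(any(duplicated(m$pairs$control_person_id)))
  expect_length(intersect(m$pairs$case_person_id,
                          m$pairs$control_person_id), 0)
  # unmatched cases are reported, not dropped
  expect_identical(nrow(m$pairs) + nrow(m$unmatched), nrow(cases))
})
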