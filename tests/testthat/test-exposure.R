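test_that("ADS follows the pooled dispensed-dose formula and 30-day window", {
  index <- as.Date("2015-06-01")
  claims <- rbind(
    claim_row("A", index - 10, dose_per_unit = 10, quantity = 30,
              days_supply = 30),
    claim_row("A", index - 5, dose_per_unit = 20, quantity = 30,
              days_supply = 15),
    claim_row("A", index - 31, ingredient = "drugB"),  # outside the window
    claim_row("A", index - 30, ingredient = "drugC", dose_per_unit = 5,
              quantity = 60, days_supply = 30),        # boundary: included
    claim_row("A", index, ingredient = "drugD"))       # fill on index: out
  out <- compute_ads(claims, "A", index)
  # two pooled fills: (10*30 + 20*30) / (30 + 15) = 20
  expect_equal(out$ads[out$ingredient == "drugA"], 20)
  expect_equal(out$ads[out$ingredient == "drugC"], 10)
  expect_false("drugB" %in% out$ingredient)
  expect_false("drugD" %in% out$ingredient)
  # single fill identity: 10 mg x 30 / 30 d = 10 mg/day
  one <- compute_ads(claim_row("A", index - 3), "A", index)
  expect_equal(one$ads, 10)
})

test_that("non-positive days of supply is rejected with a log entry", {
  index <- as.Date("2015-06-01")
  claims <- rbind(claim_row("A", index - 5),
                  claim_row("A", index - 6, days_supply = 0))
  expect_warning(out <- compute_ads(claims, "A", index), "non-positive")
  expect_equal(out$ads, 10)  # only the valid fill contributes
})

test_that("top drug-unit selection counts exposed cases with stable ties", {
  tab <- data.frame(
    person_id = c("c1", "c2", "c3", "c1", "c2", "c1", "c1"),
    ingredient = c("b", "b", "b", "a", "a", "a", "c"),
    unit = c("mg", "mg", "mg", "mg", "mg", "%", "mg"),
    ads = c(1, 2, 3, 1, 2, 5, 0))
  top <- select_top_drug_units(tab, k = 10)
  # same ingredient in two units forms two columns; the ads-0 record of
  # drug c marks no exposure, so c has no exposed case and is absent;
  # rank by exposed-case count, ties broken lexicographically on (ing, unit)
  expect_identical(top$ingredient, c("b", "a", "a"))
  expect_identical(top$unit, c("mg", "mg", "%"))
  expect_identical(top$n_exposed_cases, c(3L, 2L, 1L))
  top2 <- select_top_drug_units(tab, k = 1)
  expect_identical(nrow(top2), 1L)
  expect_error(select_top_drug_units(tab, k = 0), "k must be")
})

test_that("thresholds are case-only sample medians over exposed support", {
  du <- data.frame(ingredient = "a", unit = "mg")
  odd <- data.frame(person_id = paste0("c", 1:3), ingredient = "a",
                    unit = "mg", ads = c(10, 20, 30))
  expect_equal(compute_thresholds(odd, du)$median_ads, 20)
  even <- data.frame(person_id = paste0("c", 1:4), ingredient = "a",
                     unit = "mg", ads = c(10, 20, 30, 40))
  expect_equal(compute_thresholds(even, du)$median_ads, 25)
  # zero-ADS cases are not exposed and never enter the median
  zero <- rbind(odd, data.frame(person_id = "c9", ingredient = "a",
                                unit = "mg", ads = 0))
  expect_equal(compute_thresholds(zero, du)$median_ads, 20)
  # drug-unit with no exposed case is dropped with a warning
  du2 <- rbind(du, data.frame(ingredient = "ghost", unit = "mg"))
  expect_warning(th <- compute_thresholds(odd, du2), "no exposed case")
  expect_identical(th$ingredient, "a")
})

test_that("dose coding partitions ADS with the boundary at the median", {
  th <- data.frame(ingredient = "oxycodone", unit = "mg", median_ads = 40)
  expect_identical(code_dose(0, th), 0L)
  expect_identical(code_dose(40, th), 1L)    # at the threshold: low
  expect_identical(code_dose(40.1, th), 2L)  # just above: high
  expect_identical(code_dose(12.5, data.frame(median_ads = 25)), 1L)
  expect_error(code_dose(-1, th), "non-negative")
  # partition + monotonicity property on random values
  set.seed(1)
  ads <- c(0, sort(rlnorm(200, 3, 1)))
  codes <- code_dose(ads, th)
  expect_true(all(codes %in% 0:2))
  expect_true(all(diff(codes) >= 0))
  expect_identical(sum(codes == 0L), 1L)
})

test_that("threshold derivation ignores control exposures entirely", {
  pop <- generate_population(sim_config(n_persons = 1200, n_drugs = 3,
                                        drug_exposure_probs = 0.6, seed = 41))
  outcome <- test_outcome()
  cases <- identify_cases(pop$persons, pop$diagnoses, outcome)
  pool <- eligible_controls(pop$persons, pop$diagnoses, outcome, cases = cases)
  m <- match_controls(cases, pool)
  ex1 <- code_exposures(m$pairs, pop$claims, top_k = 3)
  # double every control's quantity: thresholds must not move
  claims2 <- pop$claims
  ctrl_ids <- ex1$members$person_id[ex1$members$role == "control"]
  sel <- claims2$person_id %in% ctrl_ids
  claims2$quantity[sel] <- claims2$quantity[sel] * 2
  ex2 <- code_exposures(m$pairs, claims2, top_k = 3)
  expect_equal(ex1$thresholds, ex2$thresholds)
  # but control codes do respond
  expect_false(identical(ex1$dose_matrix, ex2$dose_matrix))
})

test_that("exposed cases split evenly between low and high codes", {
  pop <- generate_population(sim_config(n_persons = 1200, n_drugs = 3,
                                        drug_exposure_probs = 0.6, seed = 47))
  outcome <- test_outcome()
  cases <- identify_cases(pop$persons, pop$diagnoses, outcome)
  pool <- eligible_controls(pop$persons, pop$diagnoses, outcome, cases = cases)
  m <- match_controls(cases, pool)
  ex <- code_exposures(m$pairs, pop$claims, top_k = 3)
  case_rows <- ex$dose_matrix[ex$dose_matrix$role == "case", , drop = FALSE]
  for (col in setdiff(names(case_rows), c("pair_id", "role"))) {
    codes <- case_rows[[col]][case_rows[[col]] > 0]
    # medians are computed on all exposed cases, matched or not, so allow
    # a modest imbalance beyond ties in the matched subset
    expect_lt(abs(sum(codes == 1L) - sum(codes == 2L)) / length(codes), 0.15)
  }
})

test_that("the dose matrix codes every member against case thresholds", {
  index <- as.Date("2015-06-01")
  members <- data.frame(pair_id = c(1L, 1L, 2L, 2L),
                        role = c("case", "control", "case", "control"),
                        person_id = c("p1", "p2", "p3", "p4"),
                        index_date = index)
  claims <- rbind(
    claim_row("p1", index - 5, quantity = 30),   # ADS 10
    claim_row("p3", index - 5, quantity = 90),   # ADS 30 -> median 20
    claim_row("p2", index - 5, quantity = 300),  # ADS 100 -> high
    claim_row("p4", index - 40, quantity = 300)) # out of window -> 0
  case_ads <- member_ads(claims, members[members$role == "case", ])
  th <- compute_thresholds(case_ads, select_top_drug_units(case_ads))
  expect_equal(th$median_ads, 20)
  dm <- build_dose_matrix(members, claims, th)
  expect_identical(dm[["drugA|mg"]], c(1L, 2L, 2L, 0L))
  expect_true(all(unlist(dm[, -(1:2)]) %in% 0:2))
})
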