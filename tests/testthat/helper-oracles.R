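# Independent oracles and small fixture builders shared across tests.

# Brute-force maximiser of the 1:1 conditional likelihood on a difference
# matrix z with 1 or 2 columns: deterministic coarse-to-fine grid refinement,
# entirely independent of the package's Newton-Raphson path.
grid_search_clrm <- function(z, lower = -4, upper = 4, levels = 8L,
                             points = 41L) {
  z <- as.matrix(z)
  p <- ncol(z)
  stopifnot(p <= 2L)
  ll <- function(beta) {
    d <- drop(z %*% beta)
    sum(ifelse(d > 0, -log1p(exp(-d)), d - log1p(exp(d))))
  }
  centre <- rep(0, p)
  half <- (upper - lower) / 2
  for (lev in seq_len(levels)) {
    axes <- lapply(seq_len(p), function(j)
      seq(centre[j] - half, centre[j] + half, length.out = points))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1L, ll)
    centre <- grid[which.max(vals), ]
    half <- half * 2 / (points - 1) * 2  # shrink to a few grid cells
  }
  unname(centre)
}

# Matched-pairs closed form for a single binary regressor: beta = log(b/c)
# with b pairs case-exposed-only and c pairs control-exposed-only,
# SE = sqrt(1/b + 1/c).
mcnemar_oracle <- function(b, c) {
  list(beta = log(b / c), se = sqrt(1 / b + 1 / c))
}

# Differenced no-intercept logistic reduction of the 1:1 conditional
# likelihood: glm on z with an all-one response.
glm_diff_oracle <- function(z) {
  df <- as.data.frame(z)
  df$y <- 1
  fit <- stats::glm(y ~ . - 1, data = df, family = stats::binomial())
  unname(stats::coef(fit))
}

# Single-binary-regressor difference matrix: b pairs with z = +1 and c with
# z = -1 (plus optional concordant zero rows).
single_regressor_z <- function(b, c, concordant = 0L) {
  matrix(c(rep(1, b), rep(-1, c), rep(0, concordant)), ncol = 1,
         dimnames = list(NULL, "x1"))
}

# A 7-column triplet design with diverse dose patterns (identifiable with
# high probability for n not too small).
random_triplet_design <- function(n, beta = rep(0, 7), seed = 1L) {
  cfg <- pair_sim_config(n, beta = beta, seed = seed)
  pairs_design(generate_matched_pairs(cfg))
}

# Hand-built triplet_fit for testing contrast machinery in isolation.
manual_fit <- function(beta, cov = diag(7)) {
  structure(list(triplet = c("a", "b", "c"), beta = setNames(beta,
              c("x1", "x2", "x3", "x1x2", "x1x3", "x2x3", "x1x2x3")),
              cov = cov, loglik = -1, converged = TRUE, separated = FALSE,
              n_pairs = 10L, n_discordant = 10L),
            class = "triplet_fit")
}

# Minimal claims-style tables for cohort tests. Each person row: one
# candidate ED visit at `index`, optionally decorated by the caller.
basic_persons <- function(ids, gender = "F", race = "white",
                          birth_year = 1950,
                          enroll_start = as.Date("2010-01-01"),
                          enroll_end = as.Date("2020-12-31")) {
  data.frame(person_id = ids, gender = gender, race = race,
             birth_year = birth_year, enroll_start = enroll_start,
             enroll_end = enroll_end, stringsAsFactors = FALSE)
}

dx_row <- function(person_id, date, code, position = 1L, ed_flag = 1L) {
  data.frame(person_id = person_id, date = as.Date(date), code = code,
             position = position, ed_flag = ed_flag, stringsAsFactors = FALSE)
}

claim_row <- function(person_id, fill_date, ingredient = "drugA",
                      unit = "mg", dose_per_unit = 10, quantity = 30,
                      days_supply = 30) {
  data.frame(person_id = person_id, fill_date = as.Date(fill_date),
             ingredient = ingredient, unit = unit,
             dose_per_unit = dose_per_unit, quantity = quantity,
             days_supply = days_supply, stringsAsFactors = FALSE)
}

test_outcome <- function() {
  outcome_definition("test_ade", ade_codes = "ADE01",
                     risk_factor_map = c(RF01 = "rf1", RF02 = "rf2"))
}
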