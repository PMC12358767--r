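test_that("design_row expands dose codes into the seven-term regressor", {
  expect_equal(unname(design_row(0, 0, 0)), rep(0, 7))
  expect_equal(unname(design_row(2, 2, 2)), c(2, 2, 2, 4, 4, 4, 8))
  expect_equal(unname(design_row(1, 2, 0)), c(1, 2, 0, 2, 0, 0, 0))
  expect_equal(unname(design_row(1, 1, 1)), rep(1, 7))
  expect_error(design_row(3, 0, 0), "0, 1 or 2")
  expect_error(design_row(-1, 0, 0), "0, 1 or 2")
})

test_that("conditional likelihood matches hand-computed pair contributions", {
  # concordant pair: log(1/2) for any beta
  d <- triplet_design(letters[1:3], matrix(c(1, 2, 0), 1), matrix(c(1, 2, 0), 1))
  expect_equal(conditional_loglik(rnorm(7), d), log(0.5))
  # beta = 0: n pairs each contribute log(1/2)
  d10 <- random_triplet_design(10, seed = 4)
  expect_equal(conditional_loglik(rep(0, 7), d10), 10 * log(0.5))
  # one discordant pair, case (1,0,0) vs control (0,0,0), beta1 = log 3:
  # P(case) = 3/4
  d1 <- triplet_design(letters[1:3], matrix(c(1, 0, 0), 1),
                       matrix(c(0, 0, 0), 1))
  expect_equal(conditional_loglik(c(log(3), rep(0, 6)), d1), log(3 / 4))
})

test_that("single-regressor fit equals the discordant-pair closed form", {
  z <- single_regressor_z(6, 3, concordant = 5L)
  fit <- triplerx:::clrm_fit_core(z)
  oracle <- mcnemar_oracle(6, 3)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-7)
  expect_equal(sqrt(fit$cov[1, 1]), oracle$se, tolerance = 1e-6)
  expect_equal(fit$n_discordant, 9L)
  # loglik at the optimum: b*log(b/(b+c)) + c*log(c/(b+c)) + conc*log(1/2)
  expect_equal(fit$loglik,
               6 * log(6 / 9) + 3 * log(3 / 9) + 5 * log(0.5),
               tolerance = 1e-9)
})

test_that("fitter agrees with grid-search and differenced-glm oracles", {
  # 2-column instance, 30 pairs: brute-force grid refinement
  set.seed(11)
  z2 <- cbind(x1 = sample(-2:2, 30, TRUE), x2 = sample(-1:1, 30, TRUE))
  fit2 <- triplerx:::clrm_fit_core(z2)
  expect_lt(max(abs(unname(fit2$beta) - grid_search_clrm(z2))), 1e-3)
  # full 7-term design, 50 pairs: differenced no-intercept logistic
  d <- random_triplet_design(50, beta = c(0.3, -0.2, 0.1, 0, 0.2, 0, 0.1),
                             seed = 8)
  fit7 <- fit_clrm(d)
  expect_lt(max(abs(unname(fit7$beta) - glm_diff_oracle(d$case - d$control))),
            1e-3)
})

test_that("fitter matches the conditional logistic fit from survival", {
  skip_if_not_installed("survival")
  d <- random_triplet_design(300, beta = c(0.4, 0, -0.3, 0.1, 0, 0, 0.05),
                             seed = 12)
  fit <- fit_clrm(d)
  n <- d$n_pairs
  X <- rbind(d$case, d$control)
  df <- data.frame(y = rep(c(1, 0), each = n), stratum = rep(seq_len(n), 2),
                   X)
  cl <- survival::coxph(
    survival::Surv(rep(1, 2 * n), y) ~ x1 + x2 + x3 + x1x2 + x1x3 + x2x3 +
      x1x2x3 + survival::strata(stratum), data = df, method = "exact")
  expect_equal(unname(fit$beta), unname(coef(cl)), tolerance = 1e-5)
  expect_equal(unname(diag(fit$cov)), unname(diag(vcov(cl))),
               tolerance = 1e-4)
})

test_that("degenerate designs are rejected with informative errors", {
  # all pairs concordant
  X <- matrix(rep(c(1, 2, 0), 4), ncol = 3, byrow = TRUE)
  expect_error(fit_clrm(triplet_design(letters[1:3], X, X)), "no information")
  # aliased columns: only drug 1 ever varies
  case_d <- cbind(c(1, 2, 1, 2, 1), 0, 0)
  ctrl_d <- cbind(c(0, 0, 0, 1, 2), 0, 0)
  expect_error(fit_clrm(triplet_design(letters[1:3], case_d, ctrl_d)),
               "aliased")
})

test_that("estimates shrink to zero under the null as pairs grow", {
  d <- random_triplet_design(20000, beta = rep(0, 7), seed = 5)
  fit <- fit_clrm(d)
  expect_true(fit$converged)
  expect_lt(sqrt(sum(fit$beta^2)), 0.1)
})

test_that("concordant pairs never move the estimate", {
  d <- random_triplet_design(80, beta = c(0.3, 0, 0, 0, 0, 0, 0.05), seed = 9)
  fit <- fit_clrm(d)
  # rebuild with one concordant pair appended (first three design columns
  # are the raw dose codes)
  case_doses <- rbind(d$case[, 1:3], c(2, 1, 0))
  ctrl_doses <- rbind(d$control[, 1:3], c(2, 1, 0))
  fit2 <- fit_clrm(triplet_design(d$triplet, case_doses, ctrl_doses))
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-9)
  expect_equal(fit2$n_discordant, fit$n_discordant)
  expect_equal(fit2$loglik, fit$loglik + log(0.5), tolerance = 1e-9)
})

test_that("wald contrasts follow the quadratic form and one-sided tail", {
  fit <- manual_fit(c(0.2, 0.1, 0.3, 0.05, 0, 0.1, 0.05), cov = diag(7) * 0.04)
  cv <- c(0, 0, 1, 0, 2, 2, 4)
  res <- wald_contrast(fit, cv, "221")
  expect_equal(res$estimate, sum(cv * fit$beta))
  expect_equal(res$se, sqrt(sum(cv^2) * 0.04))
  expect_equal(res$z, res$estimate / res$se)
  expect_equal(res$p_one_sided, pnorm(res$z, lower.tail = FALSE))
  # zero contrast is degenerate
  expect_error(wald_contrast(fit, rep(0, 7)), "degenerate")
  # zero estimate gives p exactly 0.5
  fit0 <- manual_fit(rep(0, 7))
  expect_equal(wald_contrast(fit0, c(1, 0, 0, 0, 0, 0, 0))$p_one_sided, 0.5)
})

test_that("log_or_at is the design-row contrast, with exact reference zero", {
  fit <- manual_fit(c(0.2, -0.1, 0.3, 0.05, 0, 0.1, 0.05),
                    cov = 0.03 * (diag(7) + 0.2))
  expect_identical(log_or_at(fit, 0, 0, 0), list(estimate = 0, se = 0))
  # beta7 = log(2)/8 alone puts OR(2,2,2) at exactly 2
  fit7 <- manual_fit(c(rep(0, 6), log(2) / 8))
  expect_equal(exp(log_or_at(fit7, 2, 2, 2)$estimate), 2)
  # additivity: difference of grid log-ORs equals the explicit contrast
  d <- random_triplet_design(400, beta = c(0.3, 0.2, 0.1, 0, 0, 0.1, 0.02),
                             seed = 21)
  f <- fit_clrm(d)
  lhs <- log_or_at(f, 2, 2, 2)$estimate - log_or_at(f, 2, 2, 1)$estimate
  rhs <- wald_contrast(f, c(0, 0, 1, 0, 2, 2, 4), "221")$estimate
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("wald intervals cover planted coefficients at nominal rate", {
  # small-scale recovery check (the full calibration study lives in the
  # acceptance suite)
  beta_star <- c(0.2, 0.1, 0.3, 0.05, 0, 0.1, 0.05)
  n_rep <- 60L
  cover <- matrix(FALSE, n_rep, 7L)
  for (r in seq_len(n_rep)) {
    d <- random_triplet_design(3000, beta = beta_star, seed = 1000 + r)
    f <- fit_clrm(d)
    se <- sqrt(diag(f$cov))
    cover[r, ] <- abs(f$beta - beta_star) <= qnorm(0.975) * se
  }
  expect_gt(min(colMeans(cover)), 0.85)
})
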