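#' Regressor row for a dose configuration
#'
#' Expands the ternary dose codes of a drug triplet into the seven regressors
#' of the dose-interaction conditional logistic model: the three main-effect
#' doses, the three pairwise products and the three-way product,
#' `(x1, x2, x3, x1*x2, x1*x3, x2*x3, x1*x2*x3)`.
#'
#' @param x1,x2,x3 Dose codes in `{0, 1, 2}` (0 = no exposure, 1 = low dose,
#'   2 = high dose).
#' @return A named numeric vector of length 7 (`b1` ... `b7` positions).
#' @examples
#' design_row(2, 2, 2)  # the highest-dose configuration
#' @export
design_row <- function(x1, x2, x3) {
  stopifnot(length(x1) == 1L, length(x2) == 1L, length(x3) == 1L)
  x <- c(x1, x2, x3)
  if (anyNA(x) || !all(x %in% 0:2)) {
    stop_data("dose codes must each be 0, 1 or 2; got (",
              paste(x, collapse = ", "), ")")
  }
  out <- c(x1, x2, x3, x1 * x2, x1 * x3, x2 * x3, x1 * x2 * x3)
  names(out) <- clrm_term_names()
  out
}

clrm_term_names <- function() {
  c("x1", "x2", "x3", "x1x2", "x1x3", "x2x3", "x1x2x3")
}

# Vectorised design expansion: n x 3 dose-code matrix -> n x 7 regressor matrix.
dose_design <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 3L)
  if (nrow(X) > 0L && (anyNA(X) || !all(X %in% 0:2))) {
    stop_data("dose codes must each be 0, 1 or 2")
  }
  Z <- cbind(X[, 1L], X[, 2L], X[, 3L],
             X[, 1L] * X[, 2L], X[, 1L] * X[, 3L], X[, 2L] * X[, 3L],
             X[, 1L] * X[, 2L] * X[, 3L])
  colnames(Z) <- clrm_term_names()
  Z
}

#' Matched-pair design for one drug triplet
#'
#' Bundles the case and control dose configurations of every matched pair into
#' the regressor matrices used by [fit_clrm()]. Regressor rows are expanded
#' from the raw dose codes with [design_row()], so interaction products are
#' consistent by construction.
#'
#' @param triplet Character vector of three drug-unit identifiers.
#' @param case_doses,control_doses Integer matrices (`n_pairs` x 3) of dose
#'   codes in `{0, 1, 2}`, row i giving the case (resp. control) doses of
#'   pair i.
#' @return An object of class `triplet_design`: a list with elements
#'   `triplet`, `case` and `control` (both `n x 7` regressor matrices), and
#'   `n_pairs`.
#' @export
triplet_design <- function(triplet, case_doses, control_doses) {
  case_doses <- as.matrix(case_doses)
  control_doses <- as.matrix(control_doses)
  if (!identical(dim(case_doses), dim(control_doses))) {
    stop_data("case and control dose matrices must have identical dimensions")
  }
  structure(list(triplet = as.character(triplet),
                 case = dose_design(case_doses),
                 control = dose_design(control_doses),
                 n_pairs = nrow(case_doses)),
            class = "triplet_design")
}

#' Conditional log-likelihood of the matched-pair dose model
#'
#' For 1:1 matched pairs the stratum intercept is eliminated by conditioning
#' on one case per pair: with linear predictors `eta_case`, `eta_control`,
#' each pair contributes `log(exp(eta_case) / (exp(eta_case) +
#' exp(eta_control)))`. Concordant pairs (identical regressor rows) contribute
#' `log(1/2)` regardless of `beta`.
#'
#' @param beta Numeric vector of coefficients (length 7 for a full triplet
#'   design).
#' @param design A [triplet_design()].
#' @return The conditional log-likelihood (a finite number `<= 0`).
#' @export
conditional_loglik <- function(beta, design) {
  z <- design$case - design$control
  stopifnot(is.numeric(beta), length(beta) == ncol(z), all(is.finite(beta)))
  d <- drop(z %*% beta)
  # log(plogis(d)) computed stably
  sum(ifelse(d > 0, -log1p(exp(-d)), d - log1p(exp(d))))
}

# Core Newton-Raphson fitter for the 1:1 conditional likelihood, expressed on
# the matrix of within-pair regressor differences z = x_case - x_control
# (any column count). Concave objective; start at 0; step-halving; gradient
# max-norm tolerance. Concordant pairs have z = 0 and contribute -log 2 to
# the log-likelihood but nothing to the score or information.
clrm_fit_core <- function(z, tol = 1e-8, max_iter = 100L, beta_bound = 15) {
  z <- as.matrix(z)
  p <- ncol(z)
  discordant <- rowSums(z != 0) > 0L
  n_disc <- sum(discordant)
  if (n_disc == 0L) {
    stop_data("no information: all pairs are concordant in the regressors")
  }
  zd <- z[discordant, , drop = FALSE]
  qr_z <- qr(zd)
  if (qr_z$rank < p) {
    aliased <- colnames(z)[qr_z$pivot[(qr_z$rank + 1L):p]] %||%
      as.character(qr_z$pivot[(qr_z$rank + 1L):p])
    stop_data("rank-deficient design: aliased column(s) ",
              paste(aliased, collapse = ", "))
  }

  loglik_at <- function(d) sum(ifelse(d > 0, -log1p(exp(-d)), d - log1p(exp(d))))

  beta <- numeric(p)
  eta <- drop(zd %*% beta)
  ll <- loglik_at(eta)
  converged <- FALSE
  separated <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- plogis(eta)
    grad <- drop(crossprod(zd, 1 - mu))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    if (any(abs(beta) > beta_bound)) {
      separated <- TRUE
      break
    }
    w <- mu * (1 - mu)
    info <- crossprod(zd, zd * w)
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) {
      separated <- TRUE
      break
    }
    # step-halving: the conditional likelihood is concave, so a short enough
    # Newton step always improves it
    for (h in 0:30) {
      beta_new <- beta + step / 2^h
      eta_new <- drop(zd %*% beta_new)
      ll_new <- loglik_at(eta_new)
      if (ll_new >= ll - 1e-12) break
    }
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
  }
  if (!converged && any(abs(beta) > beta_bound)) separated <- TRUE

  mu <- plogis(eta)
  info <- crossprod(zd, zd * mu * (1 - mu))
  cov_hat <- if (converged) {
    tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  } else {
    matrix(NA_real_, p, p)
  }
  dimnames(cov_hat) <- list(colnames(z), colnames(z))
  names(beta) <- colnames(z)
  n_conc <- nrow(z) - n_disc
  list(beta = beta, cov = cov_hat,
       loglik = ll + n_conc * log(0.5),
       converged = converged, separated = separated,
       n_pairs = nrow(z), n_discordant = n_disc, iterations = iter)
}

#' Fit the seven-term dose-interaction conditional logistic model
#'
#' Maximises the 1:1 matched-pair conditional likelihood for one drug triplet
#' by Newton-Raphson with step-halving (start at `beta = 0`, gradient max-norm
#' tolerance `1e-8`, at most 100 iterations). The covariance is the inverse of
#' the observed information at the maximum. Quasi-complete separation is
#' flagged when a coefficient escapes `beta_bound` while the score has not
#' vanished; such fits are excluded from downstream testing rather than
#' reported.
#'
#' @param design A [triplet_design()].
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @param beta_bound Absolute coefficient bound used to declare separation.
#' @return An object of class `triplet_fit` with elements `triplet`,
#'   `beta` (length-7, log-OR scale), `cov` (7 x 7), `loglik`, `converged`,
#'   `separated`, `n_pairs`, `n_discordant`.
#' @examples
#' cfg <- pair_sim_config(n_pairs = 400, beta = c(0.5, 0, 0, 0, 0, 0, 0),
#'                        seed = 1)
#' pairs <- generate_matched_pairs(cfg)
#' fit <- fit_clrm(pairs_design(pairs))
#' fit$beta
#' @export
fit_clrm <- function(design, tol = 1e-8, max_iter = 100L, beta_bound = 15) {
  stopifnot(inherits(design, "triplet_design"))
  z <- design$case - design$control
  fit <- clrm_fit_core(z, tol = tol, max_iter = max_iter,
                       beta_bound = beta_bound)
  structure(c(list(triplet = design$triplet), fit), class = "triplet_fit")
}

#' @export
print.triplet_fit <- function(x, ...) {
  cat("Conditional logistic triplet fit:",
      paste(x$triplet, collapse = " + "), "\n")
  cat(sprintf("  pairs: %d (%d discordant); loglik %.3f; %s\n",
              x$n_pairs, x$n_discordant, x$loglik,
              if (x$separated) "SEPARATED" else if (x$converged)
                "converged" else "NOT converged"))
  print(round(rbind(beta = x$beta, se = sqrt(diag(x$cov))), 4))
  invisible(x)
}

#' One-sided Wald test of a linear combination of coefficients
#'
#' Tests `H0: c'beta <= 0` against `c'beta > 0` using the Wald statistic
#' `z = c'beta_hat / sqrt(c' cov c)` and the upper-tail standard-normal
#' probability.
#'
#' @param fit A converged, non-separated [fit_clrm()] result.
#' @param contrast Numeric length-7 contrast coefficient vector.
#' @param label Optional label carried into the result.
#' @return A one-row data.frame (class `contrast_result`): `label`,
#'   `estimate` (log-OR scale), `se`, `z`, `p_one_sided`.
#' @export
wald_contrast <- function(fit, contrast, label = "") {
  stopifnot(inherits(fit, "triplet_fit"))
  if (!isTRUE(fit$converged) || isTRUE(fit$separated)) {
    stop_data("contrast requires a converged, non-separated fit")
  }
  contrast <- as.numeric(contrast)
  stopifnot(length(contrast) == length(fit$beta))
  est <- sum(contrast * fit$beta)
  v <- drop(contrast %*% fit$cov %*% contrast)
  se <- sqrt(max(v, 0))
  if (se == 0) {
    stop_data("degenerate contrast: zero standard error")
  }
  z <- est / se
  out <- data.frame(label = label, estimate = est, se = se, z = z,
                    p_one_sided = pnorm(z, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", class(out))
  out
}

#' Log odds ratio of a dose configuration relative to no exposure
#'
#' Evaluates the model's log-OR at dose configuration `(x1, x2, x3)` relative
#' to the reference `(0, 0, 0)`, with its delta-method standard error.
#'
#' @inheritParams wald_contrast
#' @inheritParams design_row
#' @return A list with `estimate` (log-OR) and `se`.
#' @export
log_or_at <- function(fit, x1, x2, x3) {
  cvec <- design_row(x1, x2, x3)
  if (all(cvec == 0)) {
    return(list(estimate = 0, se = 0))
  }
  res <- wald_contrast(fit, cvec,
                       label = paste0(x1, x2, x3))
  list(estimate = res$estimate, se = res$se)
}

#' Serialise triplet fits to JSON
#'
#' Writes one JSON record per fit: triplet, beta, lower triangle of the
#' covariance, log-likelihood, flags and pair counts.
#'
#' @param fits A list of `triplet_fit` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  recs <- lapply(fits, function(f) {
    list(triplet = f$triplet,
         beta = unname(f$beta),
         cov_lower = unname(f$cov[lower.tri(f$cov, diag = TRUE)]),
         loglik = f$loglik,
         converged = f$converged,
         separated = f$separated,
         n_pairs = f$n_pairs,
         n_discordant = f$n_discordant)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
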