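#' Sampling-weighting strategy
#'
#' Where the sampling weights enter the analysis: `"NEITHER"` ignores
#' them entirely, `"FIRST_ONLY"` uses them only when fitting the two
#' propensity models that form the mediation weights, `"SECOND_ONLY"`
#' multiplies them into the outcome-stage weights only, and `"BOTH"`
#' does both. The two logical flags are the single source of truth for
#' where the sampling weight enters; no other normalization happens
#' between the stages.
#'
#' @param name one of `"NEITHER"`, `"FIRST_ONLY"`, `"SECOND_ONLY"`,
#'   `"BOTH"`.
#' @return object of class `swm_strategy` with flags `use_sw_in_fits`
#'   and `use_sw_in_outcome`.
#' @export
weight_strategy <- function(name = c("NEITHER", "FIRST_ONLY",
                                     "SECOND_ONLY", "BOTH")) {
  name <- match.arg(name)
  flags <- switch(name,
                  NEITHER     = c(FALSE, FALSE),
                  FIRST_ONLY  = c(TRUE,  FALSE),
                  SECOND_ONLY = c(FALSE, TRUE),
                  BOTH        = c(TRUE,  TRUE))
  structure(list(name = name,
                 use_sw_in_fits = flags[1L],
                 use_sw_in_outcome = flags[2L]),
            class = "swm_strategy")
}

#' The four sampling-weighting strategies
#'
#' @return character vector of strategy names accepted by
#'   [weight_strategy()].
#' @export
weight_strategies <- function() c("NEITHER", "FIRST_ONLY", "SECOND_ONLY",
                                  "BOTH")

#' Weighted logistic regression fit
#'
#' Maximizes the weighted Bernoulli log-likelihood by iteratively
#' reweighted least squares (the standard GLM algorithm), with a tight
#' convergence tolerance (relative deviance change below 1e-10, at most
#' 100 iterations). Non-convergence or a boundary fit (separation) is
#' flagged rather than silently accepted so callers can drop the
#' affected replicate.
#'
#' @param y binary response vector.
#' @param X design matrix (including the intercept column).
#' @param obs_weights positive observation weights (default all one).
#' @return object of class `swm_propfit` with `coefficients`, `fitted`
#'   (probabilities), and `converged`.
#' @export
fit_weighted_logistic <- function(y, X, obs_weights = NULL) {
  X <- as.matrix(X)
  if (is.null(obs_weights)) obs_weights <- rep(1, length(y))
  if (any(obs_weights <= 0) || any(!is.finite(obs_weights))) {
    stop("observation weights must be positive and finite", call. = FALSE)
  }
  # weight-independent starting values: the default binomial mustart
  # treats prior weights as trial counts, which destabilizes IRLS (and
  # breaks invariance to weight rescaling) for large weights
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, weights = obs_weights,
    mustart = (y + 0.5) / 2,
    family = stats::quasibinomial("logit"),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100L)))
  if (anyNA(fit$coefficients)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  structure(list(coefficients = fit$coefficients,
                 fitted = fit$fitted.values,
                 converged = isTRUE(fit$converged) && !isTRUE(fit$boundary)),
            class = "swm_propfit")
}

# Clamp fitted propensities away from 0/1 before inversion; returns the
# clamped vector with the number of clamped values as an attribute.
floor_probs <- function(p, floor = 1e-6) {
  n_trunc <- sum(p < floor | p > 1 - floor)
  structure(pmin(pmax(p, floor), 1 - floor), n_truncated = n_trunc)
}

#' Per-unit cross-world weight
#'
#' For a unit in the exposure arm `A = a`, the weight that standardizes
#' its outcome to the counterfactual world in which the mediator takes
#' its value under exposure `a_prime` is the product of an odds weight
#' and an inverse-probability weight:
#' `w_aa' = p(A = a' | M, X) / p(A = a | M, X) * 1 / p(A = a' | X)`.
#' When `a == a_prime` the odds term is identically one and the weight
#' reduces to `1 / p(A = a | X)`.
#'
#' @param p_AX per-unit fitted `p(A = 1 | X)`.
#' @param p_AMX per-unit fitted `p(A = 1 | M, X)`.
#' @param a exposure arm the weight applies to (units with `A = a`).
#' @param a_prime mediator world.
#' @param floor probability floor applied before any inversion.
#' @return numeric weights (positive), with attribute `n_truncated`.
#' @export
cross_world_weight <- function(p_AX, p_AMX, a, a_prime, floor = 1e-6) {
  stopifnot(a %in% 0:1, a_prime %in% 0:1)
  p_AX <- floor_probs(p_AX, floor)
  p_AMX <- floor_probs(p_AMX, floor)
  n_trunc <- attr(p_AX, "n_truncated") + attr(p_AMX, "n_truncated")
  arm_p <- function(p, lev) if (lev == 1) p else 1 - p
  ipw <- 1 / arm_p(p_AX, a_prime)
  w <- if (a == a_prime) {
    ipw
  } else {
    arm_p(p_AMX, a_prime) / arm_p(p_AMX, a) * ipw
  }
  structure(as.numeric(w), n_truncated = n_trunc)
}

#' Build cross-world mediation weights for a sample
#'
#' Fits the two propensity models -- `A ~ C` (for the IPW factor) and
#' `A ~ M + C` (for the odds factor) -- by weighted logistic regression,
#' using the sampling weights as observation weights when the strategy
#' says so, then assembles the four cross-world weights `w11`, `w00`,
#' `w10`, `w01` (each defined on the exposure arm whose outcomes it
#' averages) and their composites with the sampling weight when the
#' strategy uses sampling weights in the outcome stage.
#'
#' Supplying `probs` (a list with per-unit `p_AX` and `p_AMX`) bypasses
#' the model fits; this is how known true propensities are plugged in
#' for validation.
#'
#' @param sample an `swm_sample` (needs `A`, `M`, the six covariates and
#'   `s_weight`).
#' @param strategy an [weight_strategy()].
#' @param probs optional list with numeric vectors `p_AX`, `p_AMX`.
#' @param floor probability floor before inversion.
#' @return object of class `swm_weights`: per-unit raw weights (`NA`
#'   off-arm), composite (outcome-stage) weights, truncation count and
#'   fit convergence flags.
#' @export
build_weights <- function(sample, strategy, probs = NULL, floor = 1e-6) {
  stopifnot(inherits(strategy, "swm_strategy"))
  need <- c("A", "M", covariate_names(), "s_weight")
  miss <- setdiff(need, names(sample))
  if (length(miss)) {
    stop("sample lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  A <- sample$A
  converged <- TRUE
  if (is.null(probs)) {
    C <- as_cov_matrix(sample[, covariate_names()])
    ow <- if (strategy$use_sw_in_fits) sample$s_weight else rep(1, nrow(C))
    fit_AX  <- fit_weighted_logistic(A, cbind(`(Intercept)` = 1, C), ow)
    fit_AMX <- fit_weighted_logistic(A, cbind(`(Intercept)` = 1,
                                              M = sample$M, C), ow)
    converged <- fit_AX$converged && fit_AMX$converged
    probs <- list(p_AX = fit_AX$fitted, p_AMX = fit_AMX$fitted)
  }
  n <- length(A)
  raw <- matrix(NA_real_, n, 4L,
                dimnames = list(NULL, c("w11", "w00", "w10", "w01")))
  n_trunc <- 0L
  for (spec in list(list("w11", 1L, 1L), list("w00", 0L, 0L),
                    list("w10", 1L, 0L), list("w01", 0L, 1L))) {
    arm <- A == spec[[2L]]
    w <- cross_world_weight(probs$p_AX[arm], probs$p_AMX[arm],
                            a = spec[[2L]], a_prime = spec[[3L]],
                            floor = floor)
    n_trunc <- n_trunc + attr(w, "n_truncated")
    raw[arm, spec[[1L]]] <- w
  }
  composite <- if (strategy$use_sw_in_outcome) raw * sample$s_weight else raw
  colnames(composite) <- paste0("composite_", colnames(raw))
  structure(list(strategy = strategy$name, A = A,
                 raw = raw, composite = composite,
                 n_truncated = n_trunc, converged = converged),
            class = "swm_weights")
}

#' True propensities from the generative model
#'
#' Computes, for each row, the exact `p(A = 1 | X)` (`plogis(a)`) and
#' `p(A = 1 | M, X)` (`plogis(b + d M)`) implied by a scenario. Used to
#' validate the weighting estimator with known rather than fitted
#' probabilities.
#'
#' @param rows data frame with the six covariates and `M`.
#' @param spec an [scenario_spec()].
#' @return list with `p_AX` and `p_AMX`.
#' @export
true_propensities <- function(rows, spec) {
  lp <- linear_predictors(as_cov_matrix(rows[, covariate_names()]), spec)
  list(p_AX = prob_A(lp$a),
       p_AMX = prob_A_given_M(lp$b, lp$d, rows$M))
}
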