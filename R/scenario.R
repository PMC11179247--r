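#' Stratum specification
#'
#' A stratum holds one latent-scale parameter per covariate
#' (U1, U2, U3, X1, X2, X3). Latent values are mapped to Bernoulli
#' probabilities through a logistic link, so negative values are legal
#' and give probabilities below 1/2. The link keeps every probability
#' strictly inside (0, 1), ruling out degenerate covariates.
#'
#' @param stratum_id integer in 1:3.
#' @param latent_params numeric vector of length 6, latent (logit-scale)
#'   values for U1, U2, U3, X1, X2, X3.
#' @return an object of class `swm_stratum`.
#' @export
stratum_spec <- function(stratum_id, latent_params) {
  if (!is.numeric(stratum_id) || length(stratum_id) != 1L ||
      !(stratum_id %in% 1:3)) {
    stop("`stratum_id` must be a single integer in 1:3", call. = FALSE)
  }
  if (!is.numeric(latent_params) || length(latent_params) != 6L ||
      any(!is.finite(latent_params))) {
    stop("`latent_params` must be 6 finite numbers", call. = FALSE)
  }
  p <- stats::plogis(latent_params)
  if (any(p <= 0) || any(p >= 1)) {
    stop("covariate probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(stratum_id = as.integer(stratum_id),
         latent_params = as.numeric(latent_params),
         probs = p),
    class = "swm_stratum")
}

#' Default three-stratum covariate distribution
#'
#' Latent (logit-scale) covariate parameters for the three equal-sized
#' population strata. Stratum membership only shifts the covariate
#' distribution; it plays no direct role in the exposure, mediator,
#' outcome or sampling models.
#'
#' @return list of three `swm_stratum` objects.
#' @export
default_strata <- function() {
  list(
    stratum_spec(1L, c(0.3, -0.4, -0.2, 0.25, 0.2, -0.3)),
    stratum_spec(2L, c(0.5,  0.0,  0.1, 0.60, 0.4, -0.1)),
    stratum_spec(3L, c(0.7,  0.4,  0.2, 0.75, 0.8,  0.3)))
}

covariate_names <- function() c("U1", "U2", "U3", "X1", "X2", "X3")

# The eight generative scenarios differ only in (i) whether the model of
# A given M and C carries an M-by-X2 interaction (delta = -0.5, scenarios
# 5-8, which induces an A-by-X2 interaction in the mediator model) and
# (ii) which single interaction, if any, enters the outcome model.
scenario_interactions <- function() {
  list(`1` = "none", `2` = "AM",  `3` = "AX2", `4` = "MX2",
       `5` = "none", `6` = "AM",  `7` = "AX2", `8` = "MX2")
}

#' Default outcome-model coefficients
#'
#' Logit-scale coefficients for P(Y = 1 | A, M, C): an intercept, main
#' effects of exposure and mediator, six covariate main effects, and the
#' coefficient used for whichever single interaction the scenario
#' includes. Magnitudes are moderate (0.2-0.5) with alternating signs so
#' that outcome prevalences stay well away from 0 and 1 in every
#' covariate cell.
#'
#' @return named list of coefficients.
#' @export
default_y_model <- function() {
  list(intercept = -0.3, A = 0.4, M = 0.5,
       C = stats::setNames(c(0.2, -0.25, 0.3, -0.2, 0.35, -0.3),
                           covariate_names()),
       interaction_coef = 0.3)
}

#' Scenario specification
#'
#' Bundles every generative parameter for one population scenario:
#' the exposure-model coefficients (`alpha`, entering
#' `a = 0.68 + alpha' C`), the mediator-conditional exposure-model
#' coefficients (`beta`, entering `b = 0.8 + beta' C`), the mediator
#' interaction coefficient (`delta`, entering `d = -1.52 + delta * X2`),
#' and the outcome model. At construction every one of the 3 x 64
#' stratum-by-covariate cells is checked for feasibility: the implied
#' P(M = 1), P(M = 1 | A = 1) and P(M = 1 | A = 0) must all lie in
#' [0, 1]; an infeasible coefficient set is rejected immediately rather
#' than surfacing as an error during generation.
#'
#' @param scenario_id integer 1-8 selecting the interaction structure.
#' @param alpha,beta numeric length-6 covariate coefficient vectors.
#' @param delta mediator-by-X2 coefficient in the model of A given M and
#'   C; defaults to -0.5 for scenarios 5-8 and 0 otherwise.
#' @param y_model named list as produced by [default_y_model()].
#' @param strata list of three [stratum_spec()] objects used for the
#'   feasibility pre-check.
#' @return an object of class `swm_scenario`.
#' @export
scenario_spec <- function(scenario_id,
                          alpha = c(0.3, -0.2, 0.25, -0.3, 0.35, -0.25),
                          beta  = c(0.45, -0.1, 0.2, -0.2, 0.55, -0.3),
                          delta = NULL,
                          y_model = default_y_model(),
                          strata = default_strata()) {
  if (!(scenario_id %in% 1:8)) {
    stop("`scenario_id` must be an integer in 1:8", call. = FALSE)
  }
  scenario_id <- as.integer(scenario_id)
  if (length(alpha) != 6L || length(beta) != 6L ||
      any(!is.finite(c(alpha, beta)))) {
    stop("`alpha` and `beta` must be finite length-6 vectors", call. = FALSE)
  }
  if (is.null(delta)) delta <- if (scenario_id >= 5L) -0.5 else 0
  if (!is.finite(delta)) stop("`delta` must be finite", call. = FALSE)
  interaction <- scenario_interactions()[[as.character(scenario_id)]]
  stopifnot(is.list(y_model),
            all(c("intercept", "A", "M", "C") %in% names(y_model)),
            length(y_model$C) == 6L)
  if (interaction != "none" && is.null(y_model$interaction_coef)) {
    stop("scenario requires an interaction coefficient in `y_model`",
         call. = FALSE)
  }
  spec <- structure(
    list(scenario_id = scenario_id,
         alpha = as.numeric(alpha), beta = as.numeric(beta),
         delta = delta, interaction = interaction, y_model = y_model,
         strata = strata),
    class = "swm_scenario")
  check_feasibility(spec)
  spec
}

# Enumerate all 3 x 2^6 stratum-covariate cells and fail fast on any
# cell whose implied mediator law leaves [0, 1].
check_feasibility <- function(spec) {
  grid <- covariate_grid()
  for (m in 0:1) {
    lp <- linear_predictors(grid, spec)
    pm <- prob_M_given_A(lp$a, lp$b, lp$d, a_level = m, cells = grid)
    if (any(!is.finite(pm))) {
      stop("infeasible scenario: non-finite mediator probability",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

covariate_grid <- function() {
  g <- as.matrix(expand.grid(rep(list(0:1), 6L), KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- covariate_names()
  g
}

#' Linear predictors of the exposure models
#'
#' Computes, for each covariate row, the three scalars that define the
#' exposure and mediator laws: `a = 0.68 + alpha' C` (logit of the
#' marginal exposure probability given covariates), `b = 0.8 + beta' C`
#' (logit of P(A = 1 | M = 0, C)) and `d = -1.52 + delta * X2` (the
#' mediator effect on that logit, so that
#' logit P(A = 1 | M = 1, C) = b + d).
#'
#' @param C matrix or data frame with the six binary covariate columns,
#'   or a single length-6 row.
#' @param spec an `swm_scenario`.
#' @return list with numeric vectors `a`, `b`, `d`.
#' @export
linear_predictors <- function(C, spec) {
  C <- as_cov_matrix(C)
  list(a = unname(drop(0.68 + C %*% spec$alpha)),
       b = unname(drop(0.80 + C %*% spec$beta)),
       d = unname(-1.52 + spec$delta * C[, "X2"]))
}

as_cov_matrix <- function(C) {
  if (is.null(dim(C))) C <- matrix(C, nrow = 1L,
                                   dimnames = list(NULL, covariate_names()))
  C <- as.matrix(C)
  if (ncol(C) != 6L) stop("covariate input must have 6 columns", call. = FALSE)
  if (is.null(colnames(C))) colnames(C) <- covariate_names()
  storage.mode(C) <- "double"
  C
}

#' Exposure probabilities
#'
#' `prob_A()` is the marginal exposure probability given covariates,
#' `1 / (1 + exp(-a))`. `prob_A_given_M()` is the mediator-conditional
#' exposure probability: `1 / (1 + exp(-b))` when `m = 0` and
#' `1 / (1 + exp(-b - d))` when `m = 1`.
#'
#' @param a,b,d linear predictors as returned by [linear_predictors()].
#' @param m mediator value(s), 0 or 1.
#' @return numeric probabilities.
#' @export
prob_A <- function(a) stats::plogis(a)

#' @rdname prob_A
#' @export
prob_A_given_M <- function(b, d, m) stats::plogis(b + d * m)

#' Mediator probability given exposure
#'
#' The mediator law is determined implicitly by requiring that both the
#' marginal exposure model (logit `a`) and the mediator-conditional
#' exposure model (logit `b + d m`) hold simultaneously. Solving the
#' resulting total-probability constraint gives closed forms:
#' `P(M = 1 | A = 1) = (exp(-b) - exp(-a)) / (exp(-b) - exp(-b - d))`
#' and
#' `P(M = 1 | A = 0) = (exp(-b) - exp(-a)) / (exp(d - a) - exp(-a))`.
#' A parameter combination whose solution leaves [0, 1] (or with
#' `d = 0` while `a != b`, where no solution exists) is reported as a
#' generative-validity error naming the offending covariate pattern.
#'
#' @param a,b,d numeric vectors of linear predictors.
#' @param a_level exposure arm, 0 or 1.
#' @param cells optional covariate matrix used only to name the
#'   offending pattern in error messages.
#' @return numeric vector of probabilities in [0, 1].
#' @export
prob_M_given_A <- function(a, b, d, a_level, cells = NULL) {
  stopifnot(a_level %in% c(0, 1))
  num <- exp(-b) - exp(-a)
  den <- if (a_level == 1) exp(-b) - exp(-b - d) else exp(d - a) - exp(-a)
  bad_d <- abs(den) < 1e-300
  p <- ifelse(bad_d & abs(num) < 1e-300, 0, num / den)
  bad <- bad_d & abs(num) >= 1e-300
  bad <- bad | !is.finite(p) | p < -1e-12 | p > 1 + 1e-12
  if (any(bad)) {
    i <- which(bad)[1L]
    patt <- if (!is.null(cells)) {
      paste(covariate_names(), cells[i, ], sep = "=", collapse = ", ")
    } else sprintf("a=%.4g, b=%.4g, d=%.4g", a[i], b[i], d[i])
    stop("infeasible mediator probability for covariate pattern: ", patt,
         call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

# P(Y = 1 | A = a, M = m, C) on the logit scale per the scenario's
# outcome model: main effects plus at most one interaction.
prob_Y <- function(C, a, m, spec) {
  C <- as_cov_matrix(C)
  ym <- spec$y_model
  eta <- ym$intercept + ym$A * a + ym$M * m + drop(C %*% ym$C)
  eta <- eta + switch(spec$interaction,
                      none = 0,
                      AM   = ym$interaction_coef * a * m,
                      AX2  = ym$interaction_coef * a * C[, "X2"],
                      MX2  = ym$interaction_coef * m * C[, "X2"])
  stats::plogis(eta)
}

#' @export
print.swm_scenario <- function(x, ...) {
  cat(sprintf("Scenario %d: outcome interaction %s, delta = %g\n",
              x$scenario_id, x$interaction, x$delta))
  invisible(x)
}
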