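#' Generate stratified binary covariates
#'
#' Draws the six covariates independently Bernoulli within each of three
#' equal-sized strata (sizes differ by at most one unit when `n` is not
#' divisible by three). Each stratum is generated under its own seed
#' substream derived from `rng_seed`, so per-stratum reproducibility is
#' preserved if strata are ever generated independently.
#'
#' @param n total population size (>= 3).
#' @param strata list of three [stratum_spec()] objects.
#' @param rng_seed integer seed.
#' @return data frame with columns `stratum`, `U1`..`X3`.
#' @export
generate_covariates <- function(n, strata = default_strata(), rng_seed = 1L) {
  if (!is.numeric(n) || n < 3) stop("`n` must be >= 3", call. = FALSE)
  if (length(strata) != 3L ||
      !all(vapply(strata, inherits, logical(1), "swm_stratum"))) {
    stop("`strata` must be a list of three stratum_spec objects",
         call. = FALSE)
  }
  n <- as.integer(n)
  sizes <- rep(n %/% 3L, 3L)
  extra <- n %% 3L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  seeds <- substream_seeds(rng_seed, 3L, tag = 101L)
  parts <- vector("list", 3L)
  for (s in 1:3) {
    set.seed(seeds[s])
    p <- strata[[s]]$probs
    cmat <- matrix(0L, nrow = sizes[s], ncol = 6L,
                   dimnames = list(NULL, covariate_names()))
    for (j in 1:6) {
      cmat[, j] <- as.integer(stats::runif(sizes[s]) < p[j])
    }
    parts[[s]] <- data.frame(stratum = rep(s, sizes[s]), cmat)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Generate a full population under a scenario
#'
#' Builds the pseudo-population carrying, for every unit: the stratum,
#' the six covariates, the exposure `A ~ Bernoulli(plogis(a))`, both
#' potential mediators `M1`, `M0` (Bernoulli with the closed-form
#' mediator probabilities for each exposure arm), all four potential
#' outcomes `Y11 = Y(1, M1)`, `Y00 = Y(0, M0)`, `Y10 = Y(1, M0)`,
#' `Y01 = Y(0, M1)` drawn from the scenario's outcome model, and the
#' observed `M = M_A` and `Y = Y(A, M_A)` (consistency). Potential
#' outcomes are drawn independently across the four (exposure,
#' potential-mediator) pairs; only their means enter any downstream
#' quantity, so the cross-world coupling is immaterial.
#'
#' @param n population size.
#' @param spec an [scenario_spec()] object.
#' @param rng_seed integer seed.
#' @return data frame of class `swm_population`.
#' @export
generate_population <- function(n, spec, rng_seed = 1L) {
  stopifnot(inherits(spec, "swm_scenario"))
  pop <- generate_covariates(n, spec$strata, rng_seed)
  C <- as_cov_matrix(pop[, covariate_names()])
  lp <- linear_predictors(C, spec)
  pm1 <- prob_M_given_A(lp$a, lp$b, lp$d, a_level = 1, cells = C)
  pm0 <- prob_M_given_A(lp$a, lp$b, lp$d, a_level = 0, cells = C)

  set.seed(substream_seeds(rng_seed, 1L, tag = 202L))
  n <- nrow(pop)
  pop$A  <- as.integer(stats::runif(n) < prob_A(lp$a))
  pop$M1 <- as.integer(stats::runif(n) < pm1)
  pop$M0 <- as.integer(stats::runif(n) < pm0)
  pop$Y11 <- as.integer(stats::runif(n) < prob_Y(C, 1, pop$M1, spec))
  pop$Y00 <- as.integer(stats::runif(n) < prob_Y(C, 0, pop$M0, spec))
  pop$Y10 <- as.integer(stats::runif(n) < prob_Y(C, 1, pop$M0, spec))
  pop$Y01 <- as.integer(stats::runif(n) < prob_Y(C, 0, pop$M1, spec))
  pop$M <- ifelse(pop$A == 1L, pop$M1, pop$M0)
  pop$Y <- ifelse(pop$A == 1L, pop$Y11, pop$Y00)
  structure(pop, spec = spec, class = c("swm_population", "data.frame"))
}

#' True effects from a pseudo-population (Monte Carlo)
#'
#' Potential-outcome means are the column means of the four
#' potential-outcome columns; the five effects are the corresponding
#' differences. Both total-effect decompositions
#' (TE = NDE0 + NIE1 = NDE1 + NIE0) hold exactly by construction.
#'
#' @param pop a population from [generate_population()].
#' @return an object of class `swm_effects` with `po_means` and the
#'   five effects.
#' @export
true_effects_mc <- function(pop) {
  need <- c("Y11", "Y00", "Y10", "Y01")
  if (!all(need %in% names(pop))) {
    stop("population lacks potential-outcome columns ",
         paste(setdiff(need, names(pop)), collapse = ", "), call. = FALSE)
  }
  make_effects(po11 = mean(pop$Y11), po00 = mean(pop$Y00),
               po10 = mean(pop$Y10), po01 = mean(pop$Y01))
}

#' True effects by exact enumeration
#'
#' Because every variable is binary, the population expectations have a
#' closed form: summing over the three strata, the 64 covariate
#' patterns and the two mediator values,
#' `E[Y(a, M_a')] = sum_s (1/3) sum_C P(C | s) sum_m
#'   P(M = m | A = a', C) P(Y = 1 | A = a, M = m, C)`.
#' This is deterministic (no RNG) and serves as the reference the
#' Monte-Carlo pseudo-population converges to.
#'
#' @param spec an [scenario_spec()] object (its `strata` are used).
#' @return an object of class `swm_effects`.
#' @export
true_effects_exact <- function(spec) {
  stopifnot(inherits(spec, "swm_scenario"))
  grid <- covariate_grid()
  lp <- linear_predictors(grid, spec)
  pm <- list(`0` = prob_M_given_A(lp$a, lp$b, lp$d, 0, cells = grid),
             `1` = prob_M_given_A(lp$a, lp$b, lp$d, 1, cells = grid))
  po <- matrix(0, 2, 2, dimnames = list(a = 0:1, aprime = 0:1))
  for (s in 1:3) {
    pr <- spec$strata[[s]]$probs
    p_cell <- apply(grid, 1L, function(cc) prod(ifelse(cc == 1, pr, 1 - pr)))
    for (a in 0:1) {
      ey <- cbind(prob_Y(grid, a, 0, spec), prob_Y(grid, a, 1, spec))
      for (ap in 0:1) {
        pm_ap <- pm[[as.character(ap)]]
        po[a + 1L, ap + 1L] <- po[a + 1L, ap + 1L] +
          sum((1 / 3) * p_cell * ((1 - pm_ap) * ey[, 1L] + pm_ap * ey[, 2L]))
      }
    }
  }
  make_effects(po11 = po[2, 2], po00 = po[1, 1],
               po10 = po[2, 1], po01 = po[1, 2])
}

# Assemble potential-outcome means into the five effects. Ordering of
# the subtractions is the single place the decompositions are defined,
# so TE = NDE0 + NIE1 = NDE1 + NIE0 holds exactly in floating point.
make_effects <- function(po11, po00, po10, po01, se = NULL,
                         n_by_arm = NULL) {
  eff <- structure(
    list(po_means = c(`Y(1,M1)` = po11, `Y(0,M0)` = po00,
                      `Y(1,M0)` = po10, `Y(0,M1)` = po01),
         TE   = (po11 - po10) + (po10 - po00),
         NDE0 = po10 - po00,
         NIE1 = po11 - po10,
         NDE1 = (po11 - po10) + (po10 - po00) - (po01 - po00),
         NIE0 = po01 - po00),
    class = "swm_effects")
  eff$se <- se
  eff$n_by_arm <- n_by_arm
  eff
}

effect_names <- function() c("TE", "NDE0", "NIE1", "NDE1", "NIE0")

#' @export
print.swm_effects <- function(x, digits = 4, ...) {
  cat("Potential-outcome means:\n")
  print(round(x$po_means, digits))
  eff <- unlist(x[effect_names()])
  cat("Effects:\n")
  print(round(eff, digits))
  if (!is.null(x$se)) {
    cat("SEs:\n")
    print(round(x$se, digits))
  }
  invisible(x)
}

#' Read or write a population CSV
#'
#' Columns are `stratum`, the six covariates, `A`, `M`, `Y`, and (when
#' present) the potential-outcome columns `Y11`, `Y00`, `Y10`, `Y01`,
#' `M1`, `M0`.
#'
#' @param pop population data frame.
#' @param path file path.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path)
  need <- c("stratum", covariate_names(), "A", "M", "Y")
  miss <- setdiff(need, names(pop))
  if (length(miss)) {
    stop("population file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(pop, class = c("swm_population", "data.frame"))
}
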