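# Independent oracles used across the test files. These deliberately
# re-derive quantities by a different route than the implementation.

# Mediator law by total probability + Bayes: solve P(M = 1) from the
# constraint that the marginal exposure logit a and the conditional
# exposure logits (b, b + d) are simultaneously consistent, then apply
# Bayes' rule for each arm.
oracle_prob_M_given_A <- function(a, b, d, a_level) {
  sig <- stats::plogis
  p <- (sig(a) - sig(b)) / (sig(b + d) - sig(b))
  if (a_level == 1) sig(b + d) * p / sig(a) else (1 - sig(b + d)) * p / (1 - sig(a))
}

# Marginal P(M = 1) under the same solution.
oracle_prob_M <- function(a, b, d) {
  sig <- stats::plogis
  (sig(a) - sig(b)) / (sig(b + d) - sig(b))
}

# Direct numerical maximization of the weighted Bernoulli log-likelihood.
oracle_weighted_logit <- function(y, X, w) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))$par
}

# Small feasible (a, b, d) grid: b >= a and b + d <= a in every cell.
oracle_abd_grid <- function() {
  expand.grid(a = seq(-0.5, 1.5, by = 0.25),
              shift = seq(0.05, 0.6, by = 0.11),
              d = c(-1.52, -2.02, -0.9))
}

# A tiny scenario-like population for fast pipeline tests.
tiny_population <- function(n = 3000, scenario = 1, seed = 5) {
  generate_population(n, scenario_spec(scenario), rng_seed = seed)
}
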