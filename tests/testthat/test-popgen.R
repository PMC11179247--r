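test_that("closed-form mediator law matches the total-probability oracle", {
  grid <- oracle_abd_grid()
  a <- grid$a; b <- grid$a + grid$shift; d <- grid$d
  for (lev in 0:1) {
    expect_lt(max(abs(prob_M_given_A(a, b, d, lev) -
                        oracle_prob_M_given_A(a, b, d, lev))), 1e-12)
  }
  # frozen spot values computed with the oracle
  expect_equal(prob_M_given_A(0.5, 0.8, -1.52, 1), 0.0979386, tolerance = 1e-6)
  expect_equal(prob_M_given_A(0.5, 0.8, -1.52, 0), 0.3317365, tolerance = 1e-6)
})

test_that("exposure and mediator laws are marginally coherent", {
  grid <- oracle_abd_grid()
  a <- grid$a; b <- grid$a + grid$shift; d <- grid$d
  pm1 <- prob_M_given_A(a, b, d, 1) * prob_A(a) +
    prob_M_given_A(a, b, d, 0) * (1 - prob_A(a))
  recon <- prob_A_given_M(b, d, 0) * (1 - pm1) + prob_A_given_M(b, d, 1) * pm1
  expect_lt(max(abs(recon - prob_A(a))), 1e-12)
})

test_that("mediator law handles boundary and infeasible inputs", {
  # a == b: P(M = 1 | A = 1) has a zero numerator
  expect_equal(prob_M_given_A(0.8, 0.8, -1.52, 1), 0)
  # d = 0 with a != b admits no solution
  expect_error(prob_M_given_A(0.5, 0.8, 0, 1), "infeasible")
  # solution outside [0, 1]
  expect_error(prob_M_given_A(2, 0.5, -1.52, 1), "infeasible")
})

test_that("linear predictors follow their defining formulas", {
  spec0 <- scenario_spec(1, alpha = rep(0, 6), beta = rep(0, 6))
  lp <- linear_predictors(c(1, 0, 1, 1, 0, 1), spec0)
  expect_equal(lp$a, 0.68)
  expect_equal(lp$b, 0.8)
  expect_equal(lp$d, -1.52)
  spec5 <- scenario_spec(5, alpha = rep(0, 6), beta = rep(0, 6))
  expect_equal(linear_predictors(c(0, 0, 0, 0, 1, 0), spec5)$d, -2.02)
  expect_equal(linear_predictors(c(0, 0, 0, 0, 0, 1), spec5)$d, -1.52)
})

test_that("exposure probability maps are logistic", {
  expect_equal(prob_A(0), 0.5)
  expect_equal(prob_A_given_M(0.8, -1.52, 1), 1 / (1 + exp(0.72)))
  expect_equal(prob_A_given_M(0.8, 0, 1), prob_A_given_M(0.8, 0, 0))
})

test_that("stratum and scenario constructors reject invalid input", {
  expect_error(stratum_spec(4, rep(0, 6)), "1:3")
  expect_error(stratum_spec(1, rep(0, 5)), "6 finite")
  expect_error(stratum_spec(1, c(Inf, rep(0, 5))), "6 finite")
  expect_error(scenario_spec(9), "1:8")
  # beta far below alpha makes sigma(a) > sigma(b): infeasible cells
  expect_error(scenario_spec(1, alpha = rep(0.3, 6), beta = rep(-0.3, 6)),
               "infeasible")
})

test_that("covariate generation matches stratum probabilities", {
  n <- 30000
  pop <- generate_covariates(n, rng_seed = 3)
  expect_equal(nrow(pop), n)
  expect_equal(as.integer(table(pop$stratum)), rep(n %/% 3L, 3L))
  # empirical mean of U1 in stratum 1 within 4 MC SDs of plogis(0.3)
  p <- plogis(0.3)
  m <- mean(pop$U1[pop$stratum == 1])
  expect_lt(abs(m - p), 4 * sqrt(p * (1 - p) / (n / 3)))
  # uneven n splits within one unit
  sizes <- table(generate_covariates(100, rng_seed = 1)$stratum)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), 100)
})

test_that("population generation is deterministic under a fixed seed", {
  p1 <- generate_population(600, scenario_spec(2), rng_seed = 9)
  p2 <- generate_population(600, scenario_spec(2), rng_seed = 9)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_population(600, scenario_spec(2), rng_seed = 10)
  expect_false(identical(p1$A, p3$A))
})

test_that("generated populations satisfy consistency", {
  pop <- tiny_population(n = 4000, scenario = 6)
  expect_identical(pop$M, ifelse(pop$A == 1, pop$M1, pop$M0))
  expect_identical(pop$Y, ifelse(pop$A == 1, pop$Y11, pop$Y00))
  expect_true(all(unlist(pop[, c("A", "M", "Y")]) %in% 0:1))
})

test_that("null outcome models give null effects exactly", {
  ym <- default_y_model()
  ym$intercept <- 0; ym$A <- 0; ym$M <- 0; ym$C[] <- 0; ym$interaction_coef <- 0
  spec <- scenario_spec(1, y_model = ym)
  eff <- true_effects_exact(spec)
  expect_equal(unname(eff$po_means), rep(0.5, 4))
  expect_equal(eff$TE, 0)
  # outcome depending only on A: indirect effects vanish exactly
  ym$A <- 0.7
  eff2 <- true_effects_exact(scenario_spec(1, y_model = ym))
  expect_equal(eff2$NIE1, 0)
  expect_equal(eff2$NIE0, 0)
  expect_gt(eff2$TE, 0)
})

test_that("decomposition identities hold exactly for both truth routes", {
  for (sc in c(1, 4, 8)) {
    spec <- scenario_spec(sc)
    exact <- true_effects_exact(spec)
    expect_identical(exact$TE, exact$NDE0 + exact$NIE1)
    expect_identical(exact$TE, exact$NDE1 + exact$NIE0)
    mc <- true_effects_mc(generate_population(3000, spec, rng_seed = sc))
    expect_identical(mc$TE, mc$NDE0 + mc$NIE1)
    expect_identical(mc$TE, mc$NDE1 + mc$NIE0)
  }
})

test_that("Monte-Carlo truth converges on the exact enumeration", {
  spec <- scenario_spec(1)
  n <- 120000
  mc <- true_effects_mc(generate_population(n, spec, rng_seed = 13))
  exact <- true_effects_exact(spec)
  for (q in c("TE", "NDE0", "NIE1")) {
    # each po mean has binomial SE ~ sqrt(0.25/n); a difference of two
    se <- sqrt(2 * 0.25 / n)
    expect_lt(abs(mc[[q]] - exact[[q]]), 4 * se)
  }
})

test_that("true_effects_mc demands the potential-outcome columns", {
  pop <- tiny_population(n = 300)
  pop$Y11 <- NULL
  expect_error(true_effects_mc(pop), "potential-outcome columns")
})

test_that("population CSV round-trips", {
  pop <- tiny_population(n = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  pop_df <- as.data.frame(pop)
  attr(pop_df, "spec") <- NULL
  expect_equal(as.data.frame(back), pop_df)
  expect_error(read_population({
    p2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p2, row.names = FALSE)
    p2
  }), "lacks columns")
})
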