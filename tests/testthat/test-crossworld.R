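test_that("strategy flags encode where sampling weights enter", {
  flags <- t(vapply(c("NEITHER", "FIRST_ONLY", "SECOND_ONLY", "BOTH"),
                    function(s) {
                      st <- weight_strategy(s)
                      c(st$use_sw_in_fits, st$use_sw_in_outcome)
                    }, logical(2)))
  expect_equal(unname(flags),
               rbind(c(FALSE, FALSE), c(TRUE, FALSE),
                     c(FALSE, TRUE), c(TRUE, TRUE)))
  expect_error(weight_strategy("BOGUS"))
})

test_that("weighted logistic fit solves the weighted score equations", {
  set.seed(21)
  y <- rbinom(40, 1, 0.4)
  w <- runif(40, 0.5, 2)
  # intercept-only: fitted probability is the weighted mean of y
  f <- fit_weighted_logistic(y, matrix(1, 40, 1), w)
  expect_equal(unique(round(f$fitted, 12)), round(sum(w * y) / sum(w), 12))
  f_un <- fit_weighted_logistic(y, matrix(1, 40, 1))
  expect_equal(f_un$fitted[1], mean(y), tolerance = 1e-9)
})

test_that("weighted logistic fit matches direct likelihood maximization", {
  # 8-row fixture with one binary covariate, unequal weights
  X <- cbind(1, c(0, 0, 0, 0, 1, 1, 1, 1))
  y <- c(0, 0, 1, 1, 0, 1, 1, 1)
  w <- c(1, 2, 1, 1, 2, 1, 3, 1)
  f <- fit_weighted_logistic(y, X, w)
  expect_equal(unname(f$coefficients), oracle_weighted_logit(y, X, w),
               tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("rank-deficient designs are refused", {
  X <- cbind(1, c(0, 1, 0, 1), c(0, 2, 0, 2))
  expect_error(fit_weighted_logistic(c(0, 1, 1, 0), X), "rank deficient")
  expect_error(fit_weighted_logistic(c(0, 1), matrix(1, 2, 1), c(1, -1)),
               "positive")
})

test_that("cross-world weights follow the odds-times-IPW form", {
  p_AX <- c(0.4, 0.6, 0.25)
  p_AMX <- c(0.5, 0.7, 0.2)
  # same-world weights reduce to plain IPW
  expect_equal(cross_world_weight(p_AX, p_AMX, 1, 1), 1 / p_AX,
               ignore_attr = TRUE)
  expect_equal(cross_world_weight(p_AX, p_AMX, 0, 0), 1 / (1 - p_AX),
               ignore_attr = TRUE)
  # odds term is one at p(A=1|M,X) = 1/2
  expect_equal(cross_world_weight(0.4, 0.5, 1, 0), 1 / 0.6,
               ignore_attr = TRUE)
  # hand-computed products for the cross-world arms
  expect_equal(cross_world_weight(p_AX, p_AMX, 1, 0),
               (1 - p_AMX) / p_AMX / (1 - p_AX), ignore_attr = TRUE)
  expect_equal(cross_world_weight(p_AX, p_AMX, 0, 1),
               p_AMX / (1 - p_AMX) / p_AX, ignore_attr = TRUE)
})

test_that("odds weights are reciprocal across the two arms", {
  p_AMX <- seq(0.05, 0.95, by = 0.05)
  odds10 <- cross_world_weight(rep(0.5, 19), p_AMX, 1, 0) /
    cross_world_weight(rep(0.5, 19), p_AMX, 1, 1)
  odds01 <- cross_world_weight(rep(0.5, 19), p_AMX, 0, 1) /
    cross_world_weight(rep(0.5, 19), p_AMX, 0, 0)
  expect_equal(odds10 * odds01, rep(1, 19), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("extreme fitted probabilities are floored and counted", {
  w <- cross_world_weight(c(1e-9, 0.5), c(0.5, 0.5), 1, 1)
  expect_equal(attr(w, "n_truncated"), 1L)
  expect_equal(w[1], 1e6, ignore_attr = TRUE)
})

test_that("first-stage flag changes fits, second-stage flag scales weights", {
  pop <- tiny_population(n = 5000)
  smp <- draw_sample(pop, sampling_design("COV_MED", 1000), rng_seed = 3)
  cw_n <- build_weights(smp, weight_strategy("NEITHER"))
  cw_2 <- build_weights(smp, weight_strategy("SECOND_ONLY"))
  # identical propensity fits: raw weights agree
  expect_equal(cw_n$raw, cw_2$raw)
  # final weights differ exactly by the sampling weight factor
  expect_equal(cw_2$composite[, "composite_w10"],
               cw_n$raw[, "w10"] * smp$s_weight)
  cw_1 <- build_weights(smp, weight_strategy("FIRST_ONLY"))
  expect_false(isTRUE(all.equal(cw_n$raw[, "w11"], cw_1$raw[, "w11"])))
  # first-only composites carry no sampling-weight factor
  expect_equal(cw_1$composite[, "composite_w11"], cw_1$raw[, "w11"])
})

test_that("SRS samples make all strategies numerically identical", {
  pop <- tiny_population(n = 4000)
  smp <- draw_sample(pop, sampling_design("SRS", 900), rng_seed = 12)
  ests <- lapply(c("NEITHER", "FIRST_ONLY", "SECOND_ONLY", "BOTH"),
                 function(s) {
                   estimate_effects(smp, build_weights(smp, weight_strategy(s)))
                 })
  for (k in 2:4) {
    expect_equal(ests[[1]]$po_means, ests[[k]]$po_means, tolerance = 1e-12)
    expect_equal(ests[[1]]$TE, ests[[k]]$TE, tolerance = 1e-12)
  }
})

test_that("composite IPW balances covariates to the population", {
  # with sampling weights in both stages, the w11-weighted covariate
  # distribution of the exposed arm should match the full population
  spec <- scenario_spec(1)
  pop <- generate_population(60000, spec, rng_seed = 31)
  smp <- draw_sample(pop, sampling_design("COV_MED", 6000), rng_seed = 32)
  cw <- build_weights(smp, weight_strategy("BOTH"))
  w <- cw$composite[, "composite_w11"]
  arm <- smp$A == 1
  for (v in c("U1", "U2", "X2")) {
    wm <- sum(w[arm] * smp[[v]][arm]) / sum(w[arm])
    pm <- mean(pop[[v]])
    # weighted-mean SE approximated via effective sample size
    n_eff <- sum(w[arm])^2 / sum(w[arm]^2)
    se <- sqrt(pm * (1 - pm) / n_eff)
    expect_lt(abs(wm - pm), 4 * se)
  }
})

test_that("true propensities reproduce the generative exposure laws", {
  spec <- scenario_spec(5)
  pop <- tiny_population(n = 2000, scenario = 5)
  pr <- true_propensities(pop, spec)
  lp <- linear_predictors(as.matrix(pop[, c("U1", "U2", "U3",
                                            "X1", "X2", "X3")]), spec)
  expect_equal(pr$p_AX, plogis(lp$a))
  expect_equal(pr$p_AMX, plogis(lp$b + lp$d * pop$M))
})
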