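#' Run one simulation condition
#'
#' Draws `R` independent samples from a fixed population under one
#' sampling design and, for each sample, runs the full weighting
#' pipeline under every requested sampling-weighting strategy. The two
#' propensity models are fitted at most twice per replicate (once
#' unweighted, once sampling-weighted) and shared across the strategies
#' that use them, which keeps the strategies exactly comparable within
#' a replicate. A replicate whose propensity fit fails to converge is
#' dropped for all strategies and counted; a condition with more than
#' 5% failed replicates is flagged invalid.
#'
#' @param pop population from [generate_population()] (the population
#'   is fixed; only the sampling is replicated).
#' @param design an [sampling_design()].
#' @param strategies character vector of strategy names.
#' @param R number of replicates (>= 2).
#' @param base_seed integer master seed for this condition.
#' @return data frame of per-replicate, per-strategy estimates with
#'   attributes `n_failed` and `design`.
#' @export
run_condition <- function(pop, design, strategies = weight_strategies(),
                          R = 1000L, base_seed = 1L) {
  stopifnot(inherits(pop, "swm_population"), inherits(design, "swm_design"),
            R >= 2L)
  seeds <- substream_seeds(base_seed, R, tag = 404L)
  rows <- vector("list", R)
  n_failed <- 0L
  for (r in seq_len(R)) {
    smp <- draw_sample(pop, design, rng_seed = seeds[r])
    rep_rows <- estimate_one_sample(smp, strategies, r)
    if (is.null(rep_rows)) n_failed <- n_failed + 1L
    rows[[r]] <- rep_rows
  }
  if (n_failed > 0.05 * R) {
    stop(sprintf("condition invalid: %d of %d replicates failed to fit",
                 n_failed, R), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  attr(out, "design") <- design
  out
}

# Full weighting pipeline for one drawn sample: fit each propensity
# model at most once per fit-weighting variant, share the fits across
# strategies, return NULL if any required fit fails to converge.
estimate_one_sample <- function(smp, strategies, r = 1L) {
  strat_objs <- lapply(strategies, weight_strategy)
  in_fits <- vapply(strat_objs, `[[`, logical(1), "use_sw_in_fits")
  C <- as_cov_matrix(smp[, covariate_names()])
  X_AX <- cbind(`(Intercept)` = 1, C)
  X_AMX <- cbind(`(Intercept)` = 1, M = smp$M, C)
  probs <- list()
  for (variant in c("u", "w")[c(any(!in_fits), any(in_fits))]) {
    ow <- if (variant == "w") smp$s_weight else NULL
    f1 <- fit_weighted_logistic(smp$A, X_AX, ow)
    f2 <- fit_weighted_logistic(smp$A, X_AMX, ow)
    if (!f1$converged || !f2$converged) return(NULL)
    probs[[variant]] <- list(p_AX = f1$fitted, p_AMX = f2$fitted)
  }
  rep_rows <- lapply(strat_objs, function(st) {
    pr <- probs[[if (st$use_sw_in_fits) "w" else "u"]]
    cw <- build_weights(smp, st, probs = pr)
    est <- estimate_effects(smp, cw)
    estimates_row(r, st$name, est, cw$n_truncated)
  })
  do.call(rbind, rep_rows)
}

estimates_row <- function(r, strategy, est, n_truncated) {
  data.frame(replicate = r, strategy = strategy,
             po_Y11 = est$po_means[["Y(1,M1)"]],
             po_Y00 = est$po_means[["Y(0,M0)"]],
             po_Y10 = est$po_means[["Y(1,M0)"]],
             po_Y01 = est$po_means[["Y(0,M1)"]],
             TE = est$TE, NDE0 = est$NDE0, NIE1 = est$NIE1,
             NDE1 = est$NDE1, NIE0 = est$NIE0,
             se_po_Y11 = est$po_se[["Y(1,M1)"]],
             se_po_Y00 = est$po_se[["Y(0,M0)"]],
             se_po_Y10 = est$po_se[["Y(1,M0)"]],
             se_po_Y01 = est$po_se[["Y(0,M1)"]],
             se_TE = est$se[["TE"]], se_NDE0 = est$se[["NDE0"]],
             se_NIE1 = est$se[["NIE1"]], se_NDE1 = est$se[["NDE1"]],
             se_NIE0 = est$se[["NIE0"]],
             n_truncated = n_truncated)
}

summary_quantities <- function() {
  c(effect_names(), "po_Y11", "po_Y00", "po_Y10", "po_Y01")
}

truth_value <- function(truth, q) {
  switch(q,
         po_Y11 = truth$po_means[["Y(1,M1)"]],
         po_Y00 = truth$po_means[["Y(0,M0)"]],
         po_Y10 = truth$po_means[["Y(1,M0)"]],
         po_Y01 = truth$po_means[["Y(0,M1)"]],
         truth[[q]])
}

#' Summarize a condition against the truth
#'
#' Per strategy and per quantity (five effects and four
#' potential-outcome means): the mean estimate, bias (mean minus
#' truth), relative bias (bias over truth; `NA` when the truth is
#' zero), mean squared error about the truth, mean estimated standard
#' error, empirical standard deviation (denominator R - 1) and the
#' mean-SE/SD ratio.
#'
#' @param est per-replicate estimates from [run_condition()].
#' @param truth an `swm_effects` object; by convention the fixed
#'   population's pseudo-population truth ([true_effects_mc()]).
#' @return data frame, one row per strategy-quantity pair.
#' @export
summarize_condition <- function(est, truth) {
  stopifnot(inherits(truth, "swm_effects"))
  out <- list()
  for (st in unique(est$strategy)) {
    sub <- est[est$strategy == st, , drop = FALSE]
    if (nrow(sub) < 2L) stop("need >= 2 retained replicates", call. = FALSE)
    for (q in summary_quantities()) {
      tv <- truth_value(truth, q)
      x <- sub[[q]]
      se_col <- paste0("se_", q)
      bias <- mean(x) - tv
      s <- stats::sd(x)
      out[[length(out) + 1L]] <- data.frame(
        strategy = st, quantity = q, truth = tv,
        mean = mean(x), bias = bias,
        relative_bias = if (tv != 0) bias / tv else NA_real_,
        mse = mean((x - tv)^2),
        mean_se = mean(sub[[se_col]]),
        sd = s,
        se_sd_ratio = if (s > 0) mean(sub[[se_col]]) / s else NA_real_,
        n_replicates = nrow(sub))
    }
  }
  res <- do.call(rbind, out)
  res$n_failed <- attr(est, "n_failed") %||% 0L
  rownames(res) <- NULL
  res
}

#' Run the crossed replication study
#'
#' Crosses population scenarios with sampling methods, running every
#' requested sampling-weighting strategy within each cell. One
#' population of size `N` is generated per scenario and held fixed;
#' each replicate redraws the sample only (set
#' `regenerate_population = TRUE` to regenerate per replicate instead —
#' substantially slower and off by default). Bias is measured against
#' the fixed population's pseudo-population truth.
#'
#' @param scenarios integer vector of scenario ids (subset of 1:8).
#' @param methods character vector of sampling methods.
#' @param strategies character vector of strategy names.
#' @param N population size; `n` sample size; `R` replicates.
#' @param seed master seed; every condition and replicate derives its
#'   own substream from it, so results are reproducible.
#' @param keep_estimates if `TRUE`, attach the per-replicate estimate
#'   tables as attribute `estimates` (a named list).
#' @param regenerate_population regenerate the population for every
#'   replicate rather than fixing it per scenario.
#' @return long data frame of condition summaries (one row per
#'   scenario-method-strategy-quantity).
#' @export
run_grid <- function(scenarios = 1:8, methods = sampling_methods(),
                     strategies = weight_strategies(),
                     N = 90000L, n = 9000L, R = 1000L, seed = 1L,
                     keep_estimates = FALSE,
                     regenerate_population = FALSE) {
  stopifnot(all(scenarios %in% 1:8), all(methods %in% sampling_methods()))
  out <- list()
  kept <- list()
  for (sc in scenarios) {
    spec <- scenario_spec(sc)
    pop_seed <- substream_seeds(seed, 1L, tag = 1000L + sc)
    pop <- generate_population(N, spec, rng_seed = pop_seed)
    truth <- true_effects_mc(pop)
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      design <- sampling_design(m, target_n = n)
      cond_seed <- substream_seeds(seed, 1L, tag = 2000L + 10L * sc + mi)
      est <- if (regenerate_population) {
        run_condition_regen(spec, design, strategies, R, cond_seed, N)
      } else {
        run_condition(pop, design, strategies, R, cond_seed)
      }
      smry <- summarize_condition(est, truth)
      smry <- cbind(scenario = sc, method = m, smry)
      out[[length(out) + 1L]] <- smry
      if (keep_estimates) {
        kept[[paste(sc, m, sep = ":")]] <- est
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (keep_estimates) attr(res, "estimates") <- kept
  res
}

# Per-replicate population regeneration variant. Bias summaries for
# these estimates should use true_effects_exact(spec) as truth, since
# no single fixed population exists.
run_condition_regen <- function(spec, design, strategies, R, base_seed, N) {
  seeds <- substream_seeds(base_seed, R, tag = 505L)
  rows <- vector("list", R)
  n_failed <- 0L
  for (r in seq_len(R)) {
    pop <- generate_population(N, spec, rng_seed = seeds[r])
    smp <- draw_sample(pop, design, rng_seed = seeds[r])
    rep_rows <- estimate_one_sample(smp, strategies, r)
    if (is.null(rep_rows)) n_failed <- n_failed + 1L
    rows[[r]] <- rep_rows
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}
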