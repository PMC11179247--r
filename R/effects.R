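#' Weighted potential-outcome mean (Hajek estimator)
#'
#' Ratio-form weighted mean of the observed outcomes over one exposure
#' arm, `sum(w y) / sum(w)`, with a linearized variance component
#' `sum(w^2 (y - mu)^2) / (sum w)^2` that treats the weights as known.
#'
#' @param Y outcome vector for the whole sample.
#' @param A exposure vector.
#' @param final_weights per-unit outcome-stage weights (`NA` off-arm is
#'   fine; only the `A == a` arm is used).
#' @param a exposure arm to average over.
#' @return list with `estimate` and `var_component`.
#' @export
po_mean <- function(Y, A, final_weights, a) {
  arm <- which(A == a)
  w <- final_weights[arm]
  y <- Y[arm]
  keep <- is.finite(w) & w > 0
  w <- w[keep]; y <- y[keep]
  if (length(w) < 2L) {
    stop("fewer than 2 weighted units in arm A = ", a,
         " (positivity violation)", call. = FALSE)
  }
  sw <- sum(w)
  mu <- sum(w * y) / sw
  list(estimate = mu,
       var_component = sum(w^2 * (y - mu)^2) / sw^2,
       n = length(w))
}

#' Effect estimates from a weighted sample
#'
#' Computes the four Hajek potential-outcome means using the composite
#' (outcome-stage) weights, the five effects by subtraction, and
#' linearized standard errors. Each effect's variance is the sum of the
#' variance components of its two constituent means; this working
#' independence ignores the covariance induced by shared propensity
#' fits (and, for the indirect effects, the shared arm), which is the
#' standard source of standard-error overestimation for these
#' estimators.
#'
#' @param sample an `swm_sample` (needs `Y`, `A`).
#' @param cw an `swm_weights` object from [build_weights()].
#' @return object of class `swm_effects` with `po_means`, effects, `se`
#'   and `n_by_arm`.
#' @export
estimate_effects <- function(sample, cw) {
  stopifnot(inherits(cw, "swm_weights"))
  W <- cw$composite
  p11 <- po_mean(sample$Y, sample$A, W[, "composite_w11"], 1)
  p00 <- po_mean(sample$Y, sample$A, W[, "composite_w00"], 0)
  p10 <- po_mean(sample$Y, sample$A, W[, "composite_w10"], 1)
  p01 <- po_mean(sample$Y, sample$A, W[, "composite_w01"], 0)
  v <- c(`Y(1,M1)` = p11$var_component, `Y(0,M0)` = p00$var_component,
         `Y(1,M0)` = p10$var_component, `Y(0,M1)` = p01$var_component)
  se <- c(TE   = sqrt(v[["Y(1,M1)"]] + v[["Y(0,M0)"]]),
          NDE0 = sqrt(v[["Y(1,M0)"]] + v[["Y(0,M0)"]]),
          NIE1 = sqrt(v[["Y(1,M1)"]] + v[["Y(1,M0)"]]),
          NDE1 = sqrt(v[["Y(1,M1)"]] + v[["Y(0,M1)"]]),
          NIE0 = sqrt(v[["Y(0,M1)"]] + v[["Y(0,M0)"]]))
  out <- make_effects(po11 = p11$estimate, po00 = p00$estimate,
                      po10 = p10$estimate, po01 = p01$estimate,
                      se = se,
                      n_by_arm = c(`A=1` = p11$n, `A=0` = p00$n))
  out$po_se <- sqrt(v)
  out
}

#' Mean-SE to empirical-SD ratio across replicates
#'
#' For each effect, the ratio of the mean estimated standard error to
#' the standard deviation (denominator R - 1) of the estimates across
#' replicates. Values above one indicate overestimated uncertainty.
#'
#' @param est data frame of per-replicate estimates with columns
#'   `TE`, ..., and `se_TE`, ... (as produced by [run_condition()]).
#' @return named numeric vector of ratios (NA where the SD is zero).
#' @export
sandwich_se_diagnostic <- function(est) {
  if (nrow(est) < 2L) stop("need at least 2 replicates", call. = FALSE)
  out <- sapply(effect_names(), function(e) {
    s <- stats::sd(est[[e]])
    if (s == 0) return(NA_real_)
    mean(est[[paste0("se_", e)]]) / s
  })
  stats::setNames(out, effect_names())
}
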