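#' Sampling design
#'
#' Four unequal-probability designs for selecting `target_n` units from
#' a population: selection depends on the design covariates only
#' (`"COV"`, S ~ U), on covariates and the mediator (`"COV_MED"`,
#' S ~ U + M), on covariates and the exposure (`"COV_TRT"`, S ~ U + A),
#' or on nothing (`"SRS"`, simple random sampling). The selection
#' propensity is `plogis(gamma' [1, U1, U2, U3 (, M | A)])`; default
#' coefficients make the most and least selectable units differ by
#' roughly a factor of five around the overall sampling fraction.
#'
#' @param method one of `"COV"`, `"COV_MED"`, `"COV_TRT"`, `"SRS"`.
#' @param target_n sample size to draw.
#' @param gamma named coefficient vector for the selection logit with
#'   elements `intercept`, `U1`, `U2`, `U3` and, for the mediator- or
#'   exposure-dependent designs, `M` or `A`. Ignored for SRS.
#' @return an object of class `swm_design`.
#' @export
sampling_design <- function(method = c("COV", "COV_MED", "COV_TRT", "SRS"),
                            target_n = 9000L, gamma = NULL) {
  method <- match.arg(method)
  if (!is.numeric(target_n) || target_n < 1) {
    stop("`target_n` must be a positive integer", call. = FALSE)
  }
  if (method == "SRS") {
    gamma <- c(intercept = 0)
  } else if (is.null(gamma)) {
    gamma <- c(intercept = -2.2, U1 = 0.5, U2 = -0.4, U3 = 0.3)
    extra <- switch(method, COV_MED = c(M = 0.4), COV_TRT = c(A = 0.4), NULL)
    gamma <- c(gamma, extra)
  } else {
    need <- c("intercept", "U1", "U2", "U3",
              switch(method, COV_MED = "M", COV_TRT = "A", NULL))
    miss <- setdiff(need, names(gamma))
    if (length(miss)) {
      stop("`gamma` lacks coefficients: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    gamma <- gamma[need]
  }
  structure(list(method = method, gamma = gamma,
                 target_n = as.integer(target_n)),
            class = "swm_design")
}

#' The four sampling methods
#'
#' Design labels in the order used for reported simulation conditions:
#' covariates only, covariates + mediator, covariates + exposure,
#' simple random sampling.
#'
#' @return character vector of method names.
#' @export
sampling_methods <- function() c("COV", "COV_MED", "COV_TRT", "SRS")

#' Selection propensity
#'
#' Per-unit probability scale of being selected, before normalization to
#' the target sample size. For SRS this is constant.
#'
#' @param rows population rows (needs `U1`-`U3` and, depending on the
#'   method, `M` or `A`).
#' @param design an [sampling_design()].
#' @return numeric vector, strictly in (0, 1).
#' @export
selection_propensity <- function(rows, design) {
  stopifnot(inherits(design, "swm_design"))
  if (design$method == "SRS") return(rep(0.5, nrow(rows)))
  g <- design$gamma
  need <- setdiff(names(g), "intercept")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("rows lack columns required by the design: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  eta <- g[["intercept"]]
  for (v in need) eta <- eta + g[[v]] * rows[[v]]
  stats::plogis(eta)
}

#' Draw a fixed-size unequal-probability sample
#'
#' Inclusion probabilities are proportional to the selection propensity,
#' normalized so they sum to `target_n`; any probability pushed above 1
#' is capped at 1 and the remainder renormalized (at most 100 passes).
#' Units are then drawn by systematic probability-proportional-to-size
#' sampling on a randomly permuted frame, which yields exactly
#' `target_n` distinct units with the stated inclusion probabilities.
#' Sampling weights are `1 / pi`, normalized to mean one over the
#' sample; every downstream estimator is of Hajek (ratio) form, so this
#' rescaling leaves all estimates unchanged and keeps the weights on an
#' interpretable scale. Under SRS all weights are exactly 1.
#'
#' @param pop population data frame.
#' @param design an [sampling_design()].
#' @param rng_seed integer seed.
#' @return data frame of class `swm_sample`: the sampled rows plus
#'   `pi` (inclusion probability) and `s_weight`.
#' @export
draw_sample <- function(pop, design, rng_seed = 1L) {
  stopifnot(inherits(design, "swm_design"))
  N <- nrow(pop)
  n <- design$target_n
  if (n > N) stop("`target_n` exceeds the population size", call. = FALSE)
  s <- selection_propensity(pop, design)
  # inclusion probabilities proportional to propensity, summing to n;
  # cap at 1 and renormalize the uncapped remainder until stable
  pi <- n * s / sum(s)
  capped <- rep(FALSE, N)
  for (iter in seq_len(100L)) {
    if (max(pi[!capped]) <= 1 + 1e-12) break
    capped <- capped | pi >= 1
    pi[capped] <- 1
    deficit <- n - sum(capped)
    if (deficit < 0 || (iter == 100L && max(pi[!capped]) > 1 + 1e-12)) {
      stop("selection propensities too extreme: capping failed to converge",
           call. = FALSE)
    }
    if (deficit == 0) break
    pi[!capped] <- deficit * s[!capped] / sum(s[!capped])
  }
  pi <- pmin(pi, 1)

  set.seed(substream_seeds(rng_seed, 1L, tag = 303L))
  perm <- sample.int(N)
  cum <- cumsum(pi[perm])
  targets <- stats::runif(1L) + seq_len(n) - 1
  idx <- perm[pmin(findInterval(targets, cum) + 1L, N)]

  out <- as.data.frame(pop)[idx, , drop = FALSE]
  out$pi <- pi[idx]
  out$s_weight <- normalize_weights(1 / pi[idx])
  rownames(out) <- NULL
  structure(out, design = design, class = c("swm_sample", "data.frame"))
}

#' Normalize weights to mean one
#'
#' Rescales a positive weight vector to mean 1. All estimators in the
#' package are ratio (Hajek) forms, invariant to this rescaling.
#'
#' @param w positive numeric weights.
#' @return rescaled weights.
#' @export
normalize_weights <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  w / mean(w)
}
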