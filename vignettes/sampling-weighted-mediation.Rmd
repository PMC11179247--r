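---
title: "Cross-world weighting for causal mediation under unequal-probability sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-world weighting for causal mediation under unequal-probability sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Causal mediation analysis decomposes the total effect (TE) of a binary
exposure $A$ on a binary outcome $Y$ into a natural direct effect (NDE)
and a natural indirect effect (NIE) transmitted through a binary
mediator $M$. With potential mediators $M_a$ and potential outcomes
$Y_{(a, M_{a'})}$, the estimands are

$$
\mathrm{TE} = E[Y_{(1,M_1)} - Y_{(0,M_0)}], \qquad
\mathrm{NDE}_0 = E[Y_{(1,M_0)} - Y_{(0,M_0)}], \qquad
\mathrm{NIE}_1 = E[Y_{(1,M_1)} - Y_{(1,M_0)}],
$$

with the alternative decomposition $\mathrm{NDE}_1, \mathrm{NIE}_0$
defined symmetrically, so that
$\mathrm{TE} = \mathrm{NDE}_0 + \mathrm{NIE}_1 = \mathrm{NDE}_1 + \mathrm{NIE}_0$.
Weighting estimators target the four potential-outcome means with
*cross-world weights*

$$
w_{aa'} =
\underbrace{\frac{p(A = a' \mid M, X)}{p(A = a \mid M, X)}}_{\text{odds weight}}
\;\times\;
\underbrace{\frac{1}{p(A = a' \mid X)}}_{\text{IPW}},
$$

applied to the observed outcomes of the $A = a$ arm; when $a = a'$ the
odds term is one and $w_{aa}$ is plain inverse-probability weighting.
Each mean is estimated by the Hájek (ratio) form
$\sum_{i:A_i=a} Y_i w_{aa',i} / \sum_{i:A_i=a} w_{aa',i}$.

When the analysis sample is drawn with unequal selection probabilities,
a unit carries a sampling weight $s_i \propto 1/\pi_i$. The package
implements the four places that weight can (fail to) enter:

| strategy | propensity fits | outcome stage |
|---|---|---|
| `NEITHER` | unweighted | cross-world weight only |
| `FIRST_ONLY` | sampling-weighted | cross-world weight only |
| `SECOND_ONLY` | unweighted | $s_i \times$ cross-world weight |
| `BOTH` | sampling-weighted | $s_i \times$ cross-world weight |

The theory behind composite weights says `BOTH` is sufficient for
consistent population-level estimation: the propensity models must be
fitted with the sampling weights *and* the outcome stage must weight by
the product of the sampling and cross-world weights. The simulation
harness in this package exists to measure what the other three
strategies cost.

## The synthetic populations

`generate_population()` builds populations with three equal-sized
strata. Within a stratum the six binary covariates
$C = (U_1,U_2,U_3,X_1,X_2,X_3)$ are independent Bernoulli draws whose
probabilities come from latent logit-scale parameters
(`default_strata()`); a logistic link is used because several latent
values are negative and therefore cannot be probabilities themselves.
The $U$'s drive sample selection, the $X$'s do not; all six affect
$A$, $M$ and $Y$.

The exposure and mediator laws are specified jointly through three
linear predictors,

$$
a = 0.68 + \alpha' C, \qquad
b = 0.8 + \beta' C, \qquad
d = -1.52 + \delta X_2,
$$

with $P(A=1\mid C) = \mathrm{logit}^{-1}(a)$ and
$P(A=1 \mid M=m, C) = \mathrm{logit}^{-1}(b + dm)$. Requiring both to
hold pins down the mediator law in closed form:

$$
P(M=1 \mid A=1) = \frac{e^{-b} - e^{-a}}{e^{-b} - e^{-b-d}}, \qquad
P(M=1 \mid A=0) = \frac{e^{-b} - e^{-a}}{e^{d-a} - e^{-a}},
$$

which `prob_M_given_A()` evaluates and validates (the test suite checks
it against an independently derived total-probability/Bayes solution to
$10^{-12}$). A combination for which the solution leaves $[0,1]$ — or
$d = 0$ with $a \neq b$, where no solution exists — is a generative
validity error; `scenario_spec()` enumerates all $3 \times 64$
stratum-covariate cells at construction and fails fast rather than
during generation.

Eight scenarios vary the interaction structure: $\delta = -0.5$
(scenarios 5–8) puts an $M \times X_2$ term in the exposure-given-
mediator model, which induces an $A \times X_2$ interaction in the
mediator law; the outcome logit model carries at most one interaction
($A{\times}M$ for scenarios 2 and 6, $A{\times}X_2$ for 3 and 7,
$M{\times}X_2$ for 4 and 8).

The covariate coefficients $\alpha$, $\beta$ and the outcome model are
tunable; the shipped defaults use moderate effects of alternating sign
(magnitudes 0.2–0.55). $\beta$ was chosen so that $0 < b - a < 1.52$
in every covariate cell, which guarantees feasibility of the mediator
law throughout; the outcome model (intercept $-0.3$, exposure 0.4,
mediator 0.5, interaction 0.3) keeps outcome prevalences near 0.5 and
produces a total effect around 0.06 with indirect effects around
$-0.03$ — small effects of the size routinely reported in
population-survey mediation studies.

### True effects

Two independent routes compute the truth. `true_effects_mc()` takes the
pseudo-population means of the four potential-outcome columns, exactly
as a fixed simulated population defines its own truth.
`true_effects_exact()` exploits that every variable is binary and
enumerates $E[Y(a, M_{a'})] = \sum_s \tfrac13 \sum_{C} P(C\mid s)
\sum_m P(M{=}m \mid A{=}a', C)\, P(Y{=}1 \mid A{=}a, m, C)$
deterministically. The suite verifies the two agree at $n = 10^6$
within Monte-Carlo error.

A consequence worth stating: a single fixed population of $N = 90{,}000$
differs from the exact enumeration — and from what any census-level
estimator could recover from its *observed* data — by realization noise
of order $1/\sqrt{N} \approx 0.003$. Bias measured against the fixed
population's pseudo-population truth therefore contains a shared offset
of that size for every strategy; comparisons between two nearly
unbiased strategies can be dominated by it. The harness follows the
fixed-population convention (one population per scenario, resampled
`R` times) because that is how replication studies of this design are
run; `regenerate_population = TRUE` averages the offset away at
proportionally higher cost.

## Sampling

`sampling_design()` implements four selection mechanisms: `COV`
($S \sim U$), `COV_MED` ($S \sim U + M$), `COV_TRT` ($S \sim U + A$)
and `SRS`. Selection propensities are logistic; the default
coefficients (intercept $-2.2$; $U$ effects $0.5, -0.4, 0.3$; $M$ or
$A$ effect 0.4) give a roughly five-fold spread of inclusion
probabilities around the 10% sampling fraction — informative but not
extreme. Fixed-size samples are drawn by systematic
probability-proportional-to-size sampling on a randomly permuted frame:
inclusion probabilities are the normalized propensities summing to the
target size, capped at one and renormalized where needed (at most 100
passes). A 2,000-replicate oracle test confirms the empirical inclusion
frequencies match the stated probabilities. Sampling weights $1/\pi_i$
are normalized to mean one; every downstream estimator is
scale-invariant in the weights, so this is cosmetic (and makes SRS
weights exactly one, which in turn makes the four strategies exactly
coincide there).

## Estimation details and numerical choices

* **Propensity fits.** `A ~ C` (IPW factor) and `A ~ M + C` (odds
  factor) are fitted by weighted logistic regression via iteratively
  reweighted least squares (`stats::glm.fit`), relative-deviance
  tolerance $10^{-10}$, at most 100 iterations. Starting values are
  the weight-independent $(y + 0.5)/2$: the default GLM initialization
  treats prior weights as binomial trial counts, which destabilizes
  the first iteration for large sampling weights and would break the
  invariance of the fit to weight rescaling. Non-convergent or
  boundary (separated) fits abort the replicate; the harness drops that
  replicate for all four strategies to keep them comparable and flags
  a condition with more than 5% failures.
* **The two factors are estimated separately** and multiplied, exactly
  as the cross-world weight factorization suggests; there is no hidden
  renormalization between stages.
* **Probability floor.** Fitted propensities are clamped to
  $[10^{-6}, 1 - 10^{-6}]$ before inversion; clamp counts are recorded
  on the weight object. No other trimming or stabilization is applied,
  so the estimator is the plain one under study. (Under the default
  generative models the floor never binds in practice.)
* **Outcome stage.** Each potential-outcome mean is the Hájek ratio
  over its exposure arm. An intercept-only weighted logistic fit gives
  numerically the same number (the suite asserts agreement to
  $10^{-8}$), so "outcome regression" and "weighted group mean"
  coincide here by construction.
* **Standard errors.** The variance of each mean is the linearization
  $\sum w_i^2 (y_i - \hat\mu)^2 / (\sum w_i)^2$ with weights treated as
  known; an effect's variance is the sum of its two constituent
  variances. This deliberately ignores both the covariance induced by
  estimating the propensities and the covariance of two means built on
  the same arm (relevant for the NIEs). That is the standard sandwich
  practice for these estimators and it *overestimates* uncertainty;
  quantifying the overestimation (mean SE versus the standard
  deviation of estimates across replicates,
  `sandwich_se_diagnostic()`) is one of the harness's outputs. No
  finite-population correction is applied at a 10% sampling fraction.
* **Cross-world coupling.** Potential outcomes are drawn independently
  across the four $(a, m)$ pairs. Only their means are ever consumed,
  so the unidentified cross-world dependence cannot affect any output.
* **Seeds.** Every source of randomness derives from one master seed
  through Lehmer-scrambled 31-bit substreams (per stratum, per
  condition, per replicate), so runs are bitwise reproducible and
  stable under parallel reorganization.

## The replication harness

`run_condition()` fixes a population, draws `R` samples under one
design, and runs all requested strategies on each sample, sharing the
(at most two) propensity-fit variants across strategies within a
replicate. `summarize_condition()` reports, per strategy and per
quantity (five effects, four potential-outcome means): mean, bias,
relative bias (missing when the truth is zero), MSE, mean estimated SE,
empirical SD (denominator $R - 1$; the identity
$\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{SD}^2 (R{-}1)/R$ is asserted
in the tests), and the mean-SE/SD ratio. `run_grid()` crosses
scenarios with sampling methods.

### Problem sizes used in the shipped validation

The package's validation runs use populations of $N = 90{,}000$,
samples of $n = 9{,}000$ and $R = 500$ replicates per condition — the
full population and sample sizes of the study design, with the
replicate count halved against the 1,000-replicate reference; the
mean-SE/SD band is asserted with a $\pm 0.03$ allowance to absorb the
extra Monte-Carlo noise of the smaller `R` (the SD of a ratio estimate
at $R$ replicates is roughly $1/\sqrt{2(R-1)} \approx 3\%$). Unit
tests use much smaller populations (hundreds to tens of thousands)
because the properties they check are size-free.

## What the generator does and does not emulate

The generator reproduces the *structure* of the study design: binary
everything, stratified covariates, logit exposure laws with the
mediator law derived from them, eight interaction patterns, informative
selection through $U$ plus optionally $M$ or $A$. The specific
covariate, outcome and selection coefficients are this package's
documented defaults, because the originating study design does not fix
them; magnitudes of bias, of strategy separation, and of SE
overestimation therefore need not match any particular published
figure cell-for-cell. Passing tests show the estimator and harness are
correct and that the qualitative strategy conclusions hold under
moderately informative selection; they do not show how large the
one-stage biases would be under stronger selection, nor anything about
non-probability selection (attrition, nonresponse) or continuous
variables, which are out of scope.

## Known limitations

* Strategy comparisons against a fixed population carry the
  $O(1/\sqrt N)$ benchmark offset discussed above; with near-consistent
  strategies the |bias| ordering can be decided by that offset rather
  than by the strategies themselves.
* SEs are deliberately the naive linearization (no correction for
  estimated propensities); coverage is not a target.
* One mediator, binary variables only, single-stage sampling designs;
  boosted propensity models are not implemented.
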