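---
title: "Modelling moral costs in bribe-taking decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling moral costs in bribe-taking decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralcost)
```

## The task and its payoff structure

`moralcost` models how a power-holder decides whether to accept an offer
from a proposer who may be committing fraud. The task crosses two
within-subject factors — scenario (Solo vs. Dyad, i.e. whether an
innocent third party is present) and the proposer's conduct (Control vs.
Bribe, i.e. whether the reported payoff option is the honestly indicated
one or the fraudulent alternative) — into four conditions (SC, SB, DC,
DB). A stimulus is a pair (reported payoff, offer proportion): the
proposer's two options always sum to CNY 100, the reported payoff ranges
from 56 to 96 in steps of 8 (so the reported option is always the better
one for the proposer), and the offer to the power-holder is the nearest
integer to proportion × payoff for proportions 10%–90%. Only offers
leaving the proposer strictly better off than the alternative option
survive (`reported − offer > 100 − reported`); under the default grid
exactly 36 offers do. Each offer appears once per condition (144 trials
per subject), split over two runs of 72 so that each offer occurs
exactly twice per run.

Accepting pays the power-holder the offer and the proposer the rest of
the reported payoff; in the Dyad scenario the third party receives
`100 − reported`. Rejecting pays proposer and power-holder nothing,
while the third party is paid according to the computer-indicated
option — which in the Bribe condition is the *non*-reported one, so a
rejected bribe restores the third party's larger payoff. This asymmetry
is what gives the harm-based moral cost its lever: only in Dyad–Bribe
does the decision move the third party's payoff (by
`2 × reported − 100`).

## The utility models

Seven social-utility functions compete to explain the accept/reject
choices. All assign a subjective value (SV) to each option from the
payoffs it implies; the workhorse terms are a self-interest weight
`beta_ph`, an other-regarding weight `beta_p`, a moral cost of conniving
`theta` that devalues bribe-tainted personal gain (active when the
bribe indicator `q = 1`), an inequity weight `gamma` on
`|p_p − p_ph|`, and — in the winning model — a weight `omega` on the
third party's payoff under bribery, so that accepting a harmful bribe
forgoes `omega × p_t(reject)` of utility. Two Fehr–Schmidt variants
(condition-specific and agent-specific inequity aversion) complete the
set. Choice follows a softmax with inverse temperature
`tau ∈ [0, 10]`: `P(accept) = logistic(tau × (SV_accept − SV_reject))`,
computed in log-sum-exp form since `tau × SV` can reach 10^4 at the
parameter bounds. Utility parameters are bounded in [−20, 20].

Two structural readings were genuinely open and are resolved as
follows. For the agent-specific Fehr–Schmidt model, the printed Dyad
form multiplies each agent's inequity terms by 0.5 and labels the
parameters by one condition each (proposer: DC; third party: DB); we
apply each agent's pair in both Dyad conditions, which is the minimal
literal reading. Rejection is valued by the same formula as acceptance
in every model — payoffs are simply zero except the third party's
indicated payoff — rather than special-cased; no payoff normaliser is
applied before the softmax.

## Hierarchical estimation

Individual parameters are modelled as draws from group-level normal
distributions on an unconstrained scale and squashed onto their bounded
support by `lower + (upper − lower) × Φ(mu_k + sigma_k × z_sk)`, the
convention of hierarchical Bayesian packages for bounded decision-model
parameters; `tau` is mapped to [0, 10] the same way. Priors are
`mu ~ Normal(0, 1)` and `sigma ~ half-Normal(1)` on the raw scale, with
`z ~ Normal(0, 1)` non-centred; both prior SDs are overridable in
`fit_model()`.

Sampling uses the package's own No-U-Turn sampler (in `src/`), with
closed-form gradients of the log posterior, dual-averaging step-size
adaptation targeting 0.8 acceptance, and a diagonal metric estimated in
two warmup windows. Gradient-based sampling is essential here: the
likelihood depends on products of `tau` with the utility weights, so
the posterior has a scale ridge that defeats one-coordinate-at-a-time
samplers (a Gibbs/slice implementation of the same model needs two
orders of magnitude more iterations to mix). Convergence is summarised
by split-chain R-hat over all individual and group-level quantities and
the log posterior; fits flag divergent transitions.

The full protocol (`mcmc_control("full")`) is 4 chains with 2000
warmup and 1000 sampling iterations each. The desk-scale preset
(`mcmc_control("test")`, 2 chains, 400 + 400) serves the quick fits in
the test-suite; the convergence-sensitive checks and the acceptance
script use 4 chains with 500 + 500, where fits of the winning model to
the default 39-subject study reach max split R-hat ≈ 1.03–1.05. Very
short 2-chain fits can occasionally exceed the 1.1 threshold — exactly
what `check_convergence()` is there to flag.

Model comparison uses PSIS-LOO computed from the pointwise (per-trial)
log-likelihood over all retained draws: importance ratios are smoothed
by a generalized-Pareto fit to their right tail (empirical-Bayes
estimator, tail length `min(S/5, 3√S)`, smoothed weights truncated at
the largest raw weight), and `looic = −2 × elpd` with a difference of
10 treated as decisive. The implementation is cross-checked in the
test-suite against values frozen from an independent PSIS
implementation on a deterministic fixture.

## The synthetic-data generator

`population_spec()` defaults encode the study conditions: 39 subjects,
winning-model group means/SDs `beta_p −0.88 ± 2.48`,
`beta_ph 16.02 ± 2.47`, `theta 5.94 ± 4.28`, `omega 0.97 ± 0.82`,
`gamma −2.35 ± 2.23`, each draw truncated to [−20, 20] (truncation
rather than rejection keeps draw counts seed-stable), and parameters
drawn independently (the reported θ–ω correlation of 0.258, p = 0.113,
supports near-independence; the full empirical correlation structure is
not available). The inverse temperature is fixed at `tau = 0.01`: no
`tau` estimates are published, and this value reproduces per-condition
acceptance rates in the observed 60–85% band — a default study lands
within a few points of the published 61.6% (DB), 82.8% (DC), 67.0%
(SB), 83.3% (SC).

`generate_patterns()` produces subject × voxel contrast matrices with
plantable structure: a per-subject component shared by both condition
maps (`shared_signal`), a common Bribe-vs-Control direction
(`condition_effect`), a moral-preference component in the contrast whose
per-subject amplitude follows standardised `(theta, omega)`
(`behavior_coupling`), and i.i.d. Gaussian noise. These are statistical
stand-ins for ROI-extracted GLM contrast values: no haemodynamics,
trial-level responses or spatial smoothness are modelled, so passing
tests demonstrate the correctness and calibration of the similarity and
decoding statistics, not their sensitivity on real BOLD data.

## Multivariate analyses

The behavioural RDM is the pairwise Euclidean distance in the
`(theta, omega)` plane. z-scoring each parameter first is the default:
the two spreads differ five-fold (4.28 vs 0.82), so raw distances are
theta-dominated; the convention is switchable (`standardize = FALSE`)
and recorded in the RDM's metric label. The neural RDM is
`1 − Pearson r` between subjects' voxel vectors. IS-RSA is the Spearman
correlation of the lower triangles, with Mantel permutation inference
(rows and columns of one RDM jointly permuted; one-tailed for positive
association, matching the directional claim; `p = (b + 1)/(B + 1)`).
Cross-condition pattern similarity Fisher-z-transforms each subject's
between-condition correlation and tests the mean z against zero by
sign-flipping (two-sided by default, as for a one-sample test).
LOSO decoding trains a linear SVM (`C = 1`) on all other subjects' two
condition maps and scores the held-out subject by the two-alternative
forced choice (decision value of their condition-a map above their
condition-b map); ROC and AUC pool the cross-validated decision values,
and the permutation null re-runs the full cross-validation with
condition labels randomly swapped within subjects. The full protocol
uses 5000 permutations; tests use 19–500 depending on the property
being checked, with the `+1` correction keeping p-values in
`[1/(B+1), 1]`.

## Numerical choices

* Offer rounding: nearest integer, ties to even (reproduces the 38 =
  round(0.4 × 96) exemplar and keeps CNY integral).
* Softmax and Bernoulli log-likelihoods share one `exp` per trial and
  use `log1p`; probabilities returned to users are clamped away from
  exact 0/1 so downstream logs stay finite.
* NUTS: max tree depth 10, divergence threshold 1000 on the joint log
  density, initial step size by the doubling heuristic, chain seeds
  derived from the user seed by `sample.int`.
* Per-subject correlations with |r| = 1 are clipped before the Fisher
  transform (flagged); constant voxel vectors are an error naming the
  offending subjects.
* PPC averaging uses the analytic softmax expectation per draw by
  default (the infinite-replication limit; 200 draws suffice for stable
  correlations), with draw-wise Bernoulli simulation available; the
  out-of-sample check simulates one run-2 dataset from the run-1
  individual posterior means.

## Problem sizes used by the checks

The test-suite fits use the default 39-subject study with the reduced
preset for the headline checks (convergence, recovery, predictive
checks, and a five-model comparison at 2 × (200 + 200)), an 8-subject
study for unit-level fitting contracts, and 10–39-subject pattern
matrices with 19–500 permutations for the calibration and power checks
(200 generator seeds for the null-uniformity properties). The
acceptance script fits the 39-subject study at 4 × (500 + 500).

## Known limitations

* Parameter recovery under the synthetic defaults is information-
  limited. The published across-subject statistics are statistics of
  individual *posterior means*; using them as true population spreads
  (as the generator deliberately does) yields, after hierarchical
  shrinkage, first-stage estimates whose spread is several-fold smaller
  than in the real data (for `omega`, ≈ 0.2 vs 0.82). The
  simulate-refit recovery correlation for `omega` is then far below the
  published bound, and `beta_ph` recovery is additionally limited by
  the `tau`-utility scale ridge (the generator's `tau` is constant
  across subjects, so any fitted `tau` spread is noise injected into
  `beta_ph`). A back-of-envelope bound — `r ≤ sqrt(s² / (s² + σ²))`
  with `s` the generating spread and `σ` the per-subject posterior SD —
  reproduces the published ≈ 0.71+ when `s` is set to the printed SDs,
  which is exactly the regime the real recovery ran in. Longer chains
  and alternative `sigma` priors measurably change none of this.
* The sampler reports divergent transitions but does not re-run with a
  higher `adapt_delta` automatically; occasional single-digit
  divergence counts on these posteriors have not been seen to bias the
  headline quantities.
* The deposited 36-offer list is reconstructed from the stated grid and
  constraint (it reproduces the printed cardinality and exemplar), and
  can be overridden by supplying a trial table.
* Neural patterns are generative stand-ins; nothing here validates
  against real contrast maps.

## A worked example

```{r example, eval = FALSE}
library(moralcost)

study <- generate_choice_study(population_spec(), seed = 1)
acceptance_by_condition(study$trials)

fit <- fit_model(study$trials, model_id = 5, mcmc_control("test"),
                 seed = 2)
check_convergence(fit)
tidy(fit)
ppc_within(fit, n_reps = 200, seed = 3)

pats <- generate_patterns(pattern_spec(), study$params, seed = 4)
contrast <- as_pattern_matrix(unclass(pats$bribe) -
                                unclass(pats$control))
isrsa(parameter_rdm(fit$estimates$theta, fit$estimates$omega),
      neural_rdm(contrast), n_perm = 5000, seed = 5)
```
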