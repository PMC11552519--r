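---
title: "Classify-refine models of social attribution: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classify-refine models of social attribution: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the data

The Sharing Game is an iterated Dictator game. On each trial a "dictator"
splits 10 pence either fairly (5:5) or unfairly (10:0) with the passive
participant. A session comprises four dictator blocks of 12 consecutive
trials; two dictators are generous (80% fair) and two are mean (20% fair).
Each trial yields three participant reports: a fairness expectation given
*before* the split is revealed, and attributions of harmful intent (HI) and
self-interest (SI) given after it. Dictators carry an ethnicity label
(white / non-white), and the study design is a two-wave (baseline, one-week
follow-up) randomized placebo vs. citalopram trial.

Data are long-format tibbles, one row per trial (`session_columns()`), read
and written by `read_sessions()` / `write_sessions()`. Reports live on
[0,1] internally; the on-file scale (0–1, 0–10, 0–100) is declared in
`session_schema()` because response granularity is an interface property of
a given dataset, not of the model.

## The generative model

### Learning core

Both model families are recursive Bayesian filters over a joint grid of
HI x SI attribute levels. Dictator character is static within a block, so
the hidden Markov process has identity transitions and the filter simply
propagates the posterior forward.

A dictator of attributes $(h, s)$ splits fairly with probability

$$ P(\text{fair} \mid h, s) = \sigma(w_0 - w_H h - w_S s), $$

so positive weights mean harmful/selfish dictators behave unfairly, and
$w_0$ is an overall beneficence bias (`policy_fair_prob()`).

**Classify-refine family.** Each dimension has just two states,
"beneficial" and "detrimental", anchored at attribute values 0.05 and 0.95.
The outcome likelihood of each joint state is *refineable*: it is a
Dirichlet count pair initialized at `aEv * (p_fair, 1 - p_fair)` of the
state's policy fairness. `aEv` (typing confidence) is the prior evidence
behind the state-to-policy typing — large values freeze the mapping, small
values let a few trials move it. After each observed split the count of the
observed outcome is credited *in proportion to the posterior belief* that
each state produced it; counts then decay toward their initial values by
the retention factor `omega` (forgetting); and when the participant moves
to the next dictator a fraction `lambda_other` of the accumulated
refinement carries over (`carry_over()`), while state priors reset.

The state prior factorizes over dimensions with means `pHI0` and `pSI0`.
With two states per dimension the filter uses only these means, so the
prior-evidence parameters `dEv` and `EvRat` have no leverage in this
family; they are identified only in the classic family below. This is a
known identifiability property of the two-state instantiation, and matches
the empirical finding that `dEv` is among the least stable parameters in
fits of this model class.

**Classic family.** Six fixed attribute levels per dimension at the bin
midpoints $\{1/12, 3/12, \ldots, 11/12\}$, a 36-state grid. The
state-to-policy mapping is fixed at the logistic policy values (no count
learning, no forgetting, no carry-over), and the prior over each dimension
is a discretized Beta with mean `pHI0` (resp. `pSI0`) and concentration
`dEv * EvRat` (resp. `dEv`), so both families share one parameter
vocabulary.

### Report channels

Beliefs map to the three reports through discretized squared-distance
softmax channels (`report_distribution()`): the probability of a report bin
$b$ is proportional to $\exp(-\alpha (v_b - m)^2)$ where $m$ is the model
value and $\alpha$ (`alphaPrec`, decision precision) is shared across the
three channels. The fairness expectation is scored against the one-step
predictive `predict_fair()` of the *pre-outcome* belief; HI and SI against
the posterior marginals of the *post-outcome* belief — the detrimental-state
mass in the classify-refine family, the posterior-expected attribute value
in the classic family.

For non-white dictators the attribution (not expectation) channel values
are shifted on the logit scale by `POCbias`, any sign, before entering the
channel; the learning core itself is colour-blind. Setting `POCbias = 0`
makes the biased model's likelihood identical to the unbiased one, which is
the nesting the POC model comparison rests on.

The default scale is 11 equally spaced bins on [0,1]. The channel kernel is
a deliberate design choice: a squared-distance score is symmetric,
unbounded-precision-consistent (the `alphaPrec` limits are uniform and
nearest-bin point mass), and swappable should a log-probability kernel be
preferred; observed reports are snapped to the nearest bin before scoring,
and channel probabilities are floored at $10^{-12}$.

## Fitting and model comparison

Fitting is per-session maximum a posteriori (`map_fit()`). Priors are
weakly informative over native space — Beta(1.2, 1.2) on probabilities and
rates, Gamma(2, scale 2) on positive scales, Normal(0, 2) on weights — and
are deliberately broad re-specifications, overridable in `default_priors()`.

The optimizer is an adaptive multistart coordinate grid search in
transformed space (logit / log / identity per parameter): likelihood
surfaces of this model class defeat plain gradient descent, so candidate
grids per dimension are evaluated, recentred and contracted until the
spacing drops below tolerance. The incumbent then gets one wide-grid
restart plus a Nelder–Mead simplex polish, both accepted only when they
improve the objective — the coordinate search cannot move diagonally, and
the retention/typing-confidence ridge (see limitations) benefits from a
simplex that can. The objective never decreases by construction, and fits
are deterministic given the seed.

Model comparison uses per-participant BIC with the small-sample
(AICc-style) correction $2k(k+1)/(n-k-1)$, $n$ counting every report
datapoint (3 per trial, 144 per complete session); the uncorrected BIC is
emitted alongside so either convention can be inspected. A parameter fitted
once across the sample would contribute an equivalent per-participant
penalty of $\ln(n_{total})/N$, keeping the summed penalty at
$\ln(n_{total})$, consistent with BIC/2 approximating log model evidence.
`compare_models()` reports medians, counts beyond the conventional
$|\Delta BIC| \ge 6$ evidence threshold, and both the rank-sum and
signed-rank tests (the samples are paired; the rank-sum headline is kept
for comparability, the signed-rank is arguably the right test).

The registry (`model_registry()`) holds the comparison space: the full
classify-refine model, the winning model (`EvRat = 1`, `POCbias = 0` — two
parameters fewer), the winning model with the bias restored, lesions
without carry-over or without forgetting, an attribution-only variant
(96 datapoints per session), and the classic learner.

## The synthetic cohort

`population_config()` encodes the study conditions: 74 participants, 42
randomized to citalopram, 66 returning at the one-week follow-up; four
dictators per session (two at fairness 0.8, two at 0.2, order randomized,
ethnicity labels balanced) with 12 trials each. Person-level parameters are
Normal in transformed space — consistent with the approximately normal
transformed parameter distributions this model class produces — constant
across waves up to test-retest noise (sd 0.2), with a 5% heavy-tailed
contamination fraction to exercise the outlier screen. The citalopram
group's follow-up parameters are shifted by the reported drug effects:
transformed `aEv` by −1.18 and transformed `pSI0` by +1.32.

The remaining defaults were chosen once as a realistic regime and are not
calibrated to any fitted dataset: prior attribution tendencies around
0.3/0.35, policy weights $(w_H, w_S, w_0) \approx (2, 1, 1.5)$ — which put
the two dictator types near the environment's 0.8/0.2 fairness rates —
typing confidence around 3 (a few trials of refinement visible), retention
around 0.85, carry-over around 0.3, and decision precision around 30
(reports typically within one bin of the model value; "moderate noise").
What the generator does *not* emulate: questionnaire psychometrics,
reaction times, within-trial question-order effects, or any systematic
deviation from the model family itself — so passing recovery tests shows
the pipeline is consistent, not that human data obey the model.

`parameter_recovery()` and `model_recovery()` close the loop:
simulate-at-known-truth, fit, and measure transformed-space correlations /
BIC family assignment. At study scale the problem sizes used are 74 agents
for parameter recovery and 20 replicate 30-agent cohorts per generating
family for model recovery, with a lighter optimizer budget for the latter
(family separation is tens of BIC points, far coarser than optimizer
noise).

## Second-level statistics

`average_measures()` gives the session means (HIAv, SIAv, predAv).
`stability_regression()` follows the two-step procedure: robust Huber
M-estimation (`MASS::rlm`, default tuning) for the hypothesis test on the
baseline coefficient's t-value, with the OLS adjusted R² alongside;
`outlier_screen()` then flags OLS points with Cook's distance > 1 or
|standardized residual| > 3 (strict inequalities; boundary points are not
flagged) for per-analysis exclusion; `wave_drug_mixed_model()` fits
`value ~ wave * drug + (1 | participant)` with Satterthwaite p-values,
reported uncorrected.

## Numerical choices and degenerate inputs

* Transforms clamp probabilities to $[10^{-12}, 1-10^{-12}]$ and floor
  positive scales before log; the round trip is exact to $10^{-10}$.
* Channel values of exactly 0 or 1 are clamped to $[10^{-6}, 1-10^{-6}]$
  before the POC logit shift.
* A zero total likelihood in a belief update (possible only with degenerate
  fixed likelihoods) raises an explicit degeneracy error rather than
  propagating NaN.
* Ties in nearest-bin snapping resolve to the lower bin; grid-search ties
  keep the incumbent, making fits order-independent and deterministic.
* An all-parameters-fixed spec degenerates to a pure likelihood evaluation;
  a fit whose every start is non-finite returns a flagged failure result,
  never a crash.

## Known limitations

* **Retention is weakly identified at desk scale.** With 4 x 12 trials and
  11-bin reports, `omega` trades off against `aEv` (both scale the amount
  of effective refinement); profile fits that hold every other parameter at
  truth recover `omega` at r ≈ 0.7, and the joint MAP substantially less.
  `w0`, `aEv` and `alphaPrec` recover well (r ≈ 0.65–0.97 at study scale).
  Interpreting individual-difference claims about retention therefore needs
  longer blocks or sharper response scales; the package reports recovery
  correlations rather than hiding them.
* `dEv`/`EvRat` carry no information in the classify-refine family (see
  above); their fitted values sit at the prior mode and should not be
  interpreted there.
* The carry-over operator acts on likelihood counts only, not on state
  priors: blending priors too would confound the initial-attribution
  parameters with the carry-over mechanism. This is one consistent
  instantiation of between-dictator generalization; alternatives exist.
* No hierarchical pooling: fits are per-session MAP, as in the comparison
  this package implements; group-level shrinkage would change parameter
  stability estimates.
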