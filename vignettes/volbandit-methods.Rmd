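---
title: "Modelling reward learning under volatility with volbandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward learning under volatility with volbandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its schedule

volbandit models choice behaviour on a two-option probabilistic bandit in
which reward contingencies are stable for one half of the session and
volatile for the other. The default schedule has 120 trials: a 60-trial
stable phase in which one option is rewarded on exactly 75% of trials, and
three 20-trial volatile blocks with an 80/20 contingency whose
high-probability side reverses at every block boundary. Phase order is
counterbalanced across participants. Rewards are all-or-none (no losses);
optionally each trial displays complementary coin magnitudes drawn uniformly
from 10..90 (summing to 100), for model variants whose utilities weight
probability by magnitude.

Schedules are *exact-ratio*: the number of rewarded trials per phase/block
is fixed (45/60 stable, 16/20 per volatile block) and only their positions
are permuted under the seed. Independent Bernoulli draws would only realise
the nominal contingencies on average; fixed ratios make the printed 75%/80%
contingencies a property of every generated schedule and make schedule-level
checks deterministic. The phrase "rewarded on 75% of trials" is read as a
fixed ratio, which is also how such tasks are implemented in practice.

## The model family

Twelve candidate models span the dimensions usually considered for this
task -- learning, exploration, starting bias, and magnitude sensitivity:

* **M01, M02** -- null models: choices are independent of feedback, with
  probability 0.5 (M01) or a constant bias `b` (M02).
* **M03..M10** -- Rescorla-Wagner delta-rule learners crossing
  {single vs. phase-specific (dual) learning rate} x {starting bias off/on}
  x {magnitude utility off/on}. Values update as
  `v <- v + alpha * (r - v)` for the chosen option only; `alpha` is
  `alpha_stable` on stable trials and `alpha_volatile` on volatile trials
  in dual-rate models.
* **M11, M12** -- win-stay-lose-shift: repeat a rewarded choice with
  probability `p_stay`, shift after non-reward with the same probability;
  M12 adds a first-trial bias.

Choice probabilities follow a softmax with *temperature* `tau`:
`P(A) = exp(u_A / tau) / (exp(u_A / tau) + exp(u_B / tau))`, with utilities
`u = v` (probability-only) or `u = v * m / 100` (magnitude models, keeping
`u` in [0, 1] so a single temperature scale serves all variants). Lower
temperature means less exploratory, more deterministic choice. The
designated winning model (M08) has four free parameters per participant:
starting bias `b` (initial values `(b, 1 - b)`), temperature `tau`, and the
two phase-specific learning rates.

Two parameterisation choices were genuinely open and are resolved as
follows. The bias is an *initial-value asymmetry*, not a per-trial additive
bonus: "initial preference" reads naturally as a starting state, and an
additive kernel would change the asymptotic choice probabilities, which is
a different psychological claim. Temperature multiplies as `u / tau` (a
true temperature) rather than `beta * u`, so that *lower* values mean less
exploration.

The family also exposes trialwise derived series for each fitted model:
`ev_chosen` (the value estimate of the chosen option before feedback) and
the prediction error `pe = r - ev_chosen`, the quantities used as
model-based regressors in neuroimaging analyses of this task.

## Priors and hierarchical estimation

All parameters are estimated on unconstrained scales -- logit for
unit-interval parameters, log for temperature -- with weakly informative
("soft constraint") priors: Normal(0, 1.5) on logit-scale parameters,
Normal(-1, 1) on log temperature, half-Normal(1) on group SDs. These are
configuration values (`prior_spec()`), not constants, because the exact
priors used in any given study of this task are rarely published; the
defaults cover the plausible ranges (e.g. central 95% of the temperature
prior is roughly 0.05 to 2.6) without forcing them.

Two estimators are provided:

* `fit_participant()` -- penalised maximum a posteriori estimation per
  participant (multi-start BFGS on the transformed scale, seeded restarts,
  Hessian at the mode). Used for the participant-level null-model screen
  and for K-fold refits, where independence between participants is the
  point.
* `fit_rl()` -- the hierarchical Bayesian fit. Participant parameters are
  non-centered: `theta_i = mu + sigma * z_i` with `z_i ~ Normal(0, 1)` on
  the transformed scale, which avoids the funnel pathology at small group
  SDs. Sampling is Metropolis-within-Gibbs with likelihoods in C++: one
  vectorised joint random-walk update of each participant's `z` row per
  sweep, then scalar random-walk updates of each group mean and log group
  SD. Proposal scales adapt during warmup by Robbins-Monro steps toward
  acceptance targets of 0.25 (multivariate blocks) and 0.44 (scalars), the
  standard random-walk targets. Chains are seeded independently;
  reproducibility is exact for a given `sampler_config()`.

Convergence is summarised by split-R-hat and a bulk effective sample size
on the group-level parameters, with a soft failure flag at R-hat > 1.05.
Random-walk Metropolis has no divergence diagnostic; the divergence count
reported for interface completeness is always zero. Default chain lengths
(2 chains, 500 warmup + 500 kept) suit interactive use; the recovery
analyses below use 1500 + 1500, at which split-R-hat for the winning model
on a 46-participant cohort is near 1.

## Model comparison and the exclusion rule

`compute_waic()` implements WAIC from the pointwise posterior
log-likelihood matrix: `lppd_i = log mean_s exp(loglik_si)` by log-sum-exp,
penalty `p_i = var_s(loglik_si)`, `waic = -2 * sum(lppd_i - p_i)`, with the
usual standard error over pointwise contributions. `kfold_cv()` partitions
trials within participant, stratified by phase (a continuing round-robin
keeps folds balanced overall and within phase), refits by penalised MAP on
the training trials and scores held-out trials at the fitted parameters.
The value dynamics always run over the complete sequence -- values are
conditioned on the observed history -- and the fold membership only decides
which trials' log-probabilities enter the objective or the score. K
defaults to 10, the community default when the fold count is otherwise
unspecified; `K = n` reduces exactly to leave-one-trial-out.

The participant-level screen fits every candidate to each participant
independently and excludes participants whose best *null*-family evidence
is at least as good as their best non-null evidence -- operationalising
"better evidence for the null model indicates random decision making".
Individual (non-hierarchical) fits are used deliberately: one participant's
exclusion must not depend on other participants' data, since exclusion
precedes the group-level fit. The default evidence is the Laplace
approximation to the log marginal likelihood. A WAIC variant (over draws
from the Laplace approximation of the posterior) is available, but the
screen takes a maximum over ten non-null candidates, and Monte-Carlo noise
in sampled WAIC estimates biases that maximum upward -- in simulation
roughly a third of genuinely uniform responders escape exclusion that way,
while the noise-free marginal-likelihood criterion captures essentially all
of them at a ~2% false-positive rate.

Group-level comparison sums pointwise WAIC over the included participants
(equal-weighted participant evidence) and ranks models, breaking ties
toward fewer free parameters.

## The synthetic cohort generator

`cohort_config()` encodes the study conditions the package is exercised
under: two groups of 37 (MT) and 32 (NMT) participants whose covariates
(sex, age, IQ, pubertal status, SES) are drawn i.i.d. from shared
distributions -- matched by construction -- and whose true agent parameters
follow the group structure of interest:

* temperature: NMT mean 0.30, SD 0.10 (natural scale, truncated at 0.02);
  the MT mean is lowered by `temperature_effect_d` (default 0.70) pooled-SD
  units. With utilities in [0, 1] this temperature range produces accuracy
  around 70-80%, a realistic regime for youth samples on this task.
* learning rates: means 0.35 (stable) and 0.41 (volatile) with SDs 0.07 and
  0.17, correlated within participant at 0.47. The correlation is derived,
  not free: given the two means and SDs, a paired t statistic of about
  -2.7 across 46 participants implies a difference-score SD of about 0.15,
  i.e. a correlation near 0.47.
* starting bias: logit-Normal(0, 0.7).
* 35% of participants (exact count, positions sampled) are *random
  responders* simulated from the unbiased null model -- the mechanism
  behind the exclusion phenomenon. The rest are simulated from the winning
  model with their own true parameters.
* phase order alternates deterministically within group, guaranteeing
  counterbalance even at small n.

Follow-up internalising symptoms are linear-Gaussian on standardized
predictors: standardized baseline score (coefficient 0.35), effect-coded
group (MT = +1; 0.15), standardized true temperature (-0.15), and the
group-by-temperature product with coefficient `beta_int = -0.80`, plus
Gaussian noise (default residual SD 0.5), mapped onto a natural SDQ-like
scale. Retention is Bernoulli per group with probabilities 27/37 and 29/32.
True parameters are stored in the cohort table, so parameter-recovery
checks are a join away.

What the generator does *not* emulate: item-level questionnaire structure,
integer-valued symptom scores (the follow-up scale is continuous),
maltreatment-subtype severity, non-linear or non-Gaussian
symptom-temperature relations, and any dependence of random responding on
covariates. Passing recovery tests therefore demonstrate that the
estimators work when their assumptions hold at study-realistic sizes and
noise levels -- not that the assumptions hold in any real population.

### Two metric subtleties

**Standardized interaction coefficients.** Under a strong moderation
effect the outcome's total SD at low residual noise is dominated by the
interaction term, whose regressor variance is below 1 because group and
temperature correlate by design. An *outcome-standardized* interaction
coefficient is then systematically larger in magnitude than the generating
coefficient (about -1.0 for a generating -0.80) -- a metric artefact, not
an estimation error. Recovery checks therefore compare coefficients on the
generative scale (`standardize_outcome = FALSE`); at the generator's
default residual SD the outcome-standardized coefficient is itself close
to -0.80, which is the regime the printed statistics come from.

**Recovery design for learning rates.** SDs of *hierarchically fitted*
estimates are shrunken and understate generative spread. Using the printed
stable-rate SD (0.07) as the true between-participant spread makes stable
learning rates nearly unidentifiable as individual differences (recovery
correlations around 0.2 at 60 stable trials regardless of estimator -- an
information ceiling, verified with an oracle fit that knows the generative
prior). Parameter- and model-recovery experiments therefore draw
`alpha_stable` with SD 0.15, spanning roughly 0.05-0.65 -- the field's
convention of assessing recovery across the plausible range -- while the
cohort-emulation defaults keep the printed values for the group-level
statistics.

## Problem sizes and numerical choices

The recovery analyses shipped with the package use: one 46-participant
cohort (120 trials each) with 2 chains x (1500 warmup + 1500 kept) sweeps
for parameter recovery; twenty replicate 46-participant cohorts with
2 x (400 + 300) sweeps per model for the 12-model recovery study; and
69-participant cohorts for the exclusion-rule and cohort-statistics
checks. These sizes were chosen to match the study's own scale while
keeping a full run in minutes on one core. Calibration of the group-mean
credible intervals is checked at a reduced scale (20 agents, 8
replications) as pooled per-parameter coverage; note that the joint event
"all four 95% intervals cover" has expected probability about 0.81 even
under perfect calibration, so per-parameter coverage is the meaningful
calibration measure.

Other numerical choices: choice probabilities are clamped to
[1e-12, 1 - 1e-12] before logging; MAP restarts draw from the prior with
the first start at the prior mode; Hessians that fail Cholesky are
ridge-regularised before Laplace draws; the sensitivity-d inversion uses
bisection to 1e-6; Mann-Whitney p values are exact by enumeration up to a
combined n of 12 (ties handled by enumeration over value assignments) and
tie-corrected normal otherwise; the retention chi-square is the uncorrected
Pearson statistic, which is the form that reproduces the printed value on
the retained-count table (the Yates-corrected statistic does not).

## Known limitations

* Random-walk Metropolis mixes more slowly than gradient-based samplers;
  long chains are cheap here because likelihoods are in C++, but models
  with more than ~6 free parameters per participant would warrant HMC.
* The Laplace evidence used in the exclusion screen assumes a unimodal,
  roughly Gaussian posterior on the transformed scale; for 120-trial data
  and these models that is accurate, but it would degrade for very short
  sessions.
* K-fold CV scores held-out trials at the MAP point estimate rather than
  integrating over the posterior; this is the usual pragmatic choice and
  is consistent across models being compared.
* The Bayesian volatility-observer class of models is intentionally out of
  scope; the model registry is configuration-driven so further candidates
  can be added without code changes.
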