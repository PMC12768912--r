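---
title: "Models and methods: linking glucose tolerance to reward learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: linking glucose tolerance to reward learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(glycolearn)
```

glycolearn implements a complete analysis pipeline for studies that relate
oral-glucose-tolerance dynamics to reinforcement-learning parameters:
simulate probabilistic-selection-task (PST) behaviour and continuous
glucose monitor (CGM) traces with known ground truth, summarise the OGTT
response as incremental area under the curve (iAUC), fit hierarchical
Bayesian Q-learning models by gradient-based MCMC, and propagate posterior
uncertainty into parameter–covariate correlations reported with
highest-density intervals (HDIs). This vignette documents the models, the
numerical choices, and the boundaries of what the synthetic benchmarks can
and cannot show.

## The behavioural task and the learning model

The PST presents six stimuli with reward probabilities 0.20–0.80. Training
runs 6 blocks of 60 trials over three fixed pairs (80–20, 70–30, 60–40; 20
presentations per pair per block, left/right counterbalanced). A 60-trial
test phase shows every unordered pairing twice in each left/right order
with no feedback. `build_task_design()` constructs this schedule under a
seed; the symbol-to-probability assignment is a random permutation, as in
the task participants see.

Choice follows a softmax (logistic) rule on the difference of learned
values, scaled by the outcome sensitivity (inverse temperature) $\beta$:

$$P(\text{choose } i \text{ over } j) = \mathrm{logistic}\!\big(\beta (Q_i - Q_j)\big),$$

and after feedback $R \in \{0, 1\}$ the chosen stimulus updates by the
Rescorla–Wagner delta rule

$$Q \leftarrow Q + \alpha\,(R - Q),$$

with a single learning rate (`one_lr`) or separate rates for positive and
negative prediction errors (`two_lr`: $\alpha^+$ = reward learning rate,
$\alpha^-$ = loss learning rate). Points magnitude is not modelled; a win
is 1. Q-values start at `q_init = 0.5`, the midpoint of the outcome scale
(configurable; with 0/1 outcomes and $\alpha \in [0,1]$ the values then
remain in $[0,1]$). A prediction error of exactly zero — a measure-zero
event under stochastic outcomes — takes the reward learning rate. Missed
trials carry values forward unchanged and never enter the likelihood. Only
training trials enter the likelihood: the test phase gives no feedback, so
it is held out for model-agnostic accuracy analyses and posterior-predictive
overlays.

## Hierarchical fitting

Subject-level parameters live on unconstrained scales — log-odds for
learning rates, log for $\beta$ — and are drawn non-centred from group
normals:

$$\eta_{s,p} = \mu_p + \sigma_p z_{s,p}, \qquad z_{s,p} \sim \mathcal N(0,1),$$

with weakly-informative priors $\mu_p \sim \mathcal N(0,1)$ and
$\sigma_p \sim \text{half-}\mathcal N(0,1)$. These are standard defaults
for this model family; all are fixed in code and stated here rather than
claimed to match any particular study's supplement. The $\beta$ link is a
plain exponential; the priors keep it away from degenerate greedy regimes
on ordinary cohorts.

Sampling uses a No-U-Turn sampler written for this package (Rcpp), with
analytic gradients of the full joint density obtained by forward
accumulation through the Q-value recursion. Warmup adapts the step size by
dual averaging (target acceptance 0.8) and a diagonal metric over expanding
windows. Fits are bit-reproducible from (data, seed, settings). The default
configuration is 4 chains × 1000 post-warmup draws = 4000 draws. Every fit
reports the standard Hamiltonian diagnostics — divergence count, split-Rhat
per fitted quantity, energy BFMI per chain, and max-treedepth hits — and
`fit_qlearning()` errors (or warns, per `on_bad_fit`) when any breaches the
usual thresholds: zero divergences, Rhat < 1.1, E-BFMI > 0.3, no treedepth
saturation. Very small hierarchies (a handful of participants) exhibit the
familiar funnel geometry and can show isolated divergences at the default
target acceptance; raising `target_accept` to 0.9 resolves this.

Model comparison uses approximate leave-one-out cross-validation by
Pareto-smoothed importance sampling over participant-level pointwise
log-likelihoods (one observation = one participant's full choice sequence),
with the generalized Pareto tail fitted by the Zhang–Stephens profile
posterior method and the usual shrinkage of the shape estimate. The
comparison reports the expected-log-predictive-density difference and its
standard error; a difference beyond about 2 SE is read as a clear
preference.

## Glucose metrics

`compute_iauc()` implements the trapezoid rule above the fasting baseline:
each interval contributes $((y_1 + y_2)/2)(t_2 - t_1)$ in excess
concentration; intervals that cross the baseline are truncated at the
linear interpolant's crossing point so only the positive area counts, and
intervals entirely at or below baseline contribute nothing. The baseline is
the fasting glucose of the same trace — the reading at the largest time at
or before ingestion — and the integration window is clipped to [0, 120]
minutes, the 2-hour protocol (both configurable; we assume the window is
exactly the 2 post-ingestion hours). Readings exactly at baseline are
treated as zero excess, which is the common limit of both adjacent cases.
Units are fixed internally at mmol/L and minutes; `read_cgm_csv()` converts
mg/dL on ingest (÷ 18.016).

## The synthetic cohort and what it does (not) show

`generate_cohort()` emulates the three input streams with known ground
truth. Agent parameters are drawn from group distributions chosen to span
the plausible subject-level ranges reported for this task family: reward
learning rate logit-normal around 0.35 (SD 1.0 on the log-odds scale,
covering roughly 0.05–0.85), loss learning rate around 0.25, outcome
sensitivity log-normal around 5 (SD 0.5). True iAUC is log-normal around
170 mmol·min/L (CV ≈ 36%), fasting glucose normal around 5.0 mmol/L, and
the CGM curve is a smooth gamma-like bump
$f + h\,(t/t_p)^s e^{s(1 - t/t_p)}$ sampled every 2 minutes with 0.2 mmol/L
sensor noise; the peak height is scaled so the noiseless curve integrates
exactly to the target iAUC, which is stored as ground truth (the exact
integral is computed by root-finding the baseline crossings and
high-precision quadrature). Questionnaire scores are rounded, range-clipped
monotone transforms of a Gaussian symptom latent (PHQ-9 on 0–27).

Cross-trait structure is planted through a correlated Gaussian latent for
(reward-learning-rate, metabolic, symptom), with defaults 0.32
(LR–glucose), 0.18 (LR–symptoms) and 0.10 (glucose–symptoms). The planted
values refer to the observable scales — natural-scale learning rate, iAUC,
questionnaire score — so the latent correlations are inflated by a
deterministic quadrature factor that undoes the attenuation of each
monotone transform. Affect ratings follow linear per-participant
trajectories with population intercepts/slopes at the observed task
averages (happiness 57.6%, −0.08 points/trial; confidence 37.8%, −0.11;
engagement 65.9%, −0.21), between-person variation in both, and 10-point
rating noise, clipped to [0, 100]. Training-pair order is randomised within
block under the seed (the protocol does not pin this down).

These synthetic benchmarks validate the *machinery*: that the fitting
pipeline recovers parameters at the study's design scale, that planted
effects propagate through simulate → measure → fit → correlate at roughly
their planted size, and that the power calculation reproduces the
preregistered minimum sample size. They do not reproduce any real cohort's
numbers: real CGM data have drift, lag and autocorrelated noise that the
independent-Gaussian sensor model omits; real behaviour includes lapses,
perseveration and session effects outside the Q-learning family; and real
trait correlations are not jointly Gaussian. Validation regressions of
glucose metrics against age or adiposity are supported as generic
operations (`bayesian_regression()`) but their published coefficients
require the original cohort.

## Association analyses

`posterior_correlation()` computes, per posterior draw, the Pearson
correlation between that draw's subject-level parameter values (natural
scale by default; the unconstrained scale is a flag) and a fixed covariate,
summarised by the posterior mean, 90% and 66% HDIs, and P(r > 0) — the
convention of flagging effects whose 66% or 90% interval excludes zero is
preserved in the study report. One estimator subtlety matters when
validating against simulations: the per-draw posterior-mean correlation is
attenuated by within-subject posterior width (each draw adds posterior
noise to every participant's parameter before correlating), so it is a
downward-biased point estimate of the correlation between the underlying
parameters and the covariate. `posterior_correlation()` therefore also
reports `r_of_means`, the correlation of posterior-mean parameters with
the covariate, which is the statistic to compare against a planted
generating correlation; study reports keep the per-draw convention. HDIs
use the sorted-window scan: the
narrowest window of $\lceil m n \rceil$ consecutive order statistics. For
multimodal samples this still returns a single interval by convention.

Win-stay is the probability of repeating a rewarded choice at the next
presentation *of the same pair* (pairs interleave, so the immediately
following trial usually shows a different pair); lose-shift is the
analogue after non-reward. Conditioning on the immediately preceding trial
is available via `condition = "previous_trial"` since the statistic is not
standardised in the literature. Missed trials drop out of numerators and
denominators.

`affect_trend()` fits a Gaussian mixed-effects model of rating on trial
index (fixed intercept anchored at trial 1, fixed slope per trial, random
intercepts and slopes per participant) by Gibbs sampling with conjugate
conditionals; random-effect variances get inverse-gamma priors scaled to
the spread of per-participant least-squares fits. An optional standardized
moderator adds main and moderator-by-trial interaction terms.
`bayesian_regression()` is the generic normal-likelihood linear model with
autoscaled normal priors and Gibbs sampling, reporting HDIs in the same
style.

`sample_size_for_correlation()` finds the smallest n whose two-sided test
of $\rho = 0$ reaches the target power under $\rho = r$, integrating the
exact sampling density of the Pearson correlation (Gaussian hypergeometric
series). For r = 0.4, 80% power, α = 0.05 this gives 46; the Fisher-z
approximation (`method = "fisher_z"`) is slightly conservative and gives
47.

## Recovery and the full pipeline

`run_recovery()` simulates a cohort with known parameters from the group
distributions above, refits, and reports per-parameter Pearson correlation,
bias and RMSE between generating values and posterior means. Generating
parameters deliberately come from the bulk of plausible ranges, not extreme
tails, so the recovery claim is conditional on realistic spreads. At the
study's design scale (48 participants × 360 training trials, 4000 draws)
recovery correlations land in the mid-0.9s for the learning rates and
outcome sensitivity; with 60 trials per participant they drop visibly,
which the test suite checks as a monotonicity property.

`run_study()` chains every stage — glucose summaries, both model fits, LOO
comparison, the 3 × 5 grid of parameter–covariate posterior correlations,
behavioural summaries, and affect trends — under a single global seed that
fans out to per-stage seeds (recorded in the results) via a deterministic
counter scheme, so any stage can be reproduced in isolation.
`make_report()` renders the bundle as text and JSON and fails with an
explicit list of missing stages if given an incomplete run.

## Problem sizes used by the shipped checks

The package's own test suite exercises the MCMC-heavy checks at reduced
sampler settings (2 chains, a few hundred post-warmup draws) with
correspondingly wider stochastic tolerances, and the planted-effect
propagation check at 15 seeded study-scale replicates; `scripts/acceptance.R`
reruns the headline recovery experiment at the full 4 × 1000-draw
configuration. Recovery correlations are data-limited rather than
draw-limited at these scales, so the reduced settings move them by far less
than the tolerances allow.

## Known limitations

- The sampler is single-threaded and sequential over chains; a full study
  fit takes a few minutes of CPU.
- PSIS-LOO with 48 participant-level observations is coarse; Pareto-k
  estimates above 0.7 for a few participants indicate the usual caution.
- The iAUC ground truth in simulation is the noiseless curve's integral;
  sensor noise adds a small positive bias to the measured iAUC near the
  baseline (truncation is convex), visible only at very low excursions.
- `hdi()` returns one interval by convention even for multimodal samples.
- The separate reward/punishment outcome-sensitivity variant is
  deliberately not implemented: with learning rates free it is not
  identifiable in this task.
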