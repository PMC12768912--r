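# glycolearn

Does the body's handling of glucose shape how people learn from reward?
Studies addressing this question pair an oral glucose tolerance test
(OGTT) — a fasted participant drinks a fixed glucose dose and a continuous
glucose monitor (CGM) tracks their blood glucose for two hours — with a
probabilistic selection task (PST), a two-alternative choice task in which
six stimuli pay off with probabilities 0.20–0.80. The analysis then asks
whether individual glucose control (summarised as incremental area under
the curve, iAUC) relates to the parameters of a reinforcement-learning
model fitted to the choices.

glycolearn is an R package for running that entire pipeline, end to end,
with a first-class synthetic-data generator so every stage is testable
against known ground truth. It is aimed at computational-psychiatry and
metabolic-cognition researchers who want a reproducible, seeded version of
this analysis for their own cohorts or for design/power exploration.

## The model

Choices follow a softmax on learned values, scaled by the outcome
sensitivity (inverse temperature) β:

    P(choose i over j) = logistic( β · (Q_i − Q_j) )

and learned values update by the Rescorla–Wagner rule after each outcome
R ∈ {0, 1}:

    Q ← Q + α · (R − Q)

with either a single learning rate α or separate rates α⁺ (reward, positive
prediction errors) and α⁻ (loss). Subject-level parameters are drawn
non-centred from group-level normals on unconstrained scales (log-odds for
α, log for β) and the hierarchy is fitted by a No-U-Turn sampler with
analytic gradients (implemented in Rcpp inside the package), reporting the
full set of Hamiltonian diagnostics (divergences, split-Rhat, E-BFMI,
treedepth). Model variants are compared by PSIS-LOO cross-validation at the
participant level.

Glucose traces are summarised by `compute_iauc()`: trapezoid rule above the
fasting baseline, with linear interpolation at baseline crossings so only
positive area counts, over the 2-hour window. Posterior uncertainty is
propagated into parameter–covariate correlations by computing a Pearson
correlation per posterior draw and reporting the posterior mean with 90%
and 66% highest-density intervals.

## Worked example

Simulate a small cohort, summarise its glucose traces, fit the
dual-learning-rate model, and correlate the reward learning rate with iAUC:

```r
library(glycolearn)

cohort  <- generate_cohort(n_participants = 12, seed = 7, n_blocks = 6)
glucose <- summarize_glucose(cohort$glucose)
head(glucose, 3)
#> # A tibble: 3 × 5
#>   participant_id  iauc fasting  peak time_above_baseline
#>   <chr>          <dbl>   <dbl> <dbl>               <dbl>
#> 1 P01             135.    4.59  7.08                112.
#> 2 P02             142.    5.27  7.62                120
#> 3 P03             279.    4.95  9.22                120.

fit <- fit_qlearning(cohort$trials, variant = "two_lr", chains = 2,
                     warmup = 300, iter = 500, seed = 7,
                     target_accept = 0.9)
fit
#> <ql_fit> two_lr model: 12 participants, 2 chains x 500 draws
#>   divergences: 0  max split-Rhat: 1.004  min E-BFMI: 0.71

iauc <- setNames(glucose$iauc, glucose$participant_id)
posterior_correlation(fit, "alpha_reward", iauc)
#> <correlation_posterior> alpha_reward ~ iauc: mean r = 0.22,
#>   90% HDI [-0.01, 0.40], P(r > 0) = 0.96
```

The iAUC column is in mmol·min/L (higher = poorer glucose control). The
correlation object carries the full set of per-draw correlations; its
posterior mean of 0.22 reflects the cohort's planted learning-rate–glucose
association (0.32 by default) attenuated by estimation noise at n = 12 —
at the study scale of 48 participants the recovered value centres much
closer to the planted one. `P(r > 0) = 0.96` is the posterior probability
the association is positive.

The preregistration-style power calculation is one call:

```r
sample_size_for_correlation(r = 0.4, power = 0.80, alpha = 0.05)
#> [1] 46
```

Other entry points: `run_recovery()` (parameter-recovery experiment),
`run_study()` + `make_report()` (the full simulate → iAUC → fit → correlate
pipeline under one seed), `behavioral_summaries()` (accuracy,
win-stay/lose-shift), `affect_trend()` (mixed-effects trend of on-task
affect ratings), `loo_compare_models()`, `bayesian_regression()`, and
`autoplot()`/`plot_*()` methods for the result objects. The methods
vignette (`vignettes/methods.Rmd`) documents the models, priors, numerical
choices and limitations.

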