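---
title: "Modelling placebo and nocebo effects on instrumental learning"
author: "placeboRL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling placebo and nocebo effects on instrumental learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placeboRL)
```

## The experiment this package models

Expectancy manipulations — an inert "brain stimulation" plus suggestive
instructions and a surreptitiously easier or harder conditioning task —
can shift how people learn from reward. The paradigm is a probabilistic
selection task: on every trial one of three fixed symbol pairs appears,
each symbol rewards probabilistically, and within each pair one symbol is
better. Default sessions use 80/20, 70/30 and 60/40 contingencies over
four 60-trial blocks (240 trials); the conditioning sessions are two
blocks (120 trials) with easier (90/10, 90/10, 80/20) or harder (60/40,
60/40, 55/45) contingencies. Five groups of 16 subjects run two
consecutive days: a natural history group (NHG, default task both days),
placebo and nocebo arms (default task, then the manipulated task plus the
sham treatment on day 1; treatment plus default task on day 2), and two
control arms that get the task manipulation without the treatment.
`make_design()`, `generate_session()` and `group_schedule()` encode this
structure; schedules counterbalance presentation side exactly (half of
each pair's presentations per block show the better symbol on the left)
and randomize order uniformly within block.

## The reinforcement-learning model

Each symbol `a` carries a value estimate `Q(a)`, starting at 0. After
choosing `a` and receiving reward `r ∈ {0, 1}` the chosen symbol's value
is updated with separate learning rates for gains and losses:

    Q <- Q + alpha_G * (r - Q)   if r - Q > 0
    Q <- Q + alpha_L * (r - Q)   if r - Q < 0

With rewards coded 0/1 and rates in [0, 1], every `Q` stays in [0, 1].
Choices follow a softmax on the value difference,

    P(a) = exp(Q_a / beta) / (exp(Q_a / beta) + exp(Q_b / beta)),

so the noise parameter `beta > 0` scales how deterministically the value
difference drives choice: at `beta = 2`, even perfect knowledge of the
easiest pair's values (0.8 vs 0.2) yields only a 0.57 choice probability;
as `beta → 0` choice becomes greedy. `q_update()`, `choice_prob()` and
`trial_loglik()` implement the update, the choice rule, and the
deterministic replay of a subject's trial sequence that yields the
pointwise likelihood. Trials without a response deliver no feedback: they
are dropped from the likelihood and do not advance `Q` (configurable in
principle by pre-filtering the table). Q persists across blocks within a
session and resets between sessions and days — each task uses its own
symbols, and per-day parameter sets keep the day-2 likelihood
self-contained.

## Hierarchical estimation

Subject-level parameters are modelled on unbounded scales — probit for
the learning rates, log for `beta` — and pooled through group-level
normals:

    probit(alpha_G_i) ~ Normal(mu_alphaG, sigma_alphaG)   (day 1)
    probit(alpha_L_i) ~ Normal(mu_alphaL, sigma_alphaL)
    log(beta_i)       ~ Normal(mu_beta,  sigma_beta)

Day-2 parameters are redrawn around shifted means: a common day effect
`b_theta` (what the NHG experiences — pure retest) plus a group-specific
effect `b_theta,group` for the four manipulated groups, both on the
transformed scale. Priors are weakly informative: `mu_alpha ~
Normal(-0.5, 0.6)`, `mu_beta ~ Normal(-1.5, 0.8)`, `sigma_alpha ~
half-Cauchy(0.01)`, `sigma_beta ~ half-Normal(0.3)`, and the group
effects share a `Normal(0, sigma_b)` shrinkage prior with `sigma_b ~
half-Normal(1)`. The implied priors put most learning-rate mass below 0.5
and most `beta` mass well below 2, with permissive tails.

Two documented choices deserve emphasis. First, the link for the
learning rates is probit (the estimation equations), not logit, although
effect tables in this literature are sometimes captioned on the logit
scale; the link is a one-line change in `build_model()` if needed.
Second, the three common day effects are *not* pooled into the
`Normal(0, sigma_b)` shrinkage by default (`shrink_day_effects = FALSE`):
the estimation equations state the shrinkage for the group effects only,
and pooling lets several small group effects drag the shared scale down
and crush a genuinely large retest effect — we observed exactly this
over-shrinkage in simulation. The pooled 15-effect variant remains
available as a switch.

The model ladder has three nested variants: `M1_single_alpha` (one
learning rate and one `beta` per subject, shared across days),
`M2_day_group` (single learning rate, day/group structure), and
`M3_full` (separate gain/loss rates, everything varying by day). The
spec of every variant is compiled by `build_model()` into a joint
log-density with analytic gradients: the trial-level sweep (value replay
plus forward sensitivities of Q with respect to the learning rates) runs
in C++, the hierarchy's chain rule in vectorized R.

### Sampling

`fit_rl()` runs plain Hamiltonian Monte Carlo with a jittered number of
leapfrog steps (uniform on `1:max_leapfrog`), dual-averaging step-size
adaptation toward a target acceptance rate (default 0.8; 0.9 is safer
for the full model's funnel-prone scale parameters), and a diagonal
metric estimated once mid-warm-up. Subject-level normals are
non-centered (`theta = loc + sigma * z`), a posterior-equivalent
reparameterization without which the small-`sigma` funnel defeats any
step size. Default configuration mirrors the original fitting procedure
— eight chains, 1000 warm-up iterations, 1000 retained draws each (8000
total) — and every run takes an explicit seed; chain `c` uses `seed + c`.
Convergence is assessed with the split-chain Gelman-Rubin statistic
(`rhat()`; the accepted threshold is 1.1) and post-warm-up divergences
are counted; either problem raises an R warning rather than failing
silently. Initialization draws from the central region of the priors and
re-tries until the joint density is finite.

## Model comparison

`pointwise_matrix()` evaluates the trial-wise log-likelihood under
posterior draws and `psis_loo()` computes Pareto-smoothed
importance-sampling leave-one-out cross-validation: per observation, the
raw importance weights `exp(-loglik)` have their upper tail (of size
`min(0.2 S, 3 sqrt(S))`) replaced by quantiles of a generalized Pareto
distribution fitted with the Zhang–Stephens estimator; shapes `k > 0.7`
are reported and warned about. LOOIC is `-2 elpd_loo`, and
`compare_loo()` flags absolute LOOIC differences above 10 as strong. The
leave-one-out unit is the single trial, matching the likelihood's
factorization; with very few draws the estimator reduces to exact raw
importance sampling, which is how it is unit-tested against enumeration.

## Behavioral and subjective-report regressions

Accuracy (choice of the better symbol) and reaction time are analysed
with hierarchical Bayesian regressions sampled by JAGS: logistic for
accuracy, Gaussian (identity link, milliseconds) for RT — the RT family
is configurable in principle (a lognormal is the obvious alternative) but
the reported coefficients are on the millisecond scale. Fixed effects
follow a ladder — z-scored trial, symbol pair, day, trial-by-pair and
trial-by-day interactions ("base"), plus group, plus day-by-group —
evaluated by the same LOOIC machinery via `behavior_pointwise()`.
Subject-level intercepts, trial slopes and pair offsets are correlated
multivariate normal with a Wishart prior on the precision. Baselines are
pair AB, day 1, group NHG; `contrast()` differences two day-by-group
coefficients per draw (the placebo-vs-control comparisons). Fixed-effect
priors are Normal(0, 5) on the logit scale and essentially flat for RT;
the original analysis does not state regression priors, so these
defaults are deliberately weak.

The three-category subjective reports (decline / neutral / improve, one
answer per subject for the expected and the perceived question) are fit
with a multinomial-logit ("softmax") regression with factors
task-manipulation (placebo-type vs nocebo-type arm), question, and group
type (control vs experimental), plus the group-by-question and
group-by-manipulation interactions. "Neutral" is the fixed reference
category and coefficients get Normal(0, 2.5) priors, which also
regularize empty cells; the reported quantity —
`implied_probabilities()`, the per-draw softmax of a cell's linear
predictors — is invariant to the reference choice, and each draw's
probability triple sums to one exactly.

## The synthetic cohort generator

`simulate_cohort()` is the package's study simulator: it draws
subject-level parameters from the hierarchy above, runs every subject
through their group's two-day schedule, and serializes to the same
long-format table the loaders accept. Generator defaults are fixed study
conditions, chosen once: group-level means at the field-typical centers
(probit mean -0.5, so learning rates near 0.31; log mean -1.5, so `beta`
near 0.22), spreads `sigma_alpha = 0.25` and `sigma_beta = 0.2` (modest
individual variation consistent with the implied priors), and day/group
shifts at the point estimates reported for the original cohort (e.g. a
+0.30 probit-scale retest increase in gain learning, a placebo arm that
shifts toward loss-learning with reduced noise, a nocebo arm that shifts
toward gain-learning with increased noise). Subjective responses are
drawn from per-group categorical probabilities matching the reported
posterior response probabilities; there is no generative theory behind
them, they exist to exercise the subjective-report model. Simulated
reaction times are lognormal with configurable day/group shifts,
truncated at the 1.7 s deadline — invented plumbing for the RT
regression, not a cognitive model: real RT phenomena (sequential
effects, error/RT coupling, heavy left censoring) are absent, so passing
RT tests says nothing about real chronometry. Likewise the simulator
makes every trial answered by default; real data contain missed
deadlines, which the likelihood handles by exclusion.

## Validation studies and their design

`performance_map()` traces expected accuracy over parameter space by
Monte Carlo (default: the 240-trial default session, 200 replicate
agents per cell, a small pool of shared schedules across cells as common
random numbers). It reproduces the qualitative geometry that makes the
parameter estimates interpretable: chance performance for non-learners
and for `beta` in the hundreds, and an interior optimum in `beta` at
fixed learning rates.

`run_parameter_recovery()` is a simulation-based-calibration harness:
each replicate simulates a scaled-down cohort (default two groups of
eight subjects, 120-trial sessions), fits the full model, and scores
bias, RMSE, HDI coverage of every group-level quantity, and the rank
correlation between true and estimated subject-day parameters. The day
and group effects of each replicate are freshly drawn from centered
normals (sd 0.3 and 0.2, matching the magnitude of effects this paradigm
produces). That choice is deliberate: with effects fixed at one point
value across replicates, the shrinkage prior makes HDI coverage of large
effects systematically sub-nominal, so "coverage ≈ 95%" would be the
wrong yardstick; under prior-consistent draws it is the mathematically
expected behavior of a calibrated Bayesian estimator, which is precisely
what the harness is meant to verify. `run_model_recovery()` simulates
from either ladder end — well-separated gain/loss rates (near 0.7 and
0.2) or a genuinely single rate — fits M1 and M3, and confirms that
LOOIC strongly prefers the full model only when the data were generated
by it.

## Problem sizes and numerical choices

Desk-scale defaults keep every study runnable on one CPU in minutes: the
recovery cohort (16 subjects, 120-trial sessions, ~4800 trials, 109 free
parameters) fits in about a minute with 4 chains of 600 warm-up + 400
retained draws; the acceptance script's eight-chain fit takes a few
minutes. Full paper scale (five groups of 16, 240-trial days, eight
chains of 1000/1000) is available through the same configuration objects.
Other numerical decisions: divergence threshold at an energy error of
1000 (transitions beyond it are rejected and counted); metric
regularization toward 1e-3; `hdi()` assumes unimodal marginals and
requires ≥ 50 draws; zero-variance chains define R-hat = 1; exact-zero
prediction errors update neither learning-rate branch (the update is zero
either way, strict inequalities avoid double application); reward coding
is 0/1 — gain versus loss means presence versus absence of reward, which
is what makes `Q_0 = 0` and the [0, 1] bounds coherent.

## Limitations

The HMC sampler is deliberately simple (static jittered trajectories, a
diagonal metric); it matches this model family but is no general-purpose
replacement for adaptive tree samplers, and heavy funnels (e.g. a nearly
degenerate `sigma_alpha` under the half-Cauchy(0.01) prior) can still
produce occasional divergences — these are warned about and visible in
`$divergences`. LOOIC comparisons use trial-level leave-one-out;
leave-one-subject-out would ask a different predictive question.
Synthetic cohorts share the fitted model's functional form, so recovery
results validate the estimator, not the model's adequacy for real
behavior. The deposited raw data of the original study can be loaded
with `read_trials()` plus a `column_map`, but no download is required or
performed by any test.
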