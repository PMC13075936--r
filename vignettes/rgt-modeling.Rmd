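---
title: "Modeling risky choice on the rat gambling task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling risky choice on the rat gambling task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the scientific question

The rat gambling task (rGT) confronts a rat with four response options for
30 minutes a day. Each option pays a fixed number of sucrose pellets
(1–4) with a fixed probability, and punishes the remaining trials with a
time-out penalty of fixed duration (5–40 s) during which no reward can be
earned. The contingencies are built so that the modest options P1 and P2
maximise pellets per session — their penalties are short and rare — while
the tempting three- and four-pellet options P3 and P4 squander session
time on long time-outs. A subject's preference is summarised by the
*decision score*, (P1% + P2%) − (P3% + P4%): positive means optimal,
negative means risk-preferring.

`rgtrl` implements the computational side of this paradigm: a generative
simulator of the task, a family of trial-by-trial reinforcement-learning
models of how wins and time-out penalties sculpt choice, hierarchical
Bayesian estimation with model comparison, posterior-predictive simulation
of long-run risk preference, and the behavioral endpoint measures and
their standard tests.

## The model family

All five models share the same machinery. Each option `x` carries a latent
value $Q_x$ in pellet units, initialised at zero for a task-naive subject
and carried across session boundaries (the trials behave as one long
concatenated session). Choice follows the softmax rule

$$p(P_x) = \frac{e^{\beta Q_x}}{\sum_y e^{\beta Q_y}},$$

where the inverse temperature $\beta$ sets how deterministically choice
tracks the latent values; $\beta = 0$ is uniform choice. After a win of
$R$ pellets the chosen option's value moves by a delta rule with reward
learning rate $\eta^+$:

$$Q_x \leftarrow Q_x + \eta^+ (R - Q_x).$$

The models differ in what a loss teaches. A time-out of $T$ seconds is
mapped to a pellet-equivalent cost, and the chosen value moves toward that
cost with a separate punishment learning rate $\eta^-$:

| model | loss target | extra parameters |
|---|---|---|
| `basic` | $0$ | — |
| `scaled` | $-mT$ | $m$ (pellets/s) |
| `scaled_offset` | $b - mT$ | $m$, $b$ |
| `nonlinear` | $b - T^{r}$ | $b$, $r$ |
| `reward_scaled` | $-mT$ | $m$, and wins target $mRew \cdot R$ |

The `basic` model ignores penalty duration entirely; the others encode
increasingly flexible hypotheses about how duration maps to subjective
cost. `reward_scaled` is a control: it gives rewards the same linear
scaling freedom that the cost models give losses, so that a preference for
the richer loss models cannot be an artifact of asymmetric flexibility.
Unchosen options are never updated, and no forgetting acts between
sessions. Only valid choices enter the likelihood; premature responses and
omissions are task events, not choices, and are excluded. Models are fit
to the first five sessions, the window in which outcomes have maximal
influence on choice and parameters are plausibly stationary.

## Hierarchical estimation

Subjects within a task group are partially pooled. On an unconstrained
scale each subject parameter is expressed noncentered,
$x_{sp} = \mu_p + \sigma_p z_{sp}$ with $z_{sp} \sim N(0,1)$, and mapped
to its natural range: learning rates through the standard-normal CDF,
$\beta$, $m$, $r$ and $mRew$ through $\exp$, the offset $b$ untouched.
Priors are weakly informative: $\mu_p \sim N(0, 1)$ ($N(0, 2)$ for $b$),
$\sigma_p \sim$ half-$N(0, 1)$. These defaults are deliberately
uncommitted: cohorts sampled from them span both optimal and
risk-preferring behavior, so no sign of the decision score is baked in.

### The sampler

Posterior draws come from an adaptive Metropolis-within-Gibbs scheme
written in C++:

* one block per subject updates $z_s$ jointly, with a proposal covariance
  adapted during warmup (the subject-level posterior has strong
  $\beta$/learning-rate ridges) and an occasional independence proposal
  from the prior that lets weakly identified subjects jump along flat
  directions;
* one block per parameter updates $(\mu_p, \log\sigma_p)$ jointly against
  the full likelihood;
* an interweaved *centered* step then holds every subject's unconstrained
  value $x_{sp}$ fixed — leaving the likelihood untouched — and redraws
  $\mu_p$ by its conjugate Gibbs update and $\sigma_p$ by a short random
  walk, after which the $z$ are recomputed. Alternating the two
  parameterizations decorrelates the group level from the subject deviates,
  which a purely noncentered random walk mixes very slowly.

Step sizes adapt only during warmup, so the retained chain is a valid
Markov chain at fixed tuning. Retained draws are thinned (default: keep
every 5th post-warmup sweep) so that the stored sample of
`n_chains * n_samples` draws carries less autocorrelation per draw; a
random-walk kernel needs this where a gradient-based sampler would not.
Convergence is assessed with split R-hat on every group- and
subject-level quantity; if any exceeds 1.01 the warmup doubles, to a cap
of 5000, and the fit is re-run. The outcome is recorded in the fit
(`converged`, `escalation`) and a failure warns rather than passing
silently.

Two presets are provided. The default is 4 chains of 1000 retained draws
after 1000 warmup iterations with the escalation policy above. The
`"desk"` preset (2 chains × 500, thin 3, no escalation) is for simulation
studies at laptop scale; it trades convergence certification for runtime
and leaves the `converged` flag to say so.

### Model comparison and contrasts

WAIC is computed from the pointwise log-likelihood over the posterior:
$\widehat{\mathrm{elpd}}_i = \log \tfrac1S \sum_s e^{\ell_{si}} -
\mathrm{Var}_s(\ell_{si})$, reported on the $-2\sum_i$ scale with a
pointwise standard error. Model comparisons are paired: the difference to
the `basic` baseline is summed over shared data points and its SEM comes
from the pointwise paired differences. Group differences in a parameter
are judged by the 95% highest-density interval of the difference of
group-level posterior draws on the natural scale; the difference is
credible when the interval excludes zero. No multiplicity correction is
applied across contrasts.

The fast non-Bayesian path, `fit_rgt_mle()`, maximises the same
likelihood per subject with L-BFGS-B from Latin-hypercube starts inside
documented bounds ($\eta \in [10^{-6}, 1-10^{-6}]$, $\beta \le 30$,
$m \le 2$, $r \le 3$, $|b| \le 20$), plus one "neutral" start at each
extra parameter's nesting value ($b=0$, $r=1$, $mRew=1$) so a richer model
always explores the region of the model it nests. It serves as an
independent cross-check of the posterior (subject-level rank orders agree)
and for large-n parameter recovery.

## The synthetic-data generator

`cohort_hypers()` + `sample_cohort_params()` + `generate_cohort_logs()`
produce cohorts of RL agents playing the simulated task, so that every
downstream stage — likelihoods, hierarchy, WAIC, contrasts, endpoint
statistics — is testable without any animal data. Group structure enters
exactly as the inference assumes: unconstrained group means and SDs, then
the same constraint transforms.

The default hyperparameters are the package's one-time calibration of
"a realistic task-naive cohort", chosen by forward-simulating candidates
and keeping the setting whose cohorts resemble the described rat data in
structure: group mean inverse temperature near 2, reward learning rate
near 0.10, punishment learning rate near 0.15, cost scaling near 0.1
pellets/s, power curvature near 0.65 and cost offset $b \sim N(8, 3)$.
Under these values cohorts show moderate positive mean decision scores,
wide individual spread including a risk-preferring minority, and higher
punishment learning rates produce more optimal acquisition — the
mechanism the models are asked to detect. The standard two-group recovery
design (`two_group_cohort()`) separates groups only in the punishment
learning rate, 0.15 vs 0.45 at the group level, with 12 subjects per
group and five 30-minute sessions.

The generator emulates: the reinforcement schedules; the session time
budget (risk-prone agents genuinely complete fewer trials, because long
time-outs consume the clock); cross-session value carryover; cue metadata
per task variant; premature responses and omissions as configurable
per-trial event probabilities. It does not emulate: cue-variant differences in
premature responding or latencies, satiety or motivation drift within a
session, side biases, or any within-subject parameter drift across
sessions. Tests passing on synthetic cohorts therefore certify the
machinery, not the biology: they show the pipeline recovers structure the
generator put in, under the generator's assumptions.

## Behavioral endpoints

`behavior_summary()` computes percent choice (valid choices only),
decision score, risk status (score above zero is optimal; exactly zero —
a measure-zero event in continuous data — is classified optimal by
convention), premature-response rate (denominator: all initiated trials),
omissions, trials completed and mean latencies. Percentages destined for
ANOVA can be arcsine-transformed ($\arcsin\sqrt{p/100}$) to blunt the
ceiling at 100%. `stable_window()` finds the latest k-session window
whose session effect is non-significant; the full repeated-measures
machinery with sphericity corrections is out of scope, so the stability
test is a randomized-block ANOVA (score ~ session + subject) at
$\alpha = 0.05$, and the window can always be fixed by hand instead.
One-way ANOVA uses the classical between/within mean-square ratio;
Tukey HSD reports row-minus-column mean differences with familywise
p-values from the studentized-range distribution, using Tukey–Kramer
standard errors for unequal group sizes.

## Numerical choices

* Softmax arguments $\beta Q$ are clipped at ±700 before exponentiation;
  overflow-free without altering any realistically reachable value.
* Update targets are clamped to ±10^6 inside the sampler so that extreme
  transient proposals (e.g. a huge power exponent making $T^r$ overflow)
  cannot make a Q-value non-finite; acceptance ratios guard against
  non-finite likelihoods by rejecting.
* The HDI uses the sorted-window algorithm: among all windows of
  $\lceil 0.95 n \rceil$ consecutive order statistics, the narrowest.
* Group contrasts with unequal draw counts truncate to the smaller count.
* The exponent in the exp-constraint is capped at 30 to avoid overflow on
  the natural scale.
* One master seed fans out per subject (`seed + subject index`), so
  subject streams are reproducible and independent; all C++ code draws
  from R's RNG, making every pipeline stage a pure function of the seed.

## Problem sizes used by the test-suite studies

The package's simulation studies (test suite and `scripts/acceptance.R`)
run at the desk scale the package defines for itself: two groups × 12
subjects × 5 sessions per replicate, the desk MCMC preset, 10 replicate
seeds in the suite and 5 in the acceptance script, and 40-session
forward simulations of 120 trials per session. These sizes were chosen as
the smallest at which the group-level questions are answerable;
`mcmc_config()` scales everything up to the full 4 × 1000 setting.

## Known limitations

* The punishment-learning-rate group effect is an *acquisition-phase*
  effect. At the 40-session horizon the simulated risk status of a cohort
  is dominated by where each subject's cost offset $b$ sits relative to
  the penalty scale $T^r$ (once $b > T^r$, losses teach attraction rather
  than avoidance, and a higher $\eta^-$ then amplifies risk seeking).
  Forward-simulation checks therefore compare estimate-driven simulations
  against truth-driven simulations over the same window, rather than
  assuming the early-session group ordering persists.
* The sampler is a random-walk scheme: it needs thinning and the
  interweaved centered step to mix, and subject-level quantities converge
  more slowly than group-level ones. Diagnostics are computed on
  everything and never suppressed.
* The abandoned independent-cost model (one free cost per option) is not
  implemented; at cohort sizes of 24–32 its parameters are not well
  isolated.
* Stay/perseveration dynamics, within-session satiety, and cue-driven
  modulation of premature responding are not modeled.
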