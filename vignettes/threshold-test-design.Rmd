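---
title: "Designing short olfactory threshold tests by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing short olfactory threshold tests by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfthresh)
```

## The measurement problem

Olfactory sensitivity is usually measured with a three-alternative
forced-choice (3AFC) dilution series: on each presentation the subject picks
the odorant pen (n-butanol in the standard Sniffin' Sticks series) out of
three, two of which are blank. Step 1 of the series is a 4% v/v solution and
each further step halves the concentration, so step 16 is about 1.22 ppm;
steps at or below 0 denote stronger pens (0 = 8%, −1 = 16%, −2 = 32%). The
gold-standard *staircase* procedure adapts the presented dilution to the
subject's performance and takes up to 20 minutes — infeasible in large
in-home surveys. The alternative, the *method of constant stimuli*, presents
a fixed set of dilutions to everyone and fits a model to the responses.

`olfthresh` implements the machinery needed to design and validate such
short tests: the 3AFC response model, simulators for both protocols,
marginal maximum-likelihood fitting with empirical-Bayes subject thresholds,
and a Monte-Carlo replication engine that estimates the reliability a
candidate protocol would achieve in a specified population.

## The response model

The probability that subject $i$ answers presentation $j$ (at dilution step
$d_{ij}$) correctly is

$$P(Y_{ij}=1) \;=\; \tfrac13 + \tfrac23\,
  \mathrm{logit}^{-1}(\alpha_i - \beta\, d_{ij}),$$

a logistic item-response curve with a guessing floor of 1/3 (three pens,
one target) and upper asymptote 1. $\alpha_i$ is the subject's olfactory
ability and $\beta > 0$ the common slope per dilution step. Setting the
probability to $2/3$ — halfway between floor and ceiling — defines the
subject's *threshold* $t_i = \alpha_i/\beta$ on the step scale. Abilities
are modelled as $\alpha_i \sim N(\mu_\alpha, \sigma^2_\alpha)$, making the
joint model a random-intercept logistic GLLAMM.

Two fitted populations ship as presets:

* `normosmic` — adults with normal olfaction: $\beta = 1.12$,
  $\mu_\alpha = 10.5$, $\sigma^2_\alpha = 16.6$, i.e. thresholds around step
  9.4 with SD 3.6. The presets store the unrounded quotients (10.5/1.12,
  $\sqrt{16.6}/1.12$) since the simulations are defined on the ability scale.
* `nshap_normal` / `nshap_gamma` — U.S. home-dwelling older adults
  (NSHAP Wave 2): thresholds with mean 2.4 and SD 3.0 at $\beta = 0.76$.
  The gamma version (shape 3.35, scale 1.61, location −3) keeps the same
  mean and SD but adds the positive skew expected when many subjects smell
  poorly, and places zero mass below step −3 (64% n-butanol).

```{r}
pop <- population_preset("nshap_gamma")
pop
round(cdf_threshold(pop, c(-1, -2, -3)), 2)  # tail fractions at strong pens
```

## Simulating the two protocols

`simulate_constant_stimuli()` draws one Bernoulli response per subject and
presentation. `simulate_staircase()` runs the adaptive rules: start at one
of the two weakest pens (15/16, chosen at random); a correct response is
confirmed by re-presenting the same step; two consecutive corrects move one
step weaker, any incorrect one step stronger; each change of movement
direction is a reversal; the run stops at 7 reversals and is scored as the
mean of the dilution steps at the last 4.

Three conventions are not fixed by the verbal rules, and we resolved them as
follows:

* **Reversal value.** We record the step being presented when the direction
  flips (the trajectory extremum). Recording the step moved *to*, or the
  midpoint, turns out to give numerically identical scores: the ±1 shifts
  cancel over the averaged last four reversals (two up-turns plus two
  down-turns).
* **Boundaries** (`clamp` argument of `staircase()`). The weakest listed
  step is always a hard ceiling — the test starts there, nothing weaker
  exists, and consequently no score can exceed it. For the strong end the
  default (`clamp = "ceiling"`) lets the simulated staircase continue below
  the strongest listed step. We validated this choice by reproducing the
  published simulated staircase reliabilities: with a clamped floor the
  older-adult (gamma-population) staircase reliability comes out near 0.36,
  well short of the published 0.41, because the third of that population
  with thresholds below step 1 all pile up against the floor; with the floor
  open the same simulation gives ≈ 0.41 while the normosmic result is
  unchanged. `clamp = "both"` reproduces the physical test exactly (a
  blocked move re-presents the same pen and is not a reversal) and is used
  in the boundary unit tests.
* **Termination safety.** `max_presentations` (default 60) guarantees
  termination for pathological response sequences; such runs are flagged
  censored and score from whatever reversals exist, falling back to the
  final step (so an always-correct run caps at the weakest step). Under the
  study populations fewer than 0.1% of runs hit the cap.

## Fitting and empirical Bayes

`fit_irt()` maximizes the marginal likelihood over
$(\beta, \mu_\alpha, \log \sigma_\alpha)$, integrating abilities out with a
Gauss–Hermite rule whose nodes span the population distribution. We chose a
fixed population-centred grid over per-subject adaptive centring because it
reduces each likelihood evaluation to two matrix products and lets one
3-parameter fit on 2,000 subjects finish in under a second; the price is
node density, so the default is 61 nodes, at which point further refinement
moves $\hat\beta$ by less than $10^{-4}$ (the package's quadrature is
checked against brute-force trapezoid integration to $10^{-6}$ in the test
suite). The optimizer receives the analytic score, which for this curve has
the compact form $\partial \log p/\partial\eta = 2s(1-s)/(1+2s)$ and
$\partial \log(1-p)/\partial\eta = -s$ with $s = \mathrm{logit}^{-1}(\eta)$.

Convergence is declared only for a finite interior solution whose scaled
gradient norm is below $10^{-5}\max(1, |\ell|)$ and whose observed
information inverts; variance collapses to the boundary and optimizer
failures are reported via the `converged` flag, never an error. Small
designs (6 items, 100 subjects) genuinely fail at an appreciable rate — the
data cannot always support the variance parameter — and the replication
engine reports that percentage while excluding failed replications from the
aggregates.

Subject thresholds are the empirical-Bayes posterior means
$\hat\alpha_i/\hat\beta$ under the fitted Normal prior. They are *shrunk*
toward the population mean — their variance is smaller than that of the
true thresholds, and the conditional bias grows toward the tails — but they
are unconditionally unbiased for the population mean, and as covariates in
downstream regressions they avoid the attenuation bias that error-prone
scores produce.

Survey administrations allow "don't know" and refusals;
`impute_responses()` replaces those records with Bernoulli(1/3) draws
(a forced guess is right one time in three), `m = 10` imputations by
default, and `pool_estimates()` combines fits by Rubin's rules and subject
thresholds by their mean across imputations (the combination rule for the
released survey thresholds is not documented; mean pooling is our default).

## The replication engine

`run_replications()` estimates a protocol's reliability for a population:
per replication it draws `n_subjects` true thresholds, administers the
protocol, estimates thresholds (empirical-Bayes IRT, or the last-4-reversal
score for the staircase), and records the Pearson correlation $r$ with the
truth. *Reliability* is $r^2$, averaged over replications — the mean of
squares, not the square of the mean, which is why a mean correlation of
0.75 pairs with a reported reliability slightly below $0.75^2$.
Replications are seeded from independent sub-streams of the master seed, so
results are reproducible and independent of execution order.

```{r, eval = FALSE}
rel <- run_replications(population_preset("normosmic"), constant_stimuli(1:16),
                        n_subjects = 100, n_reps = 500, seed = 1)
glance(rel)
autoplot(rel)
```

The problem sizes used in the package's own reproduction runs are the
published ones — 100 subjects × 500 replications for the normosmic designs,
2,000 subjects for the older-adult designs (100 replications there, where
the published standard errors of ≤ 0.001 show the mean is already stable at
a fraction of that) — and the test suite uses 100 replications with
correspondingly widened tolerances.

## What the simulations do and do not show

The generator draws i.i.d. thresholds and conditionally independent
Bernoulli responses from the fitted model. Real administrations add
day-to-day variation in subjects and administrators, pen depletion, possible
learning or habituation across presentations, and — among older adults —
truly anosmic subjects for whom no concentration raises the detection
probability. None of these are modelled: simulated reliabilities are
therefore best read as upper bounds that published test–retest studies
approach within a few hundredths. The model also assumes a single common
slope $\beta$; a population mixing normosmic and anosmic subjects
effectively flattens the curve, which is visible in the lower fitted slope
for older adults (0.76 vs 1.12). Extending the model with an anosmic
point-mass class would require more and stronger dilutions than the short
protocols administer.

## Numerical choices, summarised

* Concentrations are held as v/v fractions internally; percent and ppm are
  display conversions (`step_to_concentration()`).
* Steps are real-valued in the model; physical protocols use integers.
* Starting values: $\beta = 1$, $\mu$ from the pooled fraction correct
  inverted at the mean step, $\sigma = 1$. Box constraints keep
  $\beta \in [10^{-6}, 50]$ and $\sigma \in [10^{-4}, 50]$.
* Degenerate tables (all correct or all incorrect) are flagged without
  optimization; per-subject fits flag complete separation as non-estimable.
* Ties and censoring in the staircase: see the boundary discussion above.

## Limitations

Reliability here is a within-model quantity — correlation with *simulated*
truth — not test–retest agreement in humans. Convergence-failure rates are
optimizer-specific: this implementation fails far less often than the
software behind the originally published tables (e.g. 6% vs 24.6% for six
dilutions at n = 100), which slightly changes which replications enter the
aggregates but not, as both failure regimes show, the mean reliabilities.
The package deliberately stops short of classification (normosmia cutoffs,
sensitivity/specificity) and of mixture extensions for anosmia.
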