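# olfthresh

Design and reliability analysis of short olfactory threshold tests.

Psychophysical olfactory testing presents a subject with three pens — one
containing n-butanol at some dilution, two blank — and asks which smells.
Step 1 of the standard doubling-dilution series is 4% v/v; each +1 step
halves the concentration (step 16 ≈ 1.22 ppm; steps ≤ 0 are stronger pens).
The adaptive *staircase* procedure is accurate but takes up to 20 minutes,
which rules it out for in-home surveys. This package provides the modelling
and simulation machinery for designing *short* constant-stimuli protocols
(down to 6 dilutions) and quantifying, before any fieldwork, the
reliability they would achieve in a target population.

At its core is a 3AFC logistic item-response model with a guessing floor:

    P(correct) = 1/3 + 2/3 · logit⁻¹(αᵢ − β·d)

where `d` is the dilution step, `αᵢ` the subject's ability and `β` the slope
per step. A subject's *threshold* — the step where P(correct) = 2/3 — is
`αᵢ/β`. Abilities are random effects, `αᵢ ~ N(μ, σ²)`; the package fits this
model by marginal maximum likelihood (Gauss–Hermite quadrature, analytic
score), produces empirical-Bayes subject thresholds, handles survey
"don't know"/refused responses by multiple imputation at a 1/3 success
probability with Rubin pooling, simulates both staircase and
constant-stimuli administrations, and estimates protocol reliability
(mean squared correlation between estimated and true thresholds) by
Monte-Carlo replication.

## Worked example

Evaluate the 6-dilution in-home survey protocol (steps 6, 5, 4, 2, 1, 0,
i.e. 0.13% up to 8% n-butanol) for a population of older adults whose
thresholds follow a shifted gamma with mean 2.4 and SD 2.9 at slope 0.76:

```r
library(olfthresh)

pop <- population_preset("nshap_gamma")
pop
#> <olf_population> Shifted-gamma thresholds: shape 3.350, scale 1.610, location -3.000 (steps); beta = 0.760
#>   mean 2.394, sd 2.947

# analytic tail fractions: how much of the population needs very strong pens?
round(cdf_threshold(pop, c(-1, -2, -3)), 2)
#> [1] 0.09 0.01 0.00

rel <- run_replications(pop, protocol_preset("nshap"),
                        n_subjects = 2000, n_reps = 100, seed = 7)
rel
#> <olf_replication> 100 reps x 2000 subjects; estimator: irt_eb
#>   mean reliability 0.560 (SE 0.001); 5/50/95%: 0.534, 0.562, 0.583
#>   mean correlation 0.748; convergence failures 0.0%
```

A reliability of ≈ 0.56 means the short 5-minute protocol recovers 56% of
the true threshold variance in this population — close to the 0.65 the full
16-dilution series would achieve there, and *better* than the classically
scored staircase (≈ 0.41), whose early erroneous reversals inflate the
scores of poor smellers. Fitting and subject-level estimation on observed
data follow the same grammar:

```r
tab  <- read_responses("responses.csv")         # tokens 1 / 0 / DK / REF
imps <- impute_responses(tab, m = 10, seed = 1) # DK/REF -> Bernoulli(1/3)
fits <- lapply(imps, fit_irt)
ebs  <- mapply(empirical_bayes, fits, imps, SIMPLIFY = FALSE)
pool_estimates(fits, ebs)$parameters
```

A thin command-line wrapper ships in `inst/cli/olfthresh.R` with
subcommands `simulate`, `fit`, `evaluate`, `design` and `fixtures`, all
driven by a YAML run configuration that is re-serialized next to every
output for exact reproducibility.

## Package layout

- `R/dilution.R` — dilution-step scale and the 3AFC response curve
- `R/population.R` — population threshold distributions and presets
- `R/protocol.R`, `R/simulate.R` — protocol objects, constant-stimuli and
  staircase simulators
- `R/irt.R`, `R/missing.R` — marginal ML fit, empirical Bayes, imputation,
  Rubin pooling, sum scores
- `R/evaluation.R` — reliability, replication engine, method correlation,
  agreement summaries, protocol comparison tables
- `R/io.R`, `R/fixtures.R`, `R/plots.R` — response/config files, example
  data generators, ggplot2 methods
- `vignettes/threshold-test-design.Rmd` — the model, the simulation
  conventions and their rationale, and known limitations
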