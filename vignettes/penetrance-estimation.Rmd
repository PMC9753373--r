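---
title: "Estimating autosomal dominant penetrance from family disease states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating autosomal dominant penetrance from family disease states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penfam)
```

## The family disease-state model

`penfam` estimates the lifetime penetrance `f` of an autosomal dominant
variant from the distribution of the variant across family disease states in
population-scale data. The unit of modelling is a nuclear family in which
exactly one parent carries the variant (no de novo events, no homozygous
carriers). Each of `N` offspring inherits the variant with probability 1/2.
Carriers develop the phenotype with probability `f`; non-carriers with the
residual risk `g`, which absorbs phenocopies and disease of independent
aetiology. Counting affected members across the carrier parent, the other
parent and the sibs, the family is *unaffected* (none), *sporadic* (exactly
one) or *familial* (two or more), with closed-form probabilities implemented
in `state_probabilities()`. The *affected* state pools sporadic and
familial. Setting `g = 0` recovers the stricter model in which the variant
is necessary for disease.

Two views connect this model to data:

* **Forward**: given `(f, g, N)`, the expected rate of a designated state
  `X` among variant-harbouring families restricted to a set of modelled
  states (`expected_rate()`).
* **Inverse**: given an observed rate of `X`, recover `f`
  (`invert_rate()`, after `build_lookup()`).

The observed rate is assembled by `observed_rate()` from per-state variant
frequencies weighted by the familiality rate `P(F|A)` and, where the
unaffected or pooled affected state is involved, the lifetime risk `P(A)`.
Only five state combinations are coherent — `{F,S}`, `{F,U}`, `{S,U}`,
`{F,S,U}`, `{A,U}` — because the affected state is the union of familial and
sporadic. When the familial state is modelled its rate is the estimand;
otherwise the sporadic (or affected) rate is used, since that is the
informative proportion remaining.

## Parameters and defaults

| Parameter | Meaning | Units/range | Default |
|---|---|---|---|
| `f` | penetrance of the variant | probability | estimated |
| `g` | residual (non-carrier) risk | probability, `[0,1)` | derived by Bayes (`"auto"`) |
| `N` | average sibship size | offspring per family, real-valued | supplied (e.g. a Total Fertility Rate) |
| `P(F|A)` | familiality rate of the disease | probability | supplied |
| `P(A)` | lifetime disease risk | probability | supplied |
| `step` | lookup grid spacing | penetrance units | `1e-4` |
| `n_families` | families per calibration point | count | 50,000 |
| `calibration_grid` | true `f` values calibrated | `[0,1]` | step 0.02 |
| `max_degree` | error-polynomial cap | — | 3 |

`N` enters the closed forms as a real exponent, without rounding: sibship
size is supplied at population level as a Total Fertility Rate (e.g. 1.823
for East Asia and Pacific, 1.543 for the European Union in 2018) and the
formulas are smooth in `N`. The lookup grid step of `1e-4` (10,001 points)
is an order finer than the three decimals at which estimates are reported,
at negligible cost. The residual risk is derived as
`g = P(A)(1 − M_A)/(1 − P(M))` with `M_A` the familiality-weighted pooled
case frequency and `P(M)` the population variant frequency; for lifetime
risks of a few per mille (ALS) `g` is of order `0.002` and moves the
penetrance estimate by well under 0.01, while for more common traits
(lifetime risk 0.027–0.05 in the Parkinson's disease and pulmonary arterial
hypertension case studies) ignoring it inflates estimates appreciably.
Where a source states a lifetime risk as a fraction ("1 in 37", "1 in 20",
"1 in 400"), the bundled case studies store the exact fraction rather than
its printed decimal; at four-decimal reporting precision the difference is
visible in the derived `g`.

## Why a simulation-based correction, and what the simulator assumes

The lookup curve treats every family as having exactly `N` sibs. Actual
sibship sizes are non-negative integers distributed around that mean, and
the state probabilities are non-linear in sibship size, so the
population-level rate differs from the fixed-`N` rate — most starkly,
a family with no offspring can never present as familial when `g = 0`, which
depresses the familial rate below the fixed-`N` curve and makes the raw
inverse underestimate `f`.

`simulate_families()` therefore generates whole nuclear families: a sibship
size per family, carrier transmission per sib (probability 1/2), and
affection per member (`f` for carriers, `g` otherwise). Sibship sizes are
Poisson with the supplied mean by default. A count distribution whose mean
equals the supplied Total Fertility Rate is the natural population model
here, and it is what gives the correction its direction and size: with a
degenerate (fixed integer) distribution the simulation reproduces the
closed form and the fitted correction collapses to zero, a property the test
suite checks. Two alternatives are provided (`"fixed"`, and a floor/ceiling
`"mixture"` preserving the exact mean) for sensitivity analysis. One family
is sampled per record and the state is classified at family level;
proband-weighted ascertainment is deliberately not the default, matching
the one-person-per-family sampling assumption of the estimator.

`fit_error_model()` runs the simulator at each true `f` on the calibration
grid, inverts the simulated rate through the same lookup table the estimator
uses, and regresses the error (true minus estimated) on the estimate. The
defaults — 51 grid points, 50,000 families per point — keep the Monte-Carlo
standard error of each calibration point below about 0.005 while a full
calibration takes on the order of a second. The polynomial degree is chosen
among 1–3 by adjusted R² (the cap avoids boundary oscillation); if the
implied corrected estimate would not be monotone in the uncorrected one, the
next-best monotone degree is used instead, falling back to linear.
`adjust_estimate()` applies the predicted error additively and clamps to
`[0, 1]`.

What the simulator does **not** emulate: age-dependent onset (estimates are
lifetime point penetrances; sampling young cohorts in a case-only design
would bias states downward), multi-generation pedigrees, ascertainment of
families through multiple probands, de novo variants, and any correlation of
sibship size with disease state. Passing the recovery tests therefore shows
that the pipeline is internally consistent under its own sampling
assumptions, not that those assumptions hold in a given dataset.

## Error propagation

Per-state frequency standard errors (given directly, derived from counts as
binomial errors, or back-converted from reported 95% intervals via
`se_from_ci()`, i.e. `(M − M_lower)/1.96`) are propagated to the observed
rate by the first-order delta method, treating states as independent because
they are estimated in disjoint samples. The resulting normal interval is
clipped to `[0, 1]`, and both bounds are passed through inversion and bias
correction with the *same* lookup table and error model as the point
estimate — the bounds are alternative observed rates, not refitted
problems. Interval bounds that fall outside the range the rate curve can
attain (possible under sampling noise) are clamped to the nearest endpoint,
which is why published intervals can reach exactly 0 or 1.

## Numerical conventions

* At `f = 0, g = 0` with no unaffected state modelled all modelled
  probabilities vanish; the rate is defined by its one-sided limit (0 for
  the familial rate over `{F,S}`, 1 for the sporadic rate), keeping the
  lookup curve continuous at its boundary.
* The familial-probability complement is clamped at 0 when floating-point
  cancellation produces values in `(−1e-12, 0)`.
* Nearest-rate ties in the lookup break toward the lower penetrance
  (conservative reporting).
* Monotonicity of the rate curve is verified at table build; a non-monotone
  curve is an error rather than a silent misinversion.
* `onset_variability()` uses type-7 (linear interpolation) quartiles by
  default; the convention is configurable since published analyses rarely
  state theirs.

## Problem sizes used by the test suite

The distributional tests use 2×10⁵ families for goodness-of-fit against the
closed form, and the parameter-recovery check uses one default-sized
calibration (51 × 50,000 families) with five independent cohorts of 10⁵
families at each true penetrance in {0.2, 0.5, 0.8}, asking for recovery
within ±0.03 of the truth on the seed-averaged estimate. These sizes put
Monte-Carlo noise comfortably below the tolerances they are tested at.

## Known limitations

* Familiality is defined by first-degree relatives of a single sampled
  person; studies using extended-kinship definitions inflate the familial
  rate and hence the estimate (weighting by a first-degree `P(F|A)`
  mitigates but does not remove this).
* The method yields lifetime point penetrance, not an age-dependent curve.
* Covariance between per-state frequency estimates is assumed zero; if the
  same individuals inform several states the intervals will be too narrow.
* The family structure is fixed (two parents, `N` sibs); real pedigree
  variety is approximated, not enumerated.
* Estimates apply to the sampled population; penetrance may differ across
  ancestries, so inputs should be stratified (as the bundled case studies
  do for Asian and European ALS cohorts).
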