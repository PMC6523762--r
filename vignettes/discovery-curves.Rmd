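---
title: "Species discovery curves: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species discovery curves: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discurve)
```

## The problem

Taxonomic checklists record, for every described species, the year its
name was published and where it occurs. Two families of questions follow.
The first is descriptive: how many valid, extant species are known, per
family and per continental region, and at what rate are new species being
added? The second is predictive: if description effort continues on its
present trajectory, how many more species will be described by some
future year, and with what uncertainty? `discurve` implements both for
checklist-scale data, with the global stonefly (Plecoptera) fauna — about
3,700 valid extant species through 2018 — as its reference case.

## From raw checklist to analysis-ready species list

Raw nomenclatural checklists mix valid species with synonyms, homonyms,
fossils and subspecies. `normalize_checklist()` reduces them to the unit
the analysis counts — the distinct valid extant species — with these
rules:

* synonyms and homonyms are dropped; only valid names are counted;
* fossil taxa are dropped;
* each subspecies is collapsed into its parent species. The parent keeps
  the **earliest** description year among itself and its subspecies, and
  the **union** of their occurrence regions. The earliest-year rule dates
  the species' discovery at the first time any of its forms was named;
  the union rule records everywhere the species is known to occur. A
  subspecies with no parent record present is promoted to species level
  (with a warning) rather than silently discarded;
* remaining duplicate names merge by the same earliest-year/union rule;
* records sort canonically by family, then name, so downstream outputs
  are order-independent.

Every dropped or merged record is tallied in a drop log — regional
checklist curation involves judgement calls about type data, and an
explicit audit trail of what was excluded is part of the method.

Occurrence is encoded against the hierarchical TDWG world geographical
scheme (continental Level-1 regions subdividing down to political units),
so a record known only from, say, Ontario still contributes a North
America presence: `presence_matrix()` walks each code up the hierarchy to
the requested level. Richness tabulation (`richness_by_family()`) then
counts species per family, globally and per region. Because a species can
occupy several regions, a family's global count is at most — and usually
less than — the sum of its regional counts; totals are always recomputed
from the cells, never stored.

Regional *description-rate* checklists use a stricter membership rule
than occurrence: a species is credited to the region of its type locality
(`described_from`), or to a country tag for country-level subsets such as
China. Without this rule a widespread species would inflate several
regional rates at once. Records lacking type-locality data are excluded
from regional rate checklists and counted in the drop log; occurrence
gives no trustworthy substitute, precisely because widespread species
occur in regions they were not described from.

## Description rates

`rate_table()` counts species described in a window with **inclusive
endpoint years** and divides by the **window span** `end − start`: the
1980–2018 window spans 38 years. Both conventions follow the published
stonefly rate tabulations this package reproduces (1657 species globally
in that window, 1657/38 = 43.6 species/yr). Rates are rounded half-up to
one decimal for display only; full precision is kept internally.

## The NHRP discovery model

Annual description counts are modelled by a non-homogeneous renewal
process whose expected cumulative curve is logistic:

$$\Lambda(t) = \frac{N}{1 + e^{-v_1 (t - v_2)}}$$

* `N` — the asymptotic number of species that will ever be described
  (species); the quantity of scientific interest.
* `v1` — curve steepness (1/yr); the peak description rate is
  `N v1 / 4`, attained at the inflection.
* `v2` — the inflection year, at which exactly `N/2` species have been
  described.

The logistic shape encodes the standard discovery narrative: slow early
description, acceleration as collections and workers multiply, and
eventual saturation as undescribed species become rare.

### Likelihood

Description dates are known only to the year, so the process is fitted at
annual resolution: the count for calendar year `t` (the bin `[t, t+1)`)
has mean `μ(t) = Λ(t+1) − Λ(t)`. Counts are Poisson when the dispersion
`phi = 1`; with `estimate_dispersion = TRUE` they are negative binomial
with variance `phi·μ` (size `μ/(phi−1)`), which supplies the
extra-Poisson "random variability" that real description series show —
monographs and revisions land in bursts, and effort fluctuates with
funding and researcher availability. This binned count likelihood is the
standard, testable formulation of a non-homogeneous counting process at
yearly resolution.

### Fitting

`fit_nhrp()` maximizes the likelihood with bounded quasi-Newton steps
(L-BFGS-B on the `(log N, log v1, v2)` scale) from a deterministic
multi-start grid — `N` at 1/2/4/8 times the observed total, `v2` at the
first, middle and last observed year, `v1` at 0.01/0.05/0.1 — so repeated
fits of the same data are identical without a stochastic global
optimizer. Parameter boxes keep the fit identifiable on right-censored
curves (series still far from saturation): `N` in `[observed total,
100×]`, `v1` in `(0, 1]`, `v2` within 200 years before the first and 300
after the last observation. A flat series (all counts equal) leaves the
curve's shape unidentified and is returned as `converged = FALSE` with a
diagnostic, as is failure of every start; predictions refuse
non-converged fits rather than extrapolating from them.

Time-translation equivariance is a useful sanity property of this design:
shifting all years by +100 shifts `v2` by exactly +100 and leaves `N` and
`v1` unchanged, because the starts and bounds shift with the data.

### Prediction

`predict_new_species()` forward-simulates the fitted process from the
year after the last observation out to the farthest horizon, `n_reps`
times, and reports the median, mean and central 95% interval
(2.5th–97.5th percentiles) of the total newly described species at each
horizon. Two design choices matter:

* **Shared replicate streams.** Each replicate simulates one path to the
  farthest horizon; every horizon is read off that same path's cumulative
  sum. Predictions to 2100 therefore dominate predictions to 2050
  replicate by replicate, not just in distribution.
* **Parameter uncertainty.** By default intervals carry process noise
  only. With `propagate_param_uncertainty = TRUE`, each replicate first
  re-draws the parameters from the fit's curvature-based Gaussian
  approximation on the `(log N, log v1, v2)` scale (clamped to the fit
  bounds). The log scale matters: on right-censored curves the sampling
  distribution of `N` is strongly right-skewed, and a natural-scale
  Gaussian materially under-covers. For series still far from
  saturation, parameter uncertainty dominates the interval width and the
  propagated interval is the honest one; both are available and labelled.

Every stochastic operation takes an explicit seed, and replicate `r` uses
an independently derived substream, so outputs are byte-reproducible
end to end.

### Diagnostics

`goodness_of_fit()` returns per-year Pearson residuals
`(k − μ)/√(φμ)`, a dispersion statistic (mean squared Pearson residual
adjusted for the 3–4 fitted parameters; near 1 under the model), the
longest same-sign residual run (a long run flags a systematic trend
break, such as a step change in description effort), and observed versus
fitted cumulative curves for plotting with `plot_discovery_curve()`.
Discovery-curve extrapolation is known to be fragile while rates are
still rising; the diagnostics exist so that fragility is visible rather
than hidden.

## The synthetic-data generator

`generate_world()` produces per-region checklists with the statistical
structure the pipeline assumes: description years drawn along each
region's logistic curve, family composition by exact (largest-remainder)
proportions, `described_from` set to the generating region, and optional
multi-region occupancy. Two year-placement modes exist because two uses
exist:

* *stochastic* — the region's curve is rescaled so its expected in-window
  total equals the budget, then counts are drawn through
  `simulate_descriptions()`; realized totals vary, as real data would;
* *deterministic* — exactly `budget` years are allocated by
  largest-remainder against the logistic increments, for fixtures whose
  counts must be exact.

`fixture_checklists()` ships two deterministic reference fixtures built
from packaged count tables for the global stonefly fauna through 2018:
the family-by-region richness structure (3718 species) and the per-area
1980–2018 description counts (1657 globally). The species names in both
are synthetic; only the count structure is real. The per-area rate
checklists are constructed independently per area, mirroring the
separately curated regional reference checklists the published counts
came from (the published regional counts slightly exceed a strict
partition of the global pool, so they cannot all arise as filters of one
list).

What the generator deliberately does **not** emulate: authorship and
nomenclatural history, temporally autocorrelated effort (wars,
monographic bursts) beyond what `phi` captures, taxonomic concept change,
or spatially structured sampling. Passing tests on synthetic worlds
therefore demonstrate that the estimator recovers the truth *when the
model is true* and that intervals mean what they claim under the stated
noise; they cannot certify forecasts for a real fauna whose effort
process drifts.

## Numerical choices

* `plogis`/`dlogis` evaluate the curve and intensity stably at extreme
  arguments; annual means are floored at 1e-12 inside the likelihood.
* Non-finite likelihood values are treated as rejected points by the
  optimizer rather than propagating.
* Rate display rounds half-up (0.05 → 0.1); base R's banker's rounding
  would disagree with published tables at exact halves.
* Largest-remainder allocation breaks remainder ties by position,
  deterministically.
* The curvature covariance is obtained from a numerical Hessian at the
  optimum; when it is not positive definite (near-flat directions on
  heavily censored series) it is reported as absent and
  parameter-uncertainty propagation refuses, rather than sampling from a
  degenerate Gaussian.

## Verification problem sizes

The test suite verifies the model's statistical guarantees at these
sizes, chosen to give tight Monte-Carlo error while keeping a full run in
the low minutes: parameter recovery over 50 seeded replicates of a
169-year right-censored series (truth `N = 4000`, `v1 = 0.04`,
`v2 = 2020`, Poisson) — median fitted `N` and `v1` within 15%, `v2`
within 5 years; 95% interval coverage over 100 synthetic worlds at the
2050 horizon with 400 forward replicates each (≥ 88/100 expected, within
binomial noise of nominal); a grid-search oracle of ~5,000 points that
the optimizer must never fall below; and noiseless fixtures where
predictions must match the analytic logistic increment to 0.5%.

## Limitations

* The model assumes one smooth logistic effort trajectory; real
  description histories contain wars, monographic bursts and database
  backfills that violate it. The dispersion parameter absorbs some of
  this; the residual-run diagnostic flags the rest.
* On series far from saturation, `N` is weakly identified: intervals on
  long-horizon predictions are wide and strongly right-skewed, and point
  estimates of `N` should not be read as firm asymptotic richness.
* Interval calibration is demonstrated under the generating model, not
  under model misspecification.
* The checklist normalizer resolves subspecies by name structure
  (trinomials under their binomial); it performs no nomenclatural acts —
  synonymies and homonymies are taken as given by the source checklist.
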