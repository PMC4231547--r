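---
title: "Methods: synthetic estimation of local GP demand and its confrontation with supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic estimation of local GP demand and its confrontation with supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careplan)
```

## The problem

Health-workforce planners need to know, for every neighbourhood-sized area,
whether the local supply of general practitioner (GP) care matches the care
the local population can be expected to demand. Direct utilisation data
exist only for the areas covered by sample-based GP registration networks;
for all other areas demand must be *estimated*. `careplan` implements the
classical two-stage synthetic estimation used for this purpose, the
confrontation of the resulting demand estimates with registered GP supply,
and a surroundings analysis that lets neighbouring oversupply compensate
local undersupply.

## The demand model

The unit of analysis is the listed patient. Annual GP contact counts are
converted to consultation time by 10 minutes per contact (the average length
of a GP consultation), and regressed by ordinary least squares on

* a female dummy (male = reference),
* six age-band dummies for 0–4, 5–14, 15–24, 40–64, 65–74 and 75+ years
  (25–39 = reference),
* three area proportions attached to each patient as contextual covariates:
  non-Western immigrants, one-person households, and persons in low-income
  households (all in [0, 1]),
* four urbanisation dummies for categories 2–5 of the five-level address
  density classification (1 = rural = reference).

For patient $i$ in area $a$:

$$y_{ia} = \beta_0 + \beta_F F_i + \sum_k \beta_k A_{ik}
  + \gamma_1 p^{nw}_a + \gamma_2 p^{1p}_a + \gamma_3 p^{li}_a
  + \sum_u \delta_u U_{au} + \varepsilon_{ia}.$$

Individual-level GP utilisation is dominated by unobserved variation, so the
explained variance is small by construction: the packaged national
coefficient set ([`dutch_gp_coefficients()`]) carries $R^2 = 0.129$ at
roughly 270,000 patients. The coefficients, not the $R^2$, are what the
method uses.

In the second stage the fitted coefficients are projected onto the census
composition of every area: each coefficient is multiplied by the number of
inhabitants carrying its predictor (counts for the demographic dummies;
population times the proportion for contextual covariates), yielding total
expected consultation minutes and a per-inhabitant rate. Because the model
is linear and additive, this projection is *exactly* the sum of individual
predictions over any roster of inhabitants matching the area's margins —
the package tests enforce this roster-expansion identity to $10^{-6}$
minutes. Gender and age margins are used independently; the additive model
needs no cross-tabulated counts.

Estimates for areas under 1,000 inhabitants are considered unreliable and
are flagged by `apply_population_filter()` (boundary: 999 excluded, 1,000
included); they stay in the data but are suppressed in reports.

Negative predictions are meaningless demand and are floored at zero — with
a warning and a count, never silently. Under the packaged coefficient set
the smallest achievable individual prediction is +0.13 min/year, so the
floor exists as a guard for user-supplied coefficient sets rather than as an
active correction.

Confidence intervals are classical OLS Wald/t intervals. Hierarchical or
count-model refinements (the outcome is, after all, a contact count) are
deliberately out of scope; the linear model on the minutes scale is the
method being implemented. Fitting on contacts and rescaling by 10 is
algebraically identical and exposed via `outcome = "contacts"`.

## The confrontation

One full-time-equivalent (FTE) GP is defined to carry the *norm workload*:
the norm list size times the mean annual consultation time per patient,
`norm_workload(2350, 31.8)` = 74,730 minutes per year by Dutch norms. Two
indicators are computed per area:

1. **workload per FTE** = estimated demand minutes / FTE supply (undefined
   where the area has no GP — reported with a `"No GP"` sentinel, never as a
   number);
2. **FTE balance** = FTE supply − demand minutes / norm minutes (positive =
   surplus), with the percentage balance 100 × balance / needed.

Workload bands for reporting are half-open $[lo, hi)$ intervals
(8,000–50,000; 50,000–100,000; 100,000–150,000; 150,000–300,000;
300,000–500,000): printed band tables traditionally repeat the shared
endpoint in adjacent rows, so the convention is stated here and is
configurable. A positive workload below 8,000 min falls in `"Other"`.
Residents-class summaries use the eight half-open classes from 1,000–2,500
up to >30,000 inhabitants and report *unweighted means across areas*; the
mean percentage balance is the mean of per-area percentages (areas whose
needed FTE is zero are excluded from that mean and counted).

## The surroundings analysis

Patients do not necessarily see a GP in their own area, so each area is
also evaluated pooled with its surroundings: all areas within a radius,
threshold **inclusive** (a pair at exactly the radius is a neighbour), self
always included. The default radius of 3 km reflects the typical distance
between a patient's area and their GP practice (mean about 2.7 km, rounded
up because distances are measured between area centres). Per focal area the
neighbourhood's demand minutes and FTE are summed and the confrontation
recomputed; the result is attributed to the focal area. Neighbourhoods
overlap by construction, so pooled results are deliberately not additive
across areas — only the radius-0 (own-area) and saturation (national ratio)
limits are conservative, and both are asserted in the test suite.
`compensation_report()` quantifies how many shortage areas pooling clears.

Distances are consumed from a user-supplied matrix when available (allowing
true road distances); otherwise straight-line distances between centroids
are computed. Euclidean distance understates road distance, so synthetic
catchments are slightly generous — a documented divergence. Per-area radii
(e.g. urban vs rural) are supported through `per_area_radius`.

## The synthetic country

All four restricted inputs — patient registration records, area census
profiles, GP supply, and geography — are emulated by seeded generators, so
every stage of the pipeline is testable end to end.

**Geography.** Default 400 areas with populations uniform on [200, 11,342]
(mean 5,771, the national postcode-area average; the lower tail yields areas
below the 1,000-inhabitant filter). Centroids are uniform on a 60 × 60 km
box, matching the areal density at which a 3 km radius captures a realistic
handful of neighbours.

**Profiles.** Female share uniform on [0.49, 0.52]; age-band shares drawn
from a Dirichlet around the national 2008 margins (5.8 / 12.0 / 12.2 / 19.9
/ 35.4 / 8.1 / 6.6 %) with concentration 150; the three proportions from
beta distributions with means 0.10, 0.36 and 0.09; urbanisation sampled with
probabilities (0.25, 0.20, 0.20, 0.20, 0.15). Age-band counts are
apportioned by largest remainder so they sum *exactly* to the population.
Margins are simulated independently across characteristics — real areas
correlate them (e.g. urbanisation with immigrant share), which the
generator does not emulate, so passing tests demonstrate correctness of the
computation, not realism of joint area composition.

**Patients.** Each area's roster is expanded exactly to its marginal counts
(gender and age assigned independently), an optional fraction is sampled
(registration networks cover a sample of practices; the pipeline default of
0.12 yields about 270,000 patients on the default country), and minutes are
simulated as the ground-truth linear predictor plus Gaussian noise. The
default residual SD of 43.4 min/year was calibrated once from the variance
of the linear predictor under the default composition (279.4 min²) so that
the fitted model explains about 12.9% of the outcome variance. With
`rounding = TRUE` the outcome becomes nonnegative integer contacts × 10, as
in real registration data; recovery studies run with rounding off because
the truncation at zero biases coefficients downward — with rounding off the
Gaussian outcome is left untruncated (occasionally negative) precisely so
that least-squares recovery is exactly unbiased.

**Supply.** Area FTE is population / 2,350 perturbed by multiplicative
Gaussian noise (dispersion 0.3, floored at zero). A quarter of areas host
no practice (the share of no-GP postcode areas in national data); each such
area's notional supply moves to its *nearest* hosting area, because people
register with the practice closest to home, often in an adjacent area. This
conserves the national FTE stock at population/2,350, so the synthetic
country is near balance nationally while supply and demand are locally
mismatched — the regime the decision tool is designed to expose. Under
these defaults the pipeline reproduces the qualitative national pattern:
roughly half the areas in shortage on their own footprint, a substantially
smaller share after 3 km pooling, and a small national surplus.

## Validation design

* **Zero-noise exactness**: with residual SD 0 the fit recovers the truth to
  numerical precision (asserted at $10^{-9}$).
* **Stochastic recovery**: 20 replicates of ~270,000 patients (100 areas ×
  ~2,700 inhabitants) under the packaged truth. The 95% Wald intervals must
  cover the true gender and elderly-age coefficients in at least 90% of
  coefficient × replicate draws. Coverage events are pooled across the
  three monitored coefficients because that estimator of the (nominally
  95%) coverage rate is the one whose Monte Carlo error at 20 replicates
  does not condemn a correct implementation: requiring all three
  coefficients jointly per replicate has expected rate $0.95^3 = 85.7\%$
  and would fail in expectation. Unbiasedness is asserted separately
  (replicate-mean of each coefficient within 1% of truth).
* **Oracles**: roster expansion against `predict_individual()`; brute-force
  neighbourhood sums on 1–6-area fixtures; conservation of the national
  balance $\sum(\mathrm{FTE} - \mathrm{need})$ to $10^{-9}$.
* **Problem sizes**: unit and property tests run on countries of 20–60
  areas; the recovery study and the acceptance script use the
  registration-data scale of ~270,000 patients. These sizes are the
  package's own choice of test conditions.

## Known limitations

* Point projection only: no uncertainty is propagated into area estimates.
* Straight-line distances in the synthetic geography; no road network.
* Supply pooling attributes each GP's capacity to every focal area whose
  neighbourhood contains it (independent pooling per focal area); no
  exclusive allocation of capacity is attempted.
* No induced-demand feedback (supply influencing utilisation), no
  education/lifestyle covariates (not available by area), no future-demand
  projection.
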