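---
title: "Methods: dose, DRL and risk modelling in cathdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose, DRL and risk modelling in cathdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathdose)
```

## The problem

Paediatric cardiac catheterization delivers some of the highest imaging
doses in childhood, to patients who vary in weight by two orders of
magnitude and who often return for repeat procedures. Three questions
drive the package design: (i) which easily-recorded exposure quantity
makes a stable local diagnostic reference level (DRL) across such a
heterogeneous caseload; (ii) how to turn the machine-reported dose-area
product (DAP) into organ and effective doses without running a Monte Carlo
simulation for every event; and (iii) how to express those organ doses as
lifetime attributable risk (LAR) of cancer.

## Units and canonical quantities

All DAP values are carried internally in cGy·cm² and air kerma in mGy;
`convert_dap()` handles the unit dialects of dose-management exports
(Gy·m², µGy·m², Gy·cm², mGy·cm²). Fluoroscopy time is stored in seconds
and converted to minutes only where `DAP_BWxFT` is formed — a single,
tested conversion point, like the division by 100 that turns
cGy·cm²·kg⁻¹ into the Gy·cm²·kg⁻¹ scale on which conversion factors are
defined. Events with `DAP = 0` are kept (a short burst can round to zero)
and contribute zero to every sum.

## DRL statistics

A DRL here is the 75th percentile of a per-procedure distribution, with
quartiles computed by linear interpolation between order statistics at
rank `h = (n−1)p + 1` (R's type 7, the default of most statistics
software). At the small per-procedure-type samples of a single centre the
percentile convention visibly moves P75, so the type is an argument of
every table builder and is recorded in the table's attributes and in the
pipeline manifest. Two weight-normalized parameters are computed:
`DAP_BW` (cGy·cm²·kg⁻¹) and `DAP_BWxFT` (cGy·cm²·kg⁻¹·min⁻¹). Procedures
without fluoroscopy have no defined `DAP_BWxFT`; they are excluded from
that distribution (not zeroed) and alerting falls back to `DAP_BW`.
Weight groups follow RP 185 as half-open intervals `[lo, hi)` — 15.0 kg
falls in `15–<30` — with `≥80` kg collecting adolescents and the adult
congenital patients. Groups with fewer than 20 procedures carry a
small-sample flag, reflecting the RP 185 minimum for fluoroscopy-guided
procedure types. Alerts use strict exceedance: a DRL is a threshold for
review, not a limit, and equality does not trigger.

## Group comparison and dispersion

Differences in the DRL parameter across procedure types are tested with a
Kruskal–Wallis H test (tie-corrected, `stats::kruskal.test`) followed by
Dunn's pairwise z tests on mean ranks with the tie-corrected variance and
Bonferroni adjustment over all `k(k−1)/2` pairs; with nine procedure
types that is 36 comparisons. The significance threshold defaults to
α = 0.05. The dispersion diagnostic CI95/med — the width of the 95%
confidence interval of the median as a percentage of the median — is
built by a seeded percentile bootstrap (B = 2000 by default); a
construction had to be chosen, and the bootstrap makes no distributional
assumption while agreeing with the binomial order-statistic interval at
large n (this agreement is itself a test).

## Conversion-factor dose engine

Organ and effective doses are linear in weight-normalized DAP:
`dose (mGy) = CF × DAP_BW (Gy·cm²·kg⁻¹)`. The shipped table carries, per
target (12 organs + effective dose) and per RP 185 weight group, three
plane variants: `biplane` (one factor on the cumulative DAP of the
procedure), and `frontal`/`lateral` factors applied to each C-arm's DAP
share and summed — the more accurate route on a biplane system, since
lateral projections traverse different anatomy. Patients above the
table's range use the `≥80` kg group.

`derive_cf_table()` rebuilds such a table from any cohort with reference
doses (Monte Carlo output, or the synthetic generator's ground truth): an
ordinary least-squares fit of dose on `DAP_BW` per (target, plane, weight
group), fitted *with* an intercept while only the slope is reported, plus
a through-origin mode for the strict `dose = CF × DAP_BW` reading.
Lateral fits include only procedures with nonzero lateral DAP, so their n
is smaller on a partly monoplane cohort; cells with fewer than 3
procedures are omitted.

One numerical choice deserves emphasis: within a weight group the
regressor is strongly right-skewed and dose residuals grow with DAP, so
the classical homoscedastic slope CI is badly anti-conservative — in
seeded simulations under multiplicative log-normal dose noise its
coverage fell far below nominal. `derive_cf_table()` therefore defaults
to heteroscedasticity-consistent HC4 sandwich standard errors, which are
designed for exactly the high-leverage points a skewed regressor
produces and restored near-nominal coverage in the same simulations;
`fit_linear(robust = FALSE)` gives the classical interval when
comparability with standard statistics-package output is wanted.

Effective dose is either `CF_ED × DAP_BW` directly, or the ICRP
tissue-weighted sum `ED = Σ w_T H_T` over organ doses
(`effective_dose_from_organ_doses()`), with ICRP 103 weights by default
and ICRP 60 available for comparison with older literature. The phantom
organ set carries no testes dose, so the gonads weight is applied to the
ovaries dose; absent tissues contribute zero with a warning.

## Phantom geometry and FSD

Dose-simulation jobs need the focal-spot-to-entrance-skin distance (FSD)
for each event. The model: a reference hermaphrodite mathematical phantom
is selected by nearest nominal age (classes newborn, 1, 5, 10, 15 years,
adult; ties go to the older class; the adult class is given nominal age
20 for the nearest-age rule) and scaled to the patient —
`scale_height = height/href`, and the transverse factor
`sqrt((weight/wref)/scale_height)` so that mass is conserved under
uniform density. The trunk at heart level is an elliptical cylinder (the
standard mathematical-phantom trunk shape, and the choice that makes FSD
closed-form testable); the heart is assumed at the C-arm isocenter, by
default on the trunk axis (the offset is configurable — the assumption
concerns where the isocenter is, not where the heart sits in a body).
The central ray from the heart toward the focal spot crosses the trunk
surface at distance d, obtained from the ray–ellipse quadratic in the
transverse plane and divided by `cos(secondary_angle)` — the trunk
surface is treated as invariant along the cranio-caudal axis, a
documented cylinder approximation that is exact at zero angulation and
mild (<15% path error) at the ±30° angulations typical of cardiac work.
Then `FSD = SAD − d`. Angle signs follow the interventional convention
RAO−/LAO+ and CAU−/CRA+. Degenerate poses fail loudly: a heart offset
outside the trunk raises "no skin entry", and near-axial secondary
angulation (cos ≤ 0) is rejected rather than extrapolated. The closed
form is verified against a numeric bisection oracle on the same surface
to below 0.1 mm over a grid of angles and semi-axes.

Reference dimensions (heights, weights, trunk semi-axes per age class)
ship as an editable CSV (`phantom_reference.csv`) following the published
age-scaled phantom series; they are configuration, not hard-coded
constants, and no dose result in the package depends on them (doses flow
through conversion factors; the geometry module serves job preparation).

## BEIR VII risk

LAR coefficients (cases or deaths per 100,000 persons per 0.1 Gy, native
DDREF 1.5) are shipped as a CSV transcription of the BEIR VII Phase 2
incidence and mortality tables on the report's age-at-exposure grid
(0, 5, ..., 30, 40, ..., 80 y). Between grid ages the coefficient is
interpolated linearly — the grid is coarse relative to a paediatric age
distribution — and ages beyond the grid clamp to the nearest endpoint;
grid and method are visible in the fixture and echoed by
`risk_coefficient()`. The dose scaling is linear:
`LAR = (dose_Gy/0.1) × coefficient × (1.5/DDREF)` with DDREF ∈ {1.5, 2},
so the DDREF-2 value is exactly 0.75 of the DDREF-1.5 value before any
rounding. Rounding to whole cases per 100,000 happens only at report
formatting (`lar_report_chain()`), which rounds at each reported step as
risk figures are conventionally quoted; analysis values stay unrounded.
A site map is the single authority on which organ drives which cancer
site (lungs→lung, active bone marrow→leukaemia, remainder→other solid,
breast/ovary female-only, ...); the mortality table carries no thyroid
row, so thyroid contributes to incidence totals only. Because every
report states its DDREF, totals computed at 1.5 (for comparison with
older literature) and at 2 (ICRP-recommended) cannot be confused.

## The synthetic cohort generator

`generate_cohort()` draws the study conditions the analysis assumes: 222
procedures by default, a nine-type caseload mix (diagnostic plus eight
interventional types in proportions 33/33/17/18/43/34/13/7/14), a
log-normal age distribution with median 4.3 y and sdlog 1.9 (quartiles
roughly 0.9–15.6 y) truncated to 2 days–70 years, piecewise-linear growth
curves for weight and height with multiplicative noise (sdlog 0.13 and
0.04), and the dose model `DAP = k_type × BW × FT_min × e^ε` with
ε ~ N(0, 0.8²) — an order-of-magnitude spread, as procedure dose
distributions show. The per-type constants `k_type` are back-solved from
target 75th percentiles of `DAP_BWxFT` (so the pooled P75 lands near
2 cGy·cm²·kg⁻¹·min⁻¹); because the noise is log-normal the per-type P75
is exactly `k_type · e^{0.6745 σ}`, which gives the tests an analytic
oracle. Fluoroscopy's median share of DAP is 0.91 for interventional and
0.77 for diagnostic procedures (logit-normal, so the median is exact);
biplane usage probabilities are 0.73 and 0.85. Event streams (mean 63
events per procedure) split each procedure's DAP across modality × plane
buckets with gamma weights and carry full geometry, so the emitted table
passes validation with zero exclusions. Ground-truth doses are computed
from the configured conversion-factor table per estimation route;
`attach_reference_doses()` multiplies them by seeded log-normal noise for
recovery studies.

What the generator does *not* emulate: real per-event kVp/filtration
physics, demographic growth references, operator learning effects, or the
correlation structure between complexity and patient size within a
procedure type. Passing tests therefore demonstrate that the pipeline's
arithmetic, statistics and recovery behaviour are correct under the
stated model — not that any particular clinical cohort will reproduce the
shipped table values.

## Problem sizes and determinism

Every stochastic component takes an explicit seed (`withr::with_seed`
internally, so the global RNG state is untouched) and identical
configurations produce byte-identical outputs. The test suite uses
cohorts of 10–500 procedures; the conversion-factor recovery study runs
100 replicates of 400-procedure cohorts at summary level (event streams
skipped), and the geometry oracle sweeps ~600 angle/axis combinations —
sizes chosen to give stable Monte-Carlo estimates while keeping a full
test run under a minute of statistics work.

## Known limitations

- Conversion factors are cohort- and equipment-specific; the shipped
  table derives from a single biplane lab and should be replaced via
  `derive_cf_table()` where local Monte Carlo results exist.
- The FSD model ignores table position and arm-raised/lowered posture;
  jobs carry the raw pose so a future engine can refine it.
- LAR applies population-average coefficients to an individual's organ
  doses; it describes a theoretical population like the patient, not the
  patient, and the package's reports keep per-site values and DDREF
  visible for exactly that reason.
- The BEIR VII fixture is a transcription; users should verify it against
  the public report before regulatory use (`beir_coefficients(path=)`
  accepts a replacement).
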