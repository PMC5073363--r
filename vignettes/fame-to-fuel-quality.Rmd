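---
title: "From FAME profiles to biodiesel quality: models, coefficients and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From FAME profiles to biodiesel quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fameprop)
```

## Scope and model

`fameprop` predicts the composition-driven quality parameters of a
biodiesel (B100) from its fatty acid methyl ester profile and checks
the full property set against the EN 14214 and ASTM D6751
specifications. The profile is a composition: abundances are stored as
percentages of total FAME and every property model is linear in them,
so all predictions commute with blending (the property of a 50/50
blend of two profiles is the mean of their properties). Species
identity keys on `(carbons, double_bonds)` only; the omega position in
labels such as `C20:5n-3` is retained as metadata but does not split
species, because none of the property models distinguishes double-bond
position.

Three empirical models are implemented:

* **Cetane number** — the mixture CN is the abundance-weighted mean of
  neat per-ester cetane numbers, `CN_mix = Σ(A_c·CN_c)/Σ(A_c)`. The
  denominator uses the actual abundance sum rather than assuming 100,
  so slightly unnormalized input degrades gracefully. The estimate is
  necessarily bounded by the smallest and largest per-ester CN present.
* **Iodine value** — `IV = Σ A_c·f_c` with per-ester factors in the
  EN 14214 calculated-IV convention. The factors follow from halogen
  addition across each double bond: `f_c = 253.81·db/MW_c`, where
  253.81 g/mol is two atomic iodines and `MW_c` the methyl-ester
  molecular weight from its formula C(x+1)H(2x+2−2y)O2.
* **Cold flow** — the long-chain saturated factor
  `LCSF = 0.1·%C16:0 + 0.5·%C18:0 + 1·%C20:0 + 1.5·%C22:0 + 2·%C24:0`
  and the affine map `CFPP = 3.1417·LCSF − 16.477` (Ramos et al. 2009,
  Bioresour Technol 100:261). Unsaturated species and saturated chains
  below C16 contribute nothing; the latter raise a warning so the
  omission is visible.

## Coefficient tables and provenance

The per-ester CN and IV tables are the main reproducibility risk of
this kind of prediction: different compilations differ by several
units for single esters. They therefore ship as versioned CSVs
(`inst/extdata/cn_methyl_esters.csv`, `iv_factors.csv`) with a per-row
source note, and every operation accepts an injected replacement
table. The shipped CN values are the widely used measured compilation
values (methyl palmitate 74.5, methyl oleate 59.3, methyl linoleate
38.2, methyl linolenate 22.7, ...; Knothe 2005, Fuel Process Technol
86:1059, supplemented for long-chain esters by literature estimates).
The IV factors are computed from the halogen-addition stoichiometry
and rounded to four decimals; a test asserts they stay within 3% of
the exact theoretical value per species, which documents the rounding.

No measured CN exists for the C16 polyunsaturates common in green
microalgae (C16:2, C16:3). They are deliberately absent from the
shipped table and resolved by the same structure-nearest fallback used
for GC response factors when no calibration standard is available:
first the same-unsaturation ester nearest in chain length (C16:2 →
C18:2, C16:3 → C18:3), then the same-chain ester nearest in
unsaturation. Every fallback emits a warning, and the pipeline
captures these into the written report, so substitutions are never
silent. Reports also carry an MD5 hash of the coefficient tables;
regression tests on the packaged worked example pin the tolerance
(CFPP ±0.05 °C as pure arithmetic; IV ±2 g I/100 g and CN ±3 units as
coefficient-provenance tolerances), so a table change that moves the
worked example outside them fails the suite.

## Compliance checking

The limit table transcribes the EN 14214 / ASTM D6751 rows relevant to
FAME-derived and routinely measured properties. Design choices, made
once and applied mechanically:

* Bounds written `≥x`/`≤x` are inclusive; the oxidation-stability
  induction periods are strict (`>6` h EN, `>3` h ASTM), following the
  standards' typography.
* CFPP has no numeric limit: EN 14214 delegates cold-flow classes to
  national annexes. The verdict is `not_evaluable` unless the user
  supplies a national limit (`country_cfpp_limit`); the package does
  not invent one.
* Below-quantification measurements (`"<0.1"`) are censored upper
  bounds: they pass an upper limit the bound itself satisfies and are
  otherwise `not_evaluable` — a censored value can never *fail* an
  upper limit, nor settle a lower one.
* Verdicts are mechanical. A value just outside a band (e.g. density
  0.85 kg/L against the EN band 0.86–0.90) is a `fail`, however close;
  "close to limit" is prose for the discussion section, not a verdict
  class. Properties without a limit in a standard are `no_limit`,
  never `pass`, and the overall verdict fails iff at least one
  property fails.

## Culture metrics

Growth-side metrics are window-based and take the window as an
explicit argument, because productivity figures are meaningless
without it: `μ = ln(N₂/N₁)/(t₂−t₁)` from cell counts, biomass
productivity `(X₂−X₁)/(t₂−t₁)` in g DW L⁻¹ d⁻¹, and lipid
productivity as the volumetric lipid mass balance
`(X₂f₂−X₁f₁)·1000/(t₂−t₁)` in mg L⁻¹ d⁻¹. A helper suggests the
exponential window as the steepest log-linear fit with R² ≥ 0.98 over
at least three consecutive points. Published whole-experiment
productivity figures are typically not recomputable from endpoints
alone (the sampling series behind them is rarely printed), so the
package validates these estimators against synthetic series with known
parameters instead of against any published productivity number.
Medium-removal efficiency after gravity sedimentation is simply
`1 − settled volume fraction`.

## What the synthetic generator emulates — and what it does not

`gen_fame_profile()` draws compositions from a Dirichlet distribution
with mean equal to the template (default: the CTP4 reference profile)
and dispersion set by a concentration parameter: `alpha = concentration
× mean fraction`, giving per-species variance `p(1−p)/(concentration+1)`.
Noise lives on the simplex, so renormalization never biases the means —
the property a law-of-large-numbers test checks at 1000 draws. The
default concentration of 500 reproduces the few-percent relative
scatter of triplicate GC-MS determinations. It does **not** emulate
correlated detector drift, response-factor miscalibration, or
below-detection truncation of trace species.

`gen_growth_series()` emulates the canonical two-stage lipid-induction
experiment: logistic biomass `X(t) = K/(1+((K−X₀)/X₀)e^{−rt})` with
multiplicative lognormal measurement noise, cell counts proportional
to dry weight, and a piecewise-linear lipid fraction — baseline
`f_base`, a dip to `f_dip` during the exponential phase (fast-dividing
cells build membranes, not storage lipids), recovery by the nutrient
switch at `t_switch`, and, under starvation only, a linear ramp from
`f_base` to `f_max` starting `induction_lag` days after the switch.
Defaults describe a Tetraselmis-like strain: `r` = 0.30 d⁻¹, `K` = 3 g
DW L⁻¹ (10⁶ cells mL⁻¹ per g L⁻¹, so counts plateau near 3×10⁶
cells mL⁻¹), `t_switch` = 10 d, `f_base` = 0.10, `f_dip` = 0.065,
`f_max` = 0.33, `induction_lag` = 2 d (lipid accumulation needs about
48 h of starvation before triacylglycerols build up), `noise_sigma` =
0.05. The lag-then-ramp shape is the minimal form consistent with that
phenomenology; no mechanistic model of nitrogen uptake or TAG
biosynthesis is attempted, so the generator cannot answer questions
about nutrient dose-response, and passing parameter-recovery tests
shows estimator correctness on this structure, not on real cultures
with autocorrelated noise, sampling gaps or photoacclimation effects.

## Numerical choices and degenerate inputs

* Normalization multiplies by `100/sum` and is exactly idempotent: an
  already-normalized profile (flag set, sum within 1e-9 of 100) is
  returned unchanged rather than rescaled through floating point.
* All-zero or negative profiles, duplicate species (including
  duplicates that only collide after omega metadata is dropped),
  chemically impossible unsaturation (`carbons < 2·db + 2`) and chains
  shorter than C4 are rejected with named errors.
* Seeded draws save and restore the caller's RNG state, so generator
  calls are reproducible without disturbing surrounding simulations.
* The `lm`-based window search is exhaustive over consecutive-point
  windows (quadratic in series length), fine for the ≤ 30-point series
  this domain produces.
* Problem sizes in the shipped tests were chosen to exercise the
  statistics without waste: 1000 Dirichlet draws for the mean-recovery
  and pipeline-closure checks, 100 seeds × 20 points for growth-rate
  recovery (median absolute error below 10% at σ = 0.05), 20–40 random
  profiles per structural property.

## Known limitations

* Predictions are only as good as the coefficient tables; for esters
  resolved by structural fallback the CN contribution is an
  approximation, flagged in logs.
* The CFPP model is a single affine fit to the LCSF and carries that
  model's scatter; it is a screening estimate, not a substitute for the
  filterability measurement.
* The compliance engine covers the property rows relevant to
  FAME-profile assessment, not the complete certification documents
  (no ester-content chromatographic purity breakdown, water content,
  acid value, sulfur, ash).
* Profiles with an unidentified remainder are either rejected or
  proportionally redistributed (`allow_remainder`); there is no model
  of what the unidentified mass is.
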