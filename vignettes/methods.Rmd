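---
title: "Methods: adjoint-style source attribution with a quadratic O3-NOx correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adjoint-style source attribution with a quadratic O3-NOx correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srhia)
```

## Overview

`srhia` attributes a receptor country's PM2.5 and O3 exposure — and the
premature mortality associated with it — to the gridded precursor
emissions that caused it, by source country, sector and species. The
chain is: adjoint-style sensitivities of a scalar exposure cost function,
first-order contributions λ·E, a per-cell quadratic correction for the
nonlinear O3–NOx relationship, classification into imported / domestic /
exported flows and the RERER statistic, scenario projection of emission
cuts, and a GBD-style health impact assessment.

A real chemical-transport model and its adjoint are deliberately out of
scope. In their place stands an analytic surrogate transfer model with a
closed-form cost function

$$J_r = b_r + \sum_{I,k,s} K_{r,I,k}\,E_{I,k,s} + \sum_I \gamma_{r,I}
\Big(\sum_s E_{I,\mathrm{NOx},s}\Big)^2,$$

which makes gradients, scenario states and zero-out experiments exact.
Every downstream stage can therefore be verified against closed forms
rather than against another approximation.

## The synthetic world

`buildWorld()` generates a deterministic toy domain from a seed: a
regular latitude–longitude grid (default 12 × 16 cells spanning
±60° latitude), a whole-cell Voronoi country mask (default 8 countries;
fractional border cells are deliberately not modelled), log-normal
population, and sectoral emissions for the seven species
(BC, OC, NH3, NOx, SO2, VOC, CO) and seven anthropogenic sectors plus a
natural NAT pseudo-sector.

Key generator choices, fixed once:

* **Sector totals** (Tg/yr, log-normally jittered ±15 % per seed to mimic
  inventory uncertainty): AGR 45, ENE 60, IND 50, RES 30, SHP 10, TRN 40,
  AIR 1, NAT 150. Species profiles are sector-typical: agriculture is
  NH3-dominated and emits **no** O3 precursor (no NOx, VOC or CO), land
  transportation is NOx-dominated, energy SO2/NOx, residential
  carbonaceous.
* **Natural floor.** The NAT sector is biogenic-realistic: VOC-dominated
  with soil NOx, and large (real biogenic VOC emissions are of order
  1000 Tg/yr, several times the anthropogenic total). This matters
  structurally: in the real atmosphere most background O3 is *produced
  from natural precursor emissions*, so the natural-only model state must
  be emission-driven. The additive per-receptor background is
  correspondingly small (1 µg/m³ PM2.5; 5 ppb O3, a stratospheric
  residual). An early design that put ~half of O3 into an additive
  background constant was rejected: a large non-emission term has no
  analogue in a transport model's cost function and corrupts the
  fractional apportionment of the quadratic fit (see below).
* **Transport kernels.** The linear kernel for receptor r decays with
  great-circle distance from the receptor's population (population
  weighting folded in, keeping the surrogate closed-form):
  e-folding length 900 km for PM2.5 and 2600 km for O3, reflecting O3's
  month-scale lifetime versus days for PM2.5. These lengths are free
  parameters; they were chosen so that imported shares span a wide range
  across receptors (roughly 0.1–0.8 between the two pollutants),
  comparable to the spread of published country RERER values.
* **Curvature.** Per (receptor, cell), the O3–NOx curvature is
  γ = u·K/E_NOx with u drawn uniformly from (0.05, 0.35) and, for 15 % of
  draws, from (−0.15, −0.02) — a minority of weakly concave,
  titration-like cells. Because 2u ∈ (−0.3, 0.7), the base-state NOx
  sensitivity K + 2γE = K(1 + 2u) stays positive everywhere.
* **Exposure scale.** Kernels are normalized so mean receptor exposures
  sit at ~25 µg/m³ PM2.5 and ~45 ppb O3 — levels at which the RR curves
  and the TMREL threshold are active.

The generator emulates linear exposure–emission response for PM2.5,
per-cell quadratic O3–NOx response with mixed curvature signs, and
distance-decaying transboundary transport. It does **not** emulate
meteorology, seasonality, chemistry regimes beyond the quadratic, plume
geometry, or fractional border cells — so passing tests demonstrate the
correctness of the attribution arithmetic, not fidelity to any real
atmosphere.

## First-order attribution

`firstOrderContribution()` is the elementwise product λ·E;
`aggregateToSources()` bins cells into (source country, sector, species)
under the mask, keeping unassigned cells separate so any partition
conserves totals. `normalizeContributions()` rescales by a single scalar
per receptor so the contributions sum to the cost function less the
background and the natural share. The normalization scalar is applied to
the *anthropogenic* share only (the natural NAT share is estimated
first-order and excluded); this is one of two defensible orderings and is
exposed through the function's `background` / `naturalShare` arguments.

Flows: domestic = source equals receptor; imported = all other sources;
exported = the receptor's own emissions' impacts summed over the *other
modelled receptors* only — impacts in the unmodelled world are not
estimated. Negative contributions from concave O3 cells are retained with
sign (clipping would break conservation); NAT is excluded from all three
flows. `rerer()` = imported / (imported + domestic) and errors on a zero
net rather than returning NaN.

## The quadratic O3–NOx fit

For each cell and O3 receptor, `fitQuadratic()` builds the 5 × 3 system:
rows (E², E, 1) at the four states — base T, natural-only N, 10 %
anthropogenic NOx Z, doubled anthropogenic NOx D — plus the derivative
row (2E_T, 1, 0) equated to the base-state adjoint sensitivity. The data
vector holds each state's cost function multiplied by the cell's
first-order fractional share of that state's total contribution.

Decisions where the procedure is underdetermined:

* **Which λ, which E in the fractions.** Sensitivities are always the
  base-state λ (the only adjoint a real study would have); emissions in
  the fraction are the *perturbed-state* emissions by default. The
  alternative (`fractionEmissions = "base"`) is exposed and is markedly
  worse on the synthetic world: base-emission fractions make the state
  rows collapse onto a single global response pattern.
* **Background netting.** The four state values enter net of the
  receptor's additive background. The fractions apportion emission-driven
  exposure; multiplying them by a cost function containing a non-emission
  constant would attribute that constant inconsistently across states
  (the N state, with small natural totals, is distorted most). With an
  emission-driven J (background zero) the two formulations coincide.
* **Rank tolerance.** Singular values below 1e-10 of the largest are
  treated as zero; an all-zero system returns zero coefficients with a
  warning and rank 0 rather than an error. When all four states share
  fewer than three distinct emission values the system is rank-deficient
  and the pseudoinverse returns the minimum-norm solution.
* **The intercept.** The anthropogenic contribution is
  (c1E² + c2E + c3) − c3 = c1E² + c2E: the fit's value at zero emissions
  (natural/background exposure) is not attributed to anthropogenic NOx.
* **Sector split.** The cell-level quadratic contribution is divided
  across sectors proportional to each sector's share of the cell's
  anthropogenic NOx.

Exact parameter recovery (c1 = γ, c2 = K, c3 = 0 to 1e-8) holds on worlds
where the fractional apportionment is exact — single-cell worlds or
identical-cell worlds — which is what the recovery tests use. On general
multi-cell worlds the fit is approximate by construction; its value is
measured by the evaluation suite below.

## Scenario assessment

`applyScenario()` builds ΔE = (1 − multiplier)·E on the affected
(countries × sectors × species), never touching NAT;
`projectExposureChange()` applies first order only, ΔJ = Σ λ·ΔE —
appropriate because scenario changes are smaller than the absolute totals
used in attribution. The DOM case cuts one country's cells; ALL cuts all.
The net-zero ramp interprets the remaining energy-sector emission
fraction at the 2040 horizon as (target − 2040)/(target − 2020), clipped
to [0, 1] — the only reading under which earlier targets produce larger
reductions — with air-pollutant cuts scaling linearly with the CO2 cut,
energy sector only, and no replacement-energy emissions added. Scenario
deaths use the projected demographics of the assessment year (default
2040).

## Health impact assessment

* PM2.5 relative risks come from per-outcome look-up tables (six
  outcomes: IHD, stroke, COPD, LRI, lung cancer, type-2 diabetes),
  linearly interpolated between knots; RR = 1 below the first knot and
  **held flat above the last** (high-exposure RR is poorly constrained;
  flat extrapolation is the conservative rule). Per-outcome exposure
  grids are allowed. The packaged tables are synthetic stand-ins —
  monotone concave curves with realistic saturation levels — not GBD
  data.
* O3 uses RR = exp(β·max(0, X − TMREL)) with β = ln(1.06)/10 per ppb and
  TMREL uniform on 29.1–35.7 ppb, integrated by **deterministic quantile
  averaging** (default 64 midpoints) rather than random draws, for
  reproducibility; the quantile average converges to the Monte-Carlo
  integral.
* Attributable mortality is y0(1 − 1/RR)Pop; source and scenario impacts
  are differences between the burden at the baseline exposure and at the
  counterfactual (baseline minus contribution, floored at zero). Under a
  nonlinear RR the per-source differences do not sum to the total burden;
  this is a property of the method, reported rather than "fixed".
* Baseline mortality rates are projected with annualized 5-year percent
  changes, r = (rate_end/rate_start)^(1/5) − 1: the 2015–2020 rate steps
  2019 → 2020, then each increment's rate compounds annually to 2040.
  Equal toxicity of PM2.5 components is assumed throughout.
* `rescaleExposureToBaseline()` multiplies contributions by
  reference/modeled (plus a configurable daily-metric conversion factor,
  default 1) to align modelled exposures with an external baseline.

## Evaluation protocol

`evaluateProjections()` perturbs the anthropogenic NOx of the
highest-emitting cells (21 by default, the spec of the original
protocol) by ±50 %, records the **true** response of every receptor by
re-evaluating the surrogate — never by the projection under test — and
scores first- versus second-order projections over the
strongest-response receptor of each test (largest |true ΔJ|, ties broken
by receptor code order). The normalized mean bias is defined as
NMB = 100·Σ(proj − true)/Σ|true| (the originating study prints NMB values
but never the formula); R² is the squared correlation. The acceptance
property is qualitative: |NMB(second)| ≤ |NMB(first)| in both
directions. Published real-model NMB/R² figures are not reproducible
without the real transport model and are not targets.

## Problem sizes and runtime

The default study conditions — a 12 × 16 grid (192 cells), 8 countries,
21 perturbation cells — keep every closed-form check exact while the full
test suite runs in well under a minute; the pipeline smoke configuration
uses an 8 × 8 grid with 4 countries. These sizes are the package's
testing conditions, not method limits: all operations are vectorized over
cells and receptors and scale to larger grids.

## Known limitations

* The surrogate's quadratic is the *only* nonlinearity; real O3 chemistry
  has regime changes the quadratic cannot represent, and the fit quality
  reported here does not transfer to any real model.
* Country masks are whole-cell; border cells are attributed entirely to
  one country.
* Health tables are synthetic; absolute death counts from the pipeline
  are structural outputs, not estimates. The packaged 43-country
  mortality table is the one place where real published numbers enter,
  and only its own aggregates are reproduced from it.
* Uncertainty bounds (RR draws, emission inventory spread) are out of
  scope; alternative RR tables can be supplied to run bounds externally.
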