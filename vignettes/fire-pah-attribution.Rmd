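---
title: "Attributing PAH pollution and cancer risk to wildfires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing PAH pollution and cancer risk to wildfires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahfire)
```

## The problem

Wildfire smoke carries polycyclic aromatic hydrocarbons (PAHs), a family of
fused-ring combustion byproducts spanning naphthalene (NAP, two rings,
volatile, weakly carcinogenic) to dibenz[a,h]anthracene (DAHA, five rings,
particle-bound, strongly carcinogenic). Quantifying how much of ambient PAH
pollution — and of the associated incremental lifetime cancer risk (ILCR) —
is due to fires requires more than an emission budget, because fire plumes
also change the chemistry of the air they pass through: added particulate
matter (PM) shifts semivolatile PAHs into the particle phase, and enhanced
oxidants (OH, O3, and especially NO3) convert parent PAHs into nitro- and
dinitro-substituted products (NPAH/DNPAH) with toxic equivalencies up to
ten times benzo[a]pyrene's.

`pahfire` implements that attribution chain at desk scale. The full-scale
version of this analysis runs a global 3-D chemical transport model; this
package deliberately replaces the transport core with independent per-cell
boxes so that every other link — speciation, partitioning, oxidation,
product formation, scenario differencing, risk aggregation — is exercised
and testable in seconds. It is a stand-in for the full model, not a
replica: absolute magnitudes are not comparable, orderings and shares are.

## Model structure

### Emissions

An inventory is a dense array over 8 sectors (residential, agricultural,
industrial processes, industrial combustion, transportation, commercial,
fires, electric generation) x 16 parent species x 12 months x a regular
lat-lon grid, in kg/cell/month. Two operations define the scenario design:

* `zero_fire_emissions()` builds the no-wildfire (NoWF) counterfactual.
* `redistribute_fire_speciation()` rebuilds the fires sector under the
  observation that biomass burning favours light aromatics: NAP held
  constant, five-/six-ring species zeroed, and each three-/four-ring
  species scaled to `E'_i = f_i * E_total` where `f_i` is its fraction of
  the original three-/four-ring fire emission and `E_total` the original
  fire total excluding NAP. Total fire PAH mass (excluding NAP) is
  conserved to 1e-12 relative and within-group proportions are preserved.

The redistribution fixes only *annual* totals; how the adjusted total is
spread over months and cells is an open design point. We scale each
species' original monthly/spatial fire pattern uniformly (factor
`E'_i / E_i`), preserving fire seasonality and geography — the only
structure available. A species with zero original fire emission receives
zero.

### Fate: per-cell box model

Each cell holds, per parent species, a gas and two particle reservoirs
(organic and black carbon). One time step (default 3600 s) does, in order:

1. **Kinetics, exact within the step.** Gas decays at
   `k_g = k_OH[OH] + k_NO3[NO3] + k_dep,gas` while emissions (all assumed
   gas-phase) enter as a constant source, giving the analytic update
   `C_g' = C_g e^{-k_g dt} + (E/k_g)(1 - e^{-k_g dt})`; particles decay at
   `k_p = gamma_O3 * c_het * [O3] + k_dep,particle`.
2. **Instantaneous re-equilibration.** The total is re-split by the
   particulate fraction `phi = Kp c_PM / (1 + Kp c_PM)`, with the particle
   share divided between OC and BC in proportion to their mass. Kinetic
   sorption is not modelled; this is the standard equilibrium-partitioning
   simplification.

The partition coefficient uses a reduced ppLFER form,
`log10 Kp(T) = intercept(T) + (298.15/T) L + 0.2 S`, with
`intercept(T) = -11.7 + 0.5 (1000/T - 1000/298.15)` and per-species
descriptors `L` (numerically the 298 K log octanol-air partition
coefficient) and `S` (a polarity term). The coefficients are package
defaults calibrated to field-realistic fractions (NAP essentially all gas;
benzo[a]pyrene ~95% particulate at 10 ug m^-3 PM) — the published
multi-descriptor coefficient sets are not reproduced here — and every
constant is overridable through `fate_config()`. The `c1 >= 0` constraint
guarantees Kp strictly decreases with temperature.

Because driver fields are monthly, the step map has constant coefficients
within a month, and `run_scenario()` evaluates the N-step composition in
closed form (geometric series, with the exact `r -> 1` limit for lossless
cells). This is bit-compatible with iterating `step_cell()` — a test
checks the equivalence on a single cell — and keeps a 36 x 72 x 14-month
double scenario under ~10 s. Integration runs a 2-month spin-up (November,
December of the same fields) from zero initial conditions, then averages
January-December.

### Degradation products

The model carries a kinetic pyrene pathway: PYR + NO3 forms nitro-pyrene
(yield 0.02 per reaction, product loss 4e-5 s^-1), which is further
nitrated to dinitro-pyrene (yield 0.4, loss 1e-5 s^-1). At local steady
state the product:parent ratios are

```
r_N  = y_N k_NO3,PYR [NO3] (1 - phi_PYR) / k_loss,N
r_DN = r_N * y_DN k_NO3,PYR [NO3] / k_loss,DN
```

and these ratios are broadcast to *all* parents — the "same ratio across
all PAHs" rule. Whether the full-scale model applies the ratio to
concentrations or to formation rates is ambiguous; the concentration-ratio
reading is implemented here and flagged as an assumption. The `k_NO3`
values in the species table are effective first-order-in-NO3 constants
(the true naphthalene nitration channel is termolecular in NO2, folded
in), documented in the table header.

Only products with known toxic equivalencies enter the risk sums. The set
of six shipped — 1- and 4-nitropyrene, 6-nitrochrysene, 2-nitrofluorene,
1,6- and 1,8-dinitropyrene, each linked to its parent — is an assumption,
as is the whole TEQ column: the parents follow the Nisbet-LaGoy scheme,
the products comparative-potency values (1,8-dinitropyrene carries 0.9 so
that benzo[a]pyrene remains the unique TEQ = 1 reference). Everything is
overridable by supplying a species table.

### Attribution and risk

Fire contribution is `baseline - NoWF`, per cell, absolute and percent;
zero-baseline cells carry an explicit undefined flag rather than NaN. Two
oxidant modes are exposed: in **shared** mode the NoWF run reuses the
baseline environment, making the model exactly linear in emissions (the
superposition test demands agreement with a fires-only run to 1e-9
relative); in **scenario** mode the NoWF run uses its own, unenhanced
environment, mirroring a fully interactive counterfactual, in which
percent contributions can leave [0, 100] and are reported, never clipped.
The full-scale system is interactive; neither mode is asserted as its
exact analogue.

Risk follows `ILCR = sum UR_A [PAH] TEQ` with `UR_A = 1.0e-6 per ng m^-3`
for benzo[a]pyrene and the same TEQ applied to every phase of a species —
so repartitioning mass between phases leaves ILCR unchanged (tested).
Exceedance against the 1.0e-6 acceptable limit uses a strict inequality at
the boundary. `TPUM = sum M_i TEQ_i / M_total` is the burden-weighted mean
TEQ of a mixture; it is scale-invariant and bounded by the extreme TEQs
present. Global shares use cos(latitude) area weighting throughout.

### Evaluation

`NMB = 100 * sum(model - obs) / sum(obs)`. The formula is not printed in
the source analysis; this conventional sum-ratio definition is adopted.
Per-species and LMW/HMW-aggregated variants are provided (LMW = 2-4
rings, HMW = 5-6).

## The synthetic world

`synthetic_config()` states the world once:

* 36 x 72 grid (5-degree cells); four fire regions loosely standing for
  Australia, sub-Saharan Africa, Siberia and Canada with dry-season peak
  months; four anthropogenic hotspot boxes.
* Sector totals give fires ~4.5% of annual PAH emission in the low-fire
  year; the high-fire year multiplies fire mass by 1.3, the observed
  dry-matter-burned ratio between the emulated low (2013) and high (2019)
  fire years. Fires' ring-size mix sits within the anthropogenic range,
  emulating the inventory being mimicked.
* Baseline environments add PM (up to 8 ug m^-3) and oxidant enhancements
  (NO3 up to x3, OH +50%, O3 +10 ppb) proportional to normalized local
  monthly fire intensity; the NoWF variant lacks them. Enhancements are
  normalized by the upper decile of burning-cell intensity so co-location
  is material rather than confined to the single strongest cell.
* Observations: sites in random positive-truth cells with multiplicative
  lognormal noise (sigma 0.4 by default).

What a green qualitative test establishes: the *orderings* the analysis
predicts — fire-sourced TPUM above non-fire, fire-sourced particulate
fraction above all-source, degradation-product risk share larger for fire
than for all sources, high-fire year above low-fire year — emerge from the
stated mechanisms. What it does not establish: any real-world magnitude;
the generator has no transport, no real geography, no emission-factor
detail, and its noise model is a single lognormal.

## Numerical and interface choices

* Uniform month length (365.25/12 days); monthly means are closed-form
  averages of the post-step states.
* The geometric-series accumulation switches to its exact limit when the
  per-step retention factor is within 1e-9 of 1 (lossless cells).
* On-disk formats are plain long-format CSV for inventories, environment
  fields, states, region masks and observations (no NetCDF dependency);
  all round-trips are tested. Species and toxicity tables are CSV with a
  `#` provenance header.
* The CLI (`pahfire synth|simulate|attribute|risk|evaluate|all`) is a thin
  wrapper over the exported functions; every report number is reproducible
  by calling the module-level operation directly (tested). Exit codes:
  0 ok, 1 user error, 2 internal error.
* Hydrophilic/hydrophobic OC/BC sub-splitting is collapsed to one OC and
  one BC reservoir; wet/dry deposition to two first-order constants.

## Known limitations

No transport means no remote influence: fire contribution is confined to
cells with fire emissions, so regional percent contributions are sharper
than a transported reality. Oxidant fields are prescribed, not chemically
interactive. The TEQ, rate-constant and ppLFER defaults are documented
assumptions chosen for realism of behaviour, not fitted values; analyses
sensitive to their absolute values should supply their own tables. The
published global magnitudes of the full-scale analysis (percent
contributions, TPUM values, NMB levels) are outside what this desk-scale
stand-in can or should reproduce.
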