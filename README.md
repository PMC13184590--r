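# pahfire

Wildfires emit polycyclic aromatic hydrocarbons (PAHs) — carcinogenic
combustion byproducts — and also reshape the atmosphere they enter: fire
plumes add particulate matter (shifting PAHs into the particle phase) and
enhance oxidants (OH, O3, NO3), which convert parent PAHs into nitro- and
dinitro-PAH degradation products that are often far more carcinogenic than
their parents. `pahfire` is a desk-scale R implementation of the full
analysis chain used to quantify that fire contribution: from a sector-level
emission inventory, through a simplified gridded atmospheric fate model, to
a baseline-versus-no-wildfire attribution and toxic-equivalency cancer-risk
metrics. It is aimed at atmospheric-chemistry and environmental-health
researchers who want a transparent, testable sandbox for the *logic* of
fire attribution, not a replacement for a 3-D chemical transport model.

## What it computes

* **Speciation redistribution** for the fire sector. With `f_i = E_i / ΣE`
  over the three-/four-ring group and `E'_i = f_i × E_total` (total fire
  PAH excluding naphthalene), fire emissions are shifted onto light
  aromatics while conserving total fire PAH mass, holding NAP constant and
  zeroing five-/six-ring species.
* **Gas–particle partitioning** via a poly-parameter linear free energy
  (ppLFER) form, `φ = Kp·c_PM / (1 + Kp·c_PM)`, with `Kp(T)` strictly
  decreasing in temperature.
* **First-order oxidative losses** (`k_OH·[OH] + k_NO3·[NO3]` in the gas
  phase, heterogeneous ozonolysis `γ·c_het·[O3]` on particles, plus
  deposition), integrated per grid cell with exact within-step
  exponentials.
* **Degradation products**: a kinetic pyrene pathway
  (PYR + NO3 → nitro-PYR → dinitro-PYR) yields local product:parent ratios
  that are broadcast to every parent.
* **Attribution** by scenario differencing: fire contribution =
  baseline − NoWF (no-wildfire) run, absolute and percent, globally and for
  named fire-prone regions.
* **Health risk**: `ILCR = Σ UR_A × [PAH] × TEQ` over the 16 EPA priority
  PAHs and 6 known-TEQ degradation products (UR_A = 1.0×10⁻⁶ per ng m⁻³
  for benzo[a]pyrene; exceedance against the 1.0×10⁻⁶ acceptable limit),
  and `TPUM = Σ M_i·TEQ_i / M_total`, the per-mass toxicity of a mixture.
* **Evaluation**: normalized mean bias,
  `NMB = 100 × Σ(model − obs) / Σ obs`.
* **Synthetic world**: a seeded generator for inventories (8 sectors × 16
  species × 12 months), environment fields with fire-co-located PM/oxidant
  enhancements, region masks and noisy observations, so the whole pipeline
  runs with no external data.

## Worked example

```r
library(pahfire)

cfg <- synthetic_config(seed = 1)          # default 36 x 72 world
res <- run_pipeline_year(cfg, year = "high", mode = "shared")
str(res$report[c("fire_percent_of_concentration", "fire_percent_of_ilcr",
                 "tpum_fire", "tpum_nonfire",
                 "particulate_fraction_fire", "particulate_fraction_all")])
#> List of 6
#>  $ fire_percent_of_concentration: num 4.11
#>  $ fire_percent_of_ilcr         : num 4.78
#>  $ tpum_fire                    : num 0.12
#>  $ tpum_nonfire                 : num 0.102
#>  $ particulate_fraction_fire    : num 0.181
#>  $ particulate_fraction_all     : num 0.168
res$regional
#>              region  absolute  percent
#> 1         australia 0.3329791 69.48302
#> 2 subsaharan_africa 0.3218227 67.99057
#> 3           siberia 0.5324874 58.00112
#> 4            canada 0.8011326 68.43178
```

Fires contribute ~4% of global mean PAH concentration and cancer risk in
this synthetic high-fire year, but 58–69% locally in the fire regions; the
fire-sourced mixture is more toxic per unit mass (TPUM 0.120 vs 0.102) and
more particle-bound (18.1% vs 16.8%) than the all-source mixture — the
orderings, though not the magnitudes, seen in full-scale global modeling.

A command-line driver wraps the same pipeline
(`inst/cli/pahfire synth|simulate|attribute|risk|evaluate|all --config
config.json`), writing CSV fields and a JSON report.

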