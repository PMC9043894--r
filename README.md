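# btdecay

Degradation kinetics of *Bacillus thuringiensis* (Bt) Cry proteins in
soil.

Bt proteins released by genetically modified crops (root exudates,
pollen, crop residues) accumulate in soil, and environmental risk
assessment needs to know how fast they disappear. `btdecay` is for
researchers analysing laboratory soil-incubation time courses of
protein residue (typically ELISA-quantified, in ng per g dry soil). It
implements the full analysis chain for a factorial incubation
experiment — soil type × temperature × water content, with a separate
sterilization contrast — and ships a synthetic-data generator that
emulates such an experiment (36 conditions, 18 sampling times over 96
days, 3 replicates, 1944 records), so everything is testable offline.

## The models

Two nested kinetic models are fitted per condition by bounded nonlinear
least squares:

- **first-order**: Y = a·e^(−bt) — single-exponential decay to zero,
  the conventional dissipation model, with half-life
  **DT50 = ln 2 / b**;
- **plateau**: Y = Y₀ + a·e^(−bt) — decay to a non-zero asymptote Y₀,
  the residual protein that is not degraded at late times.

Since the plateau model nests the first-order one (Y₀ = 0), its R²
never falls below the first-order R²; the package compares the two per
condition (ΔR²) and prefers the simpler model on ties.

Downstream of the fits:

- a **split-plot repeated-measures ANOVA** (within-subject factor:
  time, 18 levels; between-subject factors: soil site, water content,
  temperature; subjects are replicate series) with Greenhouse–Geisser
  correction and orthogonal polynomial time contrasts
  (linear/quadratic/cubic);
- a **factor-influence ranking**: per-factor-level means of DT50
  (early-stage metric) and Y₀ (late-stage metric), their max − min
  range, and a descending ranking of the factors per stage.

## Worked example

```r
library(btdecay)

sim <- simulate_dataset(simulation_config(seed = 42))   # 37 x 3 x 18 records
one <- sim[sim$condition_id == "Gongzhuling_T15_W20", ]

fo <- fit_model(one, "first_order")
pl <- fit_model(one, "plateau")
compare_models(fo, pl)
#> <model_comparison> Gongzhuling_T15_W20: R2(first-order) = 0.8468, R2(plateau) = 0.9318,
#>   delta R2 = 0.08506 -> preferred: plateau
```

The cool-and-wet condition keeps a large residual plateau
(Y₀ ≈ 85 ng/g), so the plateau model fits visibly better — its R²
advantage is what motivates the extra parameter. The first-order fit
gives DT50 = 14.5 d (half the initial residue gone in about two weeks at
15 °C).

```r
fits <- fit_all_conditions(sim, seed = 42)
factor_influence(fits)
#> Factor influence ranking:
#>   early stage (DT50 range, d): temperature > soil_type > water_content > sterilization (9.3d > 5.7d > 5.7d > 3.0d)
#>   late stage (Y0 range, ng/g): temperature > sterilization > soil_type > water_content (71.1 > 39.2 > 10.1 > 6.4)
```

Temperature dominates both the early-stage degradation rate (its
per-level mean DT50 spans 9.3 d across 15–35 °C) and the late-stage
residue (per-level mean Y₀ spans 71.1 ng/g).

```r
an <- rm_anova(sim[!sim$sterilized, ])
an$gg_epsilon
#> [1] 0.5702
an$contrasts[, c("label", "F", "p")]
#>       label          F            p
#> 1    linear 37017.2148 2.204100e-99
#> 2 quadratic   945.3054 3.828078e-43
#> 3     cubic   713.9267 4.190415e-39
```

The strongly non-spherical covariance (ε ≈ 0.57) is why GG-corrected
p-values are reported; the significant linear, quadratic and cubic
contrasts say the mean time trend is genuinely curvilinear — exactly the
shape an exponential-plus-plateau decay produces.

## Pipeline and CLI

`run_pipeline(pipeline_config(...))` runs
simulate/read → ANOVA → fits → comparison → ranking → report and writes
`fit_results.csv`, `model_comparison.csv`, `anova.csv`, `ranking.csv`
and `report.md`, each with a seed + config-hash provenance header.
From a shell:

```sh
Rscript -e 'btdecay::btdecay_cli()' run --seed 1 --outdir out
Rscript -e 'btdecay::btdecay_cli()' simulate --seed 1 --outdir out
Rscript -e 'btdecay::btdecay_cli()' fit --input out/measurements.csv --outdir out
```

Verbs: `simulate`, `fit`, `compare`, `anova`, `rank`, `report`, `run`;
flags `--seed`, `--config`, `--outdir`, `--use-means`,
`--max-poly-order`, `--plots`, `--quiet`.

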