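---
title: "Modelling Bt protein degradation in soil with btdecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Bt protein degradation in soil with btdecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btdecay)
```

## The problem

Insecticidal Cry proteins expressed by transgenic crops enter soil and
are degraded — quickly at first, then very slowly. A time course of
residue concentration `Y(t)` (ng per g dry soil, ELISA-quantified)
under controlled conditions is the standard way to characterise this.
`btdecay` models such time courses, estimates half-lives, and ranks the
environmental factors (temperature, water content, soil type,
sterilization) that control degradation.

## Models and estimands

Two nested models are fitted per experimental condition:

* first-order kinetics, `Y = a exp(-b t)`, with `a` the initial
  concentration (ng/g) and `b` the decay rate (1/day). The half-life is
  `DT50 = ln 2 / b` (days).
* plateau exponential, `Y = Y0 + a exp(-b t)`, where `Y0 >= 0` (ng/g)
  is the asymptotic residue that is not degraded on the time scale of
  the experiment, and `a` is the degradable amplitude.

The second model nests the first (`Y0 = 0`). For it, `ln 2 / b` is the
half-life of the degradable component `Y - Y0`; a "time to 50% of the
initial value" is undefined whenever `Y0 > Y(0)/2`, so the package
deliberately exposes only the two functionals `dt50_first_order()` and
`half_life_degradable_fraction()`.

Two stage-specific influence metrics follow the fits: the early stage
is summarised by DT50 from the *first-order* fit (the convention in the
dissipation literature, since DT50 derives directly from that model's
`b`), the late stage by `Y0` from the *plateau* fit. A factor's
influence on a stage is the range (max − min) of the metric's
per-factor-level means, and factors are ranked by that range.

## Fitting: parameters, bounds, numerics

`fit_model()` minimises the residual sum of squares over all replicate
observations (default `n = 54` for a full condition; per-time-point
means are an auditable option, reflected in `n_obs`). Choices that
matter:

* **Bounds** keep parameters physical: `Y0` in `[0, max(Y)]`, `a` in
  `(0, 2 max(Y)]`, `b` in `[1e-6, 20]` per day. They also make the fit
  scale-equivariant (bounds scale with the data).
* **Starting values** (`initial_guess()`): `Y0` from the mean of the
  last two sampling times, `a` from the earliest-time mean minus that
  plateau, `b` from an OLS line on `log(Y - Y0 + 1e-6)` versus time
  (fallback `ln 2 / (t_max/10)`).
* **Optimizer**: bounded Gauss–Newton (`nls`, port algorithm), with up
  to 5 restarts from deterministically jittered starts (jitter derived
  from the run seed, so results are reproducible), an `optim`
  L-BFGS-B fallback, and a final tight L-BFGS-B polish — the port
  solver can stop a few parts in 1e4 short of the optimum on
  near-noiseless data, and the polish makes noiseless recovery exact to
  1e-6 relative error.
* **R²** is `1 - SS_res/SS_tot` about the observed mean (the
  conventional curve-fitting report); the regression p-value is the
  upper tail of `F = (SS_reg/(p-1)) / (SS_res/(n-p))`. For a bounded,
  monotone model this F test is *conservative* under a no-trend null
  (the model cannot chase an increasing noise pattern), which our null
  simulations confirm; it is reported for comparability with standard
  software output, not as a calibrated test.
* **Ties and boundaries**: `compare_models()` prefers the plateau model
  only when its R² advantage exceeds 1e-12 (parsimony on exact ties);
  fitted `Y0` below 1e-6 is reported as exactly 0 with a note that the
  two models coincide.
* **Degenerate inputs**: constant series are flagged, not fitted;
  fewer than `n_params + 1` distinct times is an error.

## Repeated-measures ANOVA

The design is split-plot: each replicate of each condition is a
"subject" whose 18 measurements over time are correlated.
(The physical experiment destroys a tube at each sampling; treating
replicate `r`'s tubes across times as one series mirrors the common
SPSS workflow and is a modelling convention, documented here as such.)

* Between-subject effects (soil site, water content, temperature and
  their interactions) are tested against subject-within-cells error —
  equivalent to a factorial ANOVA of time-averaged responses.
* Time and time×factor effects are tested against the subject×time
  residual.
* Because sphericity never holds for 18 ordered times, within-subject
  tests carry the Greenhouse–Geisser correction, with epsilon estimated
  from the pooled within-cell covariance matrix
  (`eps = tr(M)^2 / ((k-1) tr(M^2))`, `M = C'SC` for an orthonormal
  contrast basis `C`), clamped to `[1/(k-1), 1]`. Huynh–Feldt is not
  implemented; GG is the conservative default and the only correction
  the analysis conclusions need. Mauchly's test and multivariate
  within-subject statistics are out of scope.
* Polynomial contrasts project each subject series on orthonormal
  polynomial vectors over the time levels (equally spaced ranks by
  default, matching SPSS; metric spacing in actual days is an option)
  and test each order against its own subject-level error with
  `n_subjects - n_cells` df, up to order 3 by default.
* Incomplete series are excluded listwise with a warning; empty design
  cells are an error. No imputation.

The ANOVA engine is `stats::aov` with an `Error(subject)` stratum —
textbook-correct for the balanced designs in scope — while epsilon and
the contrasts are computed in-package; a brute-force cell-mean oracle
in the test suite checks every SS, df and F on a toy design.

## The synthetic-data generator

`simulate_dataset()` emulates the factorial incubation experiment the
analysis assumes: 4 soil sites × 3 temperatures (15/25/35 °C) × 3 water
contents (20/33/50%), 18 sampling times (0 h to 96 d, sub-day times as
exact day fractions), 3 replicates — 1944 records — plus one sterilized
condition paired with its unsterilized counterpart.

* **Truth curves**: the nine reference-site (Gongzhuling) conditions
  and the sterilized pair use published fitted plateau parameters
  verbatim as ground truth (measured initial concentrations are never
  reported separately from fitted intercepts, so fitted parameters are
  the only available truth). The other three sites have no published
  per-condition parameters: their truths are *synthetic stand-ins*,
  built by scaling the reference `b` by the ratio of published per-site
  mean DT50s and `Y0` by the ratio of published per-site mean `Y0`s,
  keeping `a`. They preserve the between-site ordering, not any real
  per-cell structure.
* **Noise**: truncated additive Gaussian,
  `Y_obs = max(0, mu(t) + e)`, `e ~ N(0, max(s0, cv * mu(t)))` with
  `cv = 0.10` and floor `s0 = 2` ng/g. Proportional error is the
  conventional ELISA behaviour; the floor keeps late, near-plateau
  points from having near-zero variance. CV 10% puts the first-order R²
  on simulated cool-condition data in the published 0.89–0.92 band.
  The floor truncates fewer than 1% of records for every default truth.
* **Seeds**: a single master seed; each (condition, replicate) pair
  gets a deterministic child seed from a string hash, so the same seed
  is bit-reproducible and adding conditions never reshuffles existing
  noise.

What the generator does *not* emulate: plate/batch effects and dilution
structure of real ELISA data, drifting water content, microbial
dynamics, or any mechanistic temperature dependence (no Arrhenius law).
A green pipeline test therefore establishes statistical correctness of
the estimators under the stated error model — not field validity.

## Design choices where the design was open

* The early-stage metric uses DT50 from the first-order fit even where
  the plateau model fits better, because DT50 is defined from that
  model's `b`; mixing models per condition would make level means
  incomparable.
* Sterilization is a two-level factor evaluated only on its matched
  condition pair (35 °C, 50%, reference site), then compared with the
  other factors on the common range scale — the sterilization trial is
  a separate experiment and folding it into the factorial would
  unbalance the design.
* Level means are unweighted across conditions; unequal level counts
  emit a warning rather than silently reweighting.
* Tied influence ranges are broken alphabetically and flagged; no
  formal inference is attached to the ranking (no standard errors on
  ranges).
* CSV is the single tabular interchange format, with a YAML sidecar for
  simulation provenance; times are serialized at full precision so
  round-tripping does not perturb fits.

## Known limitations

* The regression p-value is an omnibus F approximation for a nonlinear
  bounded model (see above) — use it descriptively.
* GG epsilon estimated from 2 df per cell (3 replicates) is noisy;
  with the full 36-cell design the pooled estimate has 72 df, which is
  adequate but not generous.
* The "subject" convention for destructively sampled tubes
  overstates within-series correlation if tubes are truly independent;
  the split-plot F tests are then conservative for time effects.
* DT50 printed by any downstream report is a formatting concern; all
  internal computation and CSV output carry unrounded values.
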