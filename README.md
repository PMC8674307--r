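# fcharmony

Site-effect harmonization for multi-site resting-state functional-connectivity
(FC) studies, built around **site-wise de-meaning (SWD)** and the two methods
it is most often compared against: per-feature **GLM** site removal and
parametric empirical-Bayes **ComBat**.

## The problem

Multi-site fMRI consortia (ABIDE, B-SNIP, ...) pool scans acquired on
different scanners with different protocols. The resulting site effects —
additive shifts and multiplicative rescalings of FC values — confound
case-control comparisons, and the standard fixes often *shrink* the very
disease effects the pooling was meant to detect. `fcharmony` implements and
compares three mitigation strategies on subjects × features tables of
Fisher-z connectivity values `y_ijv` (site *i*, subject *j*, ROI pair *v*):

- **SWD** — compute one scalar per site, the mean of *all* FC values over
  every subject and feature at that site, and subtract it:
  `y'_ijv = y_ijv − m_i`. A single scalar per site cannot absorb diagnosis
  information, so within-site contrasts are untouched while additive site
  offsets disappear.
- **GLM** — per feature, fit `y_ijv = α_v + X_ij'β_v + ε_ijv` with age, sex
  and site indicators, and subtract the fitted value (`full` mode, the
  printed formula) or only the site components (`site-only` mode). With
  unequal patient fractions across sites, the site indicators absorb part of
  the diagnosis effect.
- **ComBat** — the location/scale model
  `y_ijv = α_v + X_ij'β_v + γ_iv + δ_iv ε_ijv` with empirical-Bayes
  shrinkage of the per-site location (`γ`) and scale (`δ`) parameters across
  features, protecting age, sex and diagnosis as covariates of interest:
  `y*_ijv = σ_v (z_ijv − γ*_iv)/δ*_iv + α_v + X_ij'β_v`.

Methods are compared through the case-control **Hedges' g** per feature,

```
g = (M_control − M_patient) / sd_pooled,
sd_pooled² = ((n₁−1)s₁² + (n₂−1)s₂²) / (n₁+n₂−2),
```

and the **percent change** `100·(g_method − g_original)/|g_original|`.

The package also provides the upstream steps (Pearson FC from ROI time
series, Fisher z-transform, upper-triangle vectorization, age/sex
residualization), a synthetic multi-site cohort generator with known ground
truth, a pipeline orchestrator with provenance tracking, and broom-style
`tidy()`/`glance()`/`autoplot()` methods for every harmonization result.

## Worked example

```r
library(fcharmony)

sim <- simulate_features(sim_config(seed = 1))   # 4 sites, 200 subjects, 190 features
res <- run_pipeline(sim$phenotypes, features = sim$features,
                    features_of_interest = sim$truth$signal_features[1:2],
                    verbose = FALSE)
res$report
#> # A tibble: 8 × 6
#>   feature method   n_control n_patient     g percent_change
#>   <chr>   <fct>        <int>     <int> <dbl>          <dbl>
#> 1 0_1     original        67       133 0.571          0
#> 2 0_1     swd             67       133 0.617          7.95
#> 3 0_1     glm             67       133 0.596          4.27
#> 4 0_1     combat          67       133 0.617          7.93
#> 5 0_2     original        67       133 0.795          0
#> 6 0_2     swd             67       133 0.789         -0.748
#> 7 0_2     glm             67       133 0.843          6.10
#> 8 0_2     combat          67       133 0.845          6.30
```

Each row is one ROI-pair feature under one method: `g` is the control-minus-
patient standardized mean difference after that method's harmonization, and
`percent_change` is its gain or loss relative to the unharmonized
(age/sex-residualized) data. Here the simulated cohort carries additive site
offsets and a true diagnosis effect on the signal features, and all three
harmonizers recover a similar or larger effect size than the raw pooled data.

The percent-change convention applied to the published multi-site
schizophrenia and autism effect sizes bundled with the package:

```r
library(dplyr)
reference_effect_sizes() |>
  mutate(swd_pct = round_half_away(percent_change(swd, original), 1))
#>   study  contrast  feature            original   glm combat   swd swd_pct
#> 1 B-SNIP SZ vs HC  within MPFC           0.307 0.176  0.238 0.321     4.5
#> 2 B-SNIP SZ vs HC  MPFC-ACC              0.205 0.123  0.156 0.221     7.9
#> 3 ABIDE  ASD vs HC MPFC-PCC/precuneus    0.263 0.244  0.277 0.277     5.3
#> 4 ABIDE  ASD vs HC MPFC-MTG              0.489 0.433  0.483 0.503     2.9
```

A command-line front end over the same functions lives at
`inst/cli/fcharmonize.R`:

```sh
Rscript inst/cli/fcharmonize.R simulate --config sim.yaml --seed 5 --out-dir sim
Rscript inst/cli/fcharmonize.R harmonize --features adj.csv --phenotypes sim/phenotypes.csv --method swd --out swd.csv
Rscript inst/cli/fcharmonize.R run --config run.yaml
```

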