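---
title: "Harmonizing multi-site functional connectivity: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-site functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcharmony)
```

## Scope and data model

`fcharmony` operates on subjects × features tables of functional
connectivity (FC). A feature is one ROI pair `(a, b)` with `a < b`, indexed
0-based in row-major order over the strict upper triangle of the symmetric
correlation matrix; a parcellation into *R* regions yields
*V = R(R−1)/2* features. The diagonal is never stored, because the Fisher
z-transform of a unit correlation is infinite. Values are Fisher-z
correlations, `z = atanh(r)` — the variance-stabilizing scale on which all
three harmonizers and the effect-size comparisons are defined.

The canonical processing order, recorded in each table's provenance and
enforced by `run_pipeline()`, is

1. Pearson correlation of regional time courses (`compute_fc()`),
2. Fisher z-transform (`fisher_z()`), vectorization (`vectorize_fc()`),
3. age/sex residualization (`residualize_covariates()`), giving the
   "original" table,
4. harmonization (`harmonize_swd()`, `harmonize_glm()`,
   `harmonize_combat()`),
5. per-feature Hedges' g and percent change (`feature_effect()`).

SWD consumes the residualized table. GLM and ComBat consume the Fisher-z
table directly because their own designs model age and sex; the ComBat
output then has age and sex regressed out before effect sizes are computed.
This asymmetry — GLM's design holds age, sex and site; ComBat's covariates
of interest are age, sex *and diagnosis* — is deliberate and mirrors how
the methods are specified and used in the multi-site literature.

## The three harmonizers

**SWD.** For site *i*, `m_i = mean_{j,v}(y_ijv)` — a single scalar over all
subjects and all features at the site — and `y'_ijv = y_ijv − m_i`. The mean
runs over all *V* features; a diagnosis effect confined to a few features is
diluted by a factor of order (signal features)/*V* and therefore essentially
cannot leak into `m_i`. Consequences tested in the suite: every site's
overall mean is exactly zero afterwards; the operation is idempotent;
within-site group contrasts, and hence single-site Hedges' g, are
bit-invariant. Sites with a single subject are allowed with a warning (the
mean is defined but degenerate); declared-but-empty site levels are an
error.

**GLM.** Per feature, ordinary least squares of
`y = α + β_age·age + β_sex·sex + Σ_k β_k·site_k + ε` with reference-coded
site indicators. The default `full` mode subtracts the whole fitted value,
leaving OLS residuals — this follows the removal formula as printed in the
method-comparison literature, and makes the output exactly orthogonal to
every design column. The `site-only` mode subtracts just the site-indicator
component, preserving age/sex structure; on noise-free data constructed
from pure site offsets it removes them exactly (all sites are moved to the
reference-site level). The design never includes diagnosis, which is
precisely why imbalanced patient fractions let the site indicators absorb
part of the diagnosis contrast.

**ComBat.** Parametric empirical Bayes for the model
`y_ijv = α_v + X'_ij β_v + γ_iv + δ_iv ε_ijv`:

1. joint OLS with one indicator per site plus covariates, identified by the
   constraint `Σ_i n_i γ̂_i = 0` (α̂ is the site-size-weighted mean of the
   site intercepts); pooled variance `σ̂²_v` with denominator *n*;
2. standardization `z = (y − α̂ − X'β̂)/σ̂_v`;
3. per site, raw moments `γ̂_iv` (mean) and `δ̂²_iv` (n−1 variance) across
   subjects; hyperparameters by method of moments across features — normal
   prior (`γ̄_i`, `τ̄²_i`) for locations, inverse-gamma (`λ_i`, `θ_i`) for
   variances with `λ_i = (m² + 2s²)/s²`, `θ_i = (m³ + m s²)/s²`; then
   iterated conditional updates
   `γ* = (n τ̄² γ̂ + δ²* γ̄)/(n τ̄² + δ²*)` and
   `δ²* = (θ + ½ Σ_j (z − γ*)²)/(n/2 + λ − 1)`;
4. adjustment `y* = σ̂_v (z − γ*)/δ* + α̂ + X'β̂`.

The iteration stops when the largest *relative* change across features
falls below `conv = 1e-4` (cap 500, exceeding it is an error reporting the
worst change). We use the relative-change rule, the convention of the
reference parametric-ComBat implementations, so that results are
reproducible against them; the test suite confirms agreement with the
independent Bioconductor implementation (`sva::ComBat`) to better than
1e-6 per entry on a seeded 3-site instance (observed: ~1e-15). Sites need
`n_i ≥ 2` (a within-site variance must exist). The trailing age/sex
regression is exposed as `adjust_covariates` (default off) so the core
operation remains a pure ComBat that external references can be compared
against; the pipeline turns it on.

## Effect sizes

`hedges_g()` uses the (n−1)-weighted pooled SD and the sign convention
control − patient, so hypoconnectivity in patients yields positive g.
The small-sample correction `J = 1 − 3/(4(n₁+n₂−2)−1)` is **off by
default**: the printed formula in the comparison literature carries no
correction factor, at consortium sample sizes J ≈ 1, and percent change is
invariant to any factor common to both g values; a flag enables it.
`percent_change()` divides by `|g_original|` — all published originals are
positive, so this matches the tables, and it keeps the sign meaning
("increase" = magnitude direction of the original) well defined should the
original be negative. Percent changes are held at full precision and
rounded only at reporting layers, one decimal, ties away from zero
(`round_half_away()`), which is the convention needed to reproduce every
published percent-change cell from its g column.

## The synthetic cohort generator

`simulate_features()` draws from exactly the ComBat generative model:

```
y_ijv = α_v + age_j β_age,v + sex_j β_sex,v + diag_j d_v + γ_iv + δ_iv ε_ijv
```

with `ε ~ N(0, noise_sd)` on the Fisher-z scale. Defaults describe a
realistic small four-site case-control cohort: baselines
`α_v ~ N(0.25, 0.1)` (typical z-scale FC levels), age slopes around
−0.002 z/year, sex effects around 0.02 z, per-site mean ages and sex mixes
following a published four-site schizophrenia consortium, patient fractions
0.59–0.71, within-group noise SD 0.2 z, site location offsets
`γ_iv ~ N(Γ_i, τ²)` with `Γ_i ~ N(0, 0.1)` and `τ = 0.05`, and optional
inverse-gamma scale effects. The diagnosis effect is specified in
within-group SD units and applied to designated signal features, patients
lower (`d_v = −effect_size · noise_sd`). Three independent seed streams
(phenotypes, parameters, noise) are derived from one seed so that changing
one block of the configuration does not perturb the other draws; a fixed
seed reproduces the cohort bit for bit.

What the generator does *not* emulate: BOLD time-series physics (motion,
physiological noise, autocorrelation, scanner drift), realistic
correlations *between* FC features, non-Gaussian site effects, or
site-by-diagnosis interactions. Passing tests therefore demonstrate that
the estimators do what their models claim under the models' own
assumptions — not that any method removes real scanner effects from real
data. `simulate_timeseries()` covers the upstream path separately (draws
from a multivariate normal with a target correlation matrix, Cholesky
factorization, positive-definiteness required).

## The headline comparison

`evaluate_headline()` replicates the mechanism that motivates SWD: with
*imbalanced* patient fractions across sites, GLM's site indicators absorb a
fraction `Δ = Σ_i (w^P_i − w^C_i) p_i` of the diagnosis effect (the
weighted covariance between site membership and diagnosis), while SWD's
single scalar per site absorbs essentially none of it. The study conditions
(`sim_config_headline()`) are: four sites with the published patient
fractions (0.713, 0.654, 0.594, 0.705) and relative sizes (188:52:143:129,
for which Δ ≈ 0.012), one signal feature with a 1 SD effect among V = 50,
noise SD 0.2, and fixed additive site offsets
Γ = (0.0218, −0.0313, 0.0073, −0.0273). The offsets were chosen once, by
design: orthogonal to the imbalance contrast (so the raw pooled contrast is
not biased in either direction and the comparison isolates the two
mechanisms — variance inflation in the original data, signal absorption in
the GLM) and with weighted variance Δ·σ², which splits the ordering margins
evenly: SWD gains ≈ Δ/2 over the original from removed site variance, and
the original retains ≈ Δ/2 over GLM because absorption outweighs the
inflation. Cohort size is 16× the published cohort (n = 5,072 per
replicate) so that the sampling noise of the paired g differences
(≈ 0.003) sits well below those ±0.006 margins; at the published n = 317
the two estimators differ by less than their replicate-to-replicate noise
and the ordering would be a coin flip. Across 200 seeded replicates the
ordering `g_swd ≥ g_original ≥ g_glm` holds in well over 90% of runs
(observed 93–98% depending on the seed), and the suite asserts ≥ 90%.

## Numerical choices and degenerate inputs

- **Correlation clipping**: `fisher_z(r, clip_eps = 1e-7)` clips |r| to
  `1 − 1e-7` before `atanh`. Unit correlations cannot occur off-diagonal in
  real data but do in toys; the induced bias (z capped at ≈ 8.4) is
  negligible at FC magnitudes.
- **Residualization keeps the intercept** by default: grand-mean-centered
  residuals would strip FC values of their physical level, which is one of
  the stated drawbacks of ComBat-style centering; `keep_level = FALSE`
  yields pure residuals. Either way residuals are exactly orthogonal to the
  covariates and the operation is idempotent. Ages enter uncentered and
  linearly; the intercept absorbs their mean.
- **Rank checks**: every design is checked for full column rank after
  encoding; constant covariates, confounded site/covariate structures, and
  n ≤ p are hard errors rather than silent drops. The "no covariates" case
  is expressed as an empty covariate set (intercept-only design, returns
  the input exactly), not as zero columns, which would be rank-deficient.
- **Minimum sizes**: Pearson FC needs T ≥ 3 timepoints (readers and
  `compute_fc()` enforce this; the simulator will generate shorter series
  for boundary testing); Hedges' g needs ≥ 2 subjects per group and a
  nonzero pooled SD; ComBat needs ≥ 2 subjects per site; SWD warns on
  single-subject sites.
- **Percent change at g_original = 0** is undefined and an error, not NA.
- **Feature tables on disk** are plain CSV/TSV with a `# provenance:`
  header comment; round trips are lossless at full double precision, and a
  paired read against a phenotype table with a different subject order is
  an error rather than a silent re-sort.

## Problem sizes used by the test suite

Unit tests run on toy cohorts (tens of subjects, ≤ 20 features). The deeper
checks use: 3 sites × 10 subjects × 20 features for the reference-
implementation comparison; 4 × 50 × 500 for ComBat location recovery
(r > 0.95 against truth) and for the null-cohort perturbation bound
(RMS < 0.05 z); and 200 replicates of the n = 5,072 headline cohort. These
sizes were chosen so that each statistical assertion has comfortable margin
under its stated threshold while the full suite stays in the minutes range
on a single core.

## Known limitations

- Only the parametric-prior ComBat is provided (no nonparametric priors,
  ComBat-GAM, or covariance-preserving variants), and no traveling-subject
  calibration.
- Covariate adjustment is linear in age with no interactions; no
  mixed-effects structure.
- The effect-size module reports raw Hedges' g only — no confidence
  intervals, permutation tests, or multiple-comparison control.
- The simulator's independence of features means empirical-Bayes shrinkage
  operates under ideal exchangeability; correlated features in real FC data
  make the hyperparameter estimates noisier than the tests reflect.
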