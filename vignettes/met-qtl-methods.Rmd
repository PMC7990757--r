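---
title: "Multi-environment QTL mapping with factor-analytic mixed models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment QTL mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metqtl)
```

## The problem

Grain yield in wheat trialled across dry and hot environments is highly
polygenic, has low single-trial heritability, and interacts strongly with
the environment. A multi-environment trial (MET) series — the same
doubled-haploid (DH) population phenotyped at many location-by-year
combinations — lets a single analysis separate QTL with stable main effects
from QTL whose effects change sign or magnitude across trials (Q×E). This
package implements that analysis end to end, plus the NIL fine-mapping step
that validates a detected locus, and a simulator that generates data with
exactly the statistical structure the model assumes, so every stage can be
tested against known truth.

## The plot-level mixed model

For trait values `y` stacked over all plots of all environments:

$$ y = X\tau + Zu + Z_g g + e $$

* **Fixed part** `X tau`: one intercept per environment; one column per
  control variety (control lines are fixed because they are replicated
  checks, not part of the mapping population — `build_design()` classifies
  any phenotyped line absent from the genotype matrix as a control);
  optional centred linear row/column trends per environment; covariate
  columns during the scan.
* **Replicates** `u`: a random intercept for each environment-by-replicate
  block with a single scalar variance. Which non-genetic random terms the
  original field analyses carried per trial is not fully specifiable from
  the outside; replicate-within-environment plus optional fixed row/column
  trends is this package's interpretation, chosen because it is the minimal
  structure that separates replicate layout effects from the spatial field.
* **Genetic term** `Z_g g`: `g` holds one effect per (line, environment)
  with covariance `Sigma ⊗ I_m`. `Sigma` is `diag(sigma2_g[j])` (DIAG) or
  factor-analytic `Lambda Lambda' + Psi` (FA(k)). FA loadings use the
  upper-triangular-zero identifiability constraint for k > 1, with the first
  nonzero loading of each factor kept positive.
* **Residual** `e`: per environment, variance `sigma2[j]` times a separable
  AR1×AR1 correlation over the field grid (`rho_row^a * rho_col^b` at lag
  (a, b)), or independent. Missing plots are dropped and correlations follow
  integer lag distances; complete, evenly spaced grids use the closed-form
  tridiagonal AR1 precision.

### REML evaluation and optimization

The restricted log-likelihood
$-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py]$
is evaluated by absorbing all random effects through
$|V| = |R|\,|G|\,|G^{-1} + Z'R^{-1}Z|$ with a sparse Cholesky factor of the
mixed-model-equations matrix, whose symbolic factorization is cached and
updated across evaluations. Three progressively specialised paths give the
same value (tested against a dense first-principles evaluation to 1e-8):

1. DIAG genetic × iid residual: the genetic block of the MME is diagonal and
   the replicate block is per-environment, so an evaluation is pure vector
   arithmetic plus J tiny Schur complements;
2. complete evenly spaced grids (iid or AR1×AR1): the AR1 precision is
   `1/(1-rho^2) (I + rho^2 D - rho A)`, so every cross-product is a cached
   parameter-free sparse matrix and an evaluation is one dense
   matrix–vector product plus a sparse Cholesky update;
3. a general sparse path for irregular layouts.

Optimization is quasi-Newton (`nlminb`) on an unconstrained scale: log
variances, `atanh` autocorrelations, free loadings. Starting values are
per-environment moment estimates, which are the exact REML solution for
balanced single trials — this is why the balanced-toy check converges to
machine-level accuracy. FA fits are initialized from the DIAG fit and each
FA(k) from FA(k−1); `n_starts` adds jittered restarts against local optima.
Variances are floored at 1e-8 of the response variance. Because a
log-parameterized variance cannot reach zero, a post-fit boundary snap tests
each genetic variance at the floor and accepts it when the deviance is flat
(within 0.01), reporting a boundary estimate.

### Workflow rules

* **Trial filter**: environments with `sigma2_g < 0.01 * sigma2_e` under the
  DIAG fit are removed before the final MET model.
* **FA order**: k is increased until the common factors explain more than
  80% of the summed between-environment genetic variance
  (`fa_percent_variance()`), bounded by J−1.
* **Heritability**: Cullis
  $h^2_j = 1 - \overline{\mathrm{PEV}}_j / (2\hat\sigma^2_{g,j})$, with the
  mean taken over line pairs within environment j; in the balanced
  single-trial case this reduces exactly to
  $\sigma^2_g / (\sigma^2_g + \sigma^2_e / r)$.

## Genetic predictors and the scan

A predictor at map position t is the conditional expectation of the ±1
genotype (+1 = parent-1/Excalibur-role homozygote, −1 = parent-2/Kukri
role) given the nearest non-missing flanking markers, with flanking
recombination fractions obtained from cM gaps by the inverse Kosambi
function. The flanking probabilities combine the two r's without
interference (`r_LR = r_l + r_r − 2 r_l r_r`). This is a deliberate,
documented mismatch: Kosambi is used exactly where map distances are
converted, while the three-point conditional probabilities require the
no-interference algebra to stay closed-form. The simulator uses the same
Markov recombination model, so the predictor oracle equivalence is exact,
not approximate. Predictors are never re-standardized; at an observed
homozygote the value is exactly ±1.

The default query scheme places one predictor at each adjacent-marker
interval midpoint (labels carry the flanking marker names); a marker-position
scheme exists for diagnostics and for studies where a locus is planted at a
marker.

Each predictor extends the fixed part of the fitted MET model with a main
effect and a predictor-by-environment interaction in sum-to-zero coding, so
the main effect is the across-environment mean effect. Wald tests: 1 df for
the main effect, J−1 df for Q×E. Variance parameters are held at the
null-model estimates (`refit_variance = TRUE` refits per interval; on null
data the two agree closely and the fixed-θ scan is the standard fast
approximation). Covariate markers (e.g. phenology loci found by scanning
DTH first) are fitted as additional fixed effects, excluding covariates on
the scanned linkage group to avoid collinearity with the tested predictor —
a consequence is that a covariate's own group is scanned unadjusted, so the
pipeline flags (rather than suppresses) target-trait QTL that coincide with
a covariate position (`phenology_linked`).

Intervals significant at p < 0.01 (either term; no further multiplicity
correction, matching the exploratory threshold choice) merge by contiguity
into one QTL per run; the peak is the interval with the largest Wald
statistic, reported with its own flanking markers and cM span. No formal
support-interval rule is applied because none is defined for this workflow;
the peak interval's span is the honest minimal statement.

## NIL fine-mapping

`derive_pairs()` pairs, within each family, the most-parent-1 and
most-parent-2 fully homozygous lines over the interval markers — members may
carry recombination points, as real NIL families do — and records the
maximal contiguous block where the pair is A vs B. `compare_traits()` is a
pooled-variance Student t-test (Welch optional); pooled is the recorded
default since the original comparisons specify only "t test", and star
tiers use strict inequalities at 0.05/0.01/0.001. `delimit_interval()`
computes: intersection of segments of significant pairs, minus the union of
segments of non-significant pairs; discordance (a non-significant pair
covering the candidate region, or disjoint significant segments) raises an
explicit error instead of silently resolving — formalising what is
otherwise done by eye on a haplotype figure.

## The simulator

`simulate_dh_genotypes()` draws each line/group as a Markov chain with
inverse-Kosambi flip probabilities; `simulate_met_phenotypes()` builds line
genetic values as planted-QTL contributions (±1 genotype at the locus,
drawn conditionally on its flanking markers) plus an FA polygenic term
`Lambda f + delta`, then adds environment means, replicate effects, an
AR1×AR1 Gaussian field, and assigns entries to a full row×column grid by a
seeded permutation. Everything is deterministic given the seed, and the
`truth` record (QTL positions/effects, Sigma, spatial parameters, per-line
genetic values) scores any recovery test without re-simulation.

What it emulates: the scale and structure of a wheat MET series (~200 DH
lines, 21 linkage groups, ~850 loci at ~3 cM, 6–10 environments,
2 replicates, heterogeneous genetic variance with FA-structured
between-environment correlation, spatially correlated plot noise, control
varieties, genotyping dropout). What it does not: crossover interference,
augmented/alpha-lattice designs, weather-driven trait models, multi-parent
populations, measurement-scale artefacts. Passing tests therefore
demonstrate correctness of the machinery under the model's own assumptions,
not robustness to field realities outside them.

## Study conditions used by the tests

Replicate studies are sized to run on one CPU in minutes, as the package's
own choice of experimental design:

* **Null calibration**: one DH population of 200 lines; 50 unlinked 2-marker
  groups (one interval each); 6 environments with heterogeneous *diagonal*
  genetic variance and iid residuals; 2 replicates; 200 phenotype
  re-draws → 10,000 interval tests. The generator and the fitted model use
  the same (diagonal, iid) class because a size property is only
  interpretable under a correctly specified null; FA and AR1×AR1 structures
  are exercised by their own recovery criteria and the end-to-end run.
  Measured fraction of p < 0.01 sits inside the binomial 95% band.
* **Recovery/coverage**: a QTL of effect 0.5 (genetic SD 1) planted at a
  marker; 100 populations × one phenotype draw; localization within 10 cM
  and 1.96·SE coverage at the peak (scheme `both`, so the locus itself is
  queryable).
* **Q×E discrimination**: effects ±0.6 alternating across 6 environments;
  50 replicates.
* **Trial filter**: 150 lines × 2 reps, one truly-zero-variance trial among
  three. Note a sampling fact documented here deliberately: under a null
  trial, `sigma2_g_hat = max((MSG − MSE)/r, 0)` has SD ≈ 0.08·σ²_e at this
  size, so the < 1% rule removes such a trial in roughly half of
  replicates, not nearly always; the filter's value is discrimination
  (trials with real genetic variance are essentially never dropped).
* **AR1×AR1 recovery**: a single 20×25 trial (250 lines × 2 reps),
  ρ_row = 0.5, ρ_col = 0.4, recovered within ±0.15.

## Numerical choices and limitations

* Ties in map position are broken by input order; an estimated
  recombination fraction is capped at 0.4999 before map conversion
  (unlinked markers carry no interval information).
* The distortion filter is a 1:1 chi-square with default alpha 1e-3,
  Bonferroni-corrected over markers — an explicit assumption, since the
  source workflow names no test.
* Monomorphic predictors are skipped with a warning; a singular extended
  fixed matrix skips the interval rather than aborting the scan.
* PEV blocks require a dense solve of the MME inverse (fine to a few
  thousand genetic effects; skip with `pev = FALSE` in large scans).
* The Wald test's chi-square reference is asymptotic in the number of
  lines; at 200 lines its size at 0.01 is accurate (measured above), but
  very small populations would need a finite-sample reference.
* One-stage plot-level fitting throughout; no two-stage BLUE
  summarization, no multi-trait models, no pedigree/kinship term, no
  composite-interval or multi-QTL forward selection.
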