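# metqtl

Multi-environment QTL mapping for biparental doubled-haploid (DH)
populations, built around the mixed-model workflow used for wheat
multi-environment trials (MET) under drought and heat: factor-analytic
genotype-by-environment models with spatial field residuals, marker-interval
genetic predictors, Wald-test genome scans for QTL and Q×E effects, Cullis
generalized heritability, and near-isogenic-line (NIL) fine-mapping logic.
A fully seeded DH simulator with recorded truth makes every stage testable
without field data.

## Who this is for

Quantitative geneticists and breeding-program analysts who have plot-level
MET phenotypes (environment, line, replicate, row, column, trait), a
biparental genetic map, and an A/B-coded genotype matrix, and who want a
transparent, reproducible implementation of the one-stage MET QTL analysis —
or a simulation bench to study its operating characteristics.

## The model

For plots stacked across environments the package fits, by REML,

```
y = X tau + Z u + Z_g g + e
```

* `tau` — fixed per-environment means, control-variety effects, optional
  row/column trends and covariates;
* `u` — replicate-within-environment random effects;
* `g` — genotype-by-environment effects with covariance `Sigma ⊗ I_m` across
  environments, where `Sigma` is diagonal (DIAG) or factor-analytic,
  `Sigma = Lambda Lambda' + Psi` (FA(k));
* `e` — per-environment residuals, independent or separable AR1×AR1 over the
  field row/column grid.

The workflow mirrors standard MET practice: a DIAG fit screens trials
(environments with genetic variance below 1% of residual variance are
dropped); the FA order is raised until the common factors explain over 80%
of the total between-environment genetic variance; heritability per
environment is Cullis' `h2 = 1 − PEV̄ / (2 sigma2_g)` from the BLUPs'
prediction-error variance.

For the scan, each marker interval contributes a genetic predictor: the
conditional expectation of the ±1-coded genotype given the nearest
non-missing flanking markers (Martinez–Curnow), with map distances converted
through the Kosambi function. The predictor enters the fixed part as a main
effect plus predictor-by-environment interaction (sum-to-zero coding), and
both receive Wald tests; intervals with p < 0.01 for either term merge into
QTL records with per-environment effect ranges — positive effects mean the
parent-1 (Excalibur-role) allele raises the trait.

NIL fine-mapping is formalised as set logic: sib pairs homozygous A/B across
a target interval are compared by t-test, and the QTL interval is the
intersection of the differing segments of significant pairs minus the union
of the non-significant ones.

## Worked example

```r
library(metqtl)

map <- simulate_map(map_spec(n_groups = 3, length_cM = 100, n_markers = 11),
                    seed = 1)
gen <- simulate_dh_genotypes(map, 200, seed = 2)
cfg <- sim_config(n_envs = 6, qtl = data.frame(group = "G2", pos_cM = 50,
                                               effect = 0.5),
                  Lambda = matrix(0, 6, 1), Psi = 1, n_reps = 2,
                  rep_var = 0.1, resid_sigma2 = 1, rho_row = 0, rho_col = 0,
                  seed = 3)
sim <- simulate_met_phenotypes(gen, map, cfg)

d   <- build_design(sim$phenotypes, "yld", rownames(gen),
                    model_spec("diag", residual = "iid"))
fit <- reml_fit(d)
sc  <- genome_scan(fit, predictor_matrix(gen, map))
merge_to_qtl(sc, scan_config(), map, trait = "yld")
```

which prints one detected QTL:

```
         qtl group peak_lo peak_hi left_marker right_marker term            p   effect effect_lo effect_hi
1 Qyld.mq-G2    G2      50      60      G2_m06       G2_m07 main 1.096405e-43 0.569486 0.4889565 0.6500155
```

the planted locus (G2, 50 cM, effect 0.5): the peak interval spans 50–60 cM,
the main-effect Wald test is decisive, and the ±1.96·SE interval
(0.489, 0.650) covers the simulated effect. `heritability(fit)` returns the
per-environment Cullis h² table for the same fit.

The `analysis/` directory holds the full narrative workflow over a
wheat-scale simulation (861 markers, 21 groups, 6 environments, AR1×AR1
noise, phenology confound): `01_simulate.R` → `05_nil_finemap.R`, each
writing its tables under `results/`.

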