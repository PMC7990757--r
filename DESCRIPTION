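Package: metqtl
Title: Multi-Environment QTL Mapping with Factor-Analytic Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-environment trial (MET) QTL analysis for biparental doubled
    haploid populations. Fits plot-level linear mixed models by residual maximum
    likelihood with diagonal or factor-analytic genotype-by-environment variance
    structures and separable AR1xAR1 spatial residuals, computes marker-interval
    genetic predictors as conditional expectations of the +/-1 genotype given
    flanking markers, scans the genome with Wald tests for QTL main and
    QTL-by-environment interaction effects, reports Cullis generalized
    heritability from BLUP prediction error variance, and formalises
    near-isogenic line (NIL) fine-mapping by segment/phenotype concordance.
    Includes a fully seeded doubled-haploid multi-environment simulator with
    recorded truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
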