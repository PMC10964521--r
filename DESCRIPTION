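Package: droughtscreen
Title: Drought-Stress Screening of Crop Genotypes: Tolerance Indices,
    Relative Gene Expression, Pigments and Factorial ANOVA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for yield-based drought screening of crop germplasm.
    Computes the classical stress-tolerance indices (SSI, TOL, MP, GMP,
    STI, harmonic mean), the Finlay-Wilkinson sensitivity slope, and a
    composite stress-tolerance score (STS) used to rank genotypes across
    non-stress and stress environments; quantifies relative gene
    expression from qPCR cycle-threshold tables by the 2^-ddCt (Livak)
    method with primer-efficiency estimation from dilution series;
    converts ethanol-extract absorbances to chlorophyll a, chlorophyll b
    and carotenoid concentrations; and analyses balanced two-factor
    completely randomized designs with closed-form ANOVA, CV% and
    Duncan's multiple range test.  A synthetic-data generator emulates a
    multi-environment yield trial with tolerant/sensitive archetypes and
    a greenhouse genotype-by-drought factorial so every stage of the
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, tools, utils
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
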