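Package: twinLEA
Title: Leukocyte-Endothelial Adhesion Assay Quantification and Twin
    Heritability
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput leukocyte-endothelial adhesion (LEA)
    screens run on 96-well plates and for twin-design heritability analysis
    of the resulting cellular phenotypes. Provides readers and validators
    for long-format plate readings, plate layouts, standard-curve points
    and twin/sibling pair manifests; plate quality-control statistics
    (replicate coefficient of variation, Z'-factor, signal-to-noise ratio);
    conversion of raw fluorescence to percent-input and percent-adherent-cell
    phenotypes via four-parameter logistic standard curves with
    control-anchored cross-plate standardization; and heritability
    estimation from monozygotic twin and full-sibling pairs (ANOVA
    intraclass correlation, Falconer's formula, permutation-based empirical
    p-values, confounder screening). A fully synthetic study generator with
    a specified additive genetic architecture makes every pipeline stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBasedAssays, QualityControl, Genetics, StatisticalMethod
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
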