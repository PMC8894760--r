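Package: bittertea
Title: Quantitative Analysis of Herbal-Tea Formulation Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethnobotany of herbal-tea traditions,
    built around store-level formulation surveys such as the Taiwanese
    bitter tea (ku-cha) trade. Computes per-material frequencies and use
    values, Shannon diversity of the plant-material inventory (overall and
    by region), distributions of botanical family, plant part, source,
    traditional property, flavor and function, k-way inventory overlap
    (Venn partition) comparisons, and a thresholded drug-pair co-occurrence
    network that identifies core plant materials by weighted degree. A
    seeded synthetic-survey generator reproduces the statistical structure
    of such surveys (long-tailed material popularity, truncated-Poisson
    formulation sizes, attribute marginals) so every pipeline stage is
    testable without access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
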