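Package: nodulecomm
Title: Bacterial Community Analysis for Polymetallic Nodule Field Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Community-level analysis of 16S rRNA amplicon surveys spanning
    the water column, sediments, and polymetallic nodules of abyssal nodule
    fields. Provides OTU-table input/output and preprocessing (blank-control
    subtraction, lineage filtering, relative-abundance normalization,
    rarefaction), alpha diversity (observed richness, Shannon, Chao-1),
    beta diversity from first principles (Bray-Curtis, non-metric
    multidimensional scaling, PERMANOVA, two-way ANOVA with Tukey HSD),
    occupancy-based habitat-specialization classification (specialists,
    moderate generalists, generalists), cross-habitat abundance coupling,
    a permutation-based 16S-18S co-occurrence network with FDR control,
    and a synthetic community generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS
Config/testthat/edition: 3
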