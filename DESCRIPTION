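Package: bbmpattern
Title: Expression-Pattern Analysis of the Intestinal Brush-Border Membrane Proteome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline for label-free spectral-count proteomics of
    the intestinal brush-border membrane under a 2x2 factorial design
    (genotype x treatment). Proteins are selected by hypergeometric gene-ontology
    term enrichment with Benjamini-Hochberg control, per-protein spectral counts
    are normalized to their maximum across the four pooled groups, and each
    normalized profile is classified against idealized template expression models
    by Pearson correlation with explicit change and no-change thresholds.
    Supporting quantification conventions are included: plain fold changes,
    two-way ANOVA with Sidak post-hoc comparisons, the 2^-ddCt method for qPCR,
    and vehicle-control-relative densitometry normalization. A synthetic-data
    generator with planted ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
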