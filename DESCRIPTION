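Package: dipaR
Title: Stage-Dependent Treatment-Rescue Analysis of Bulk RNA-Seq with DiPa
    Pattern Classification and Diameter Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how much of a disease-induced transcriptome
    change is reversed by a treatment, and how that rescue depends on the
    disease stage at which therapy starts. Implements two-group differential
    expression on normalized counts with volcano classification, the DiPa
    ("differentiation pattern") two-contrast geometry that assigns every gene
    to a rescue pattern group (fully rescued 1a/1b, partially rescued 2a/2b,
    not-treatable nta/ntb, drug-only 3a/3b), per-direction rescue
    percentages, extreme-deregulation subsets, and cross-stage migration of
    pattern groups. Also implements sham-referenced Tukey-fence outlier
    morphometry for structure-diameter measurements and a stratified
    subsampling stability analysis. A seeded negative-binomial synthetic-data
    generator with known gene archetypes makes the whole pipeline testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
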