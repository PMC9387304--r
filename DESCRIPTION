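Package: brimmune
Title: Immunogenomic Comparison of Primary Triple-Negative Breast Cancer
    and Brain Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the immunogenomic comparison of primary
    triple-negative breast tumors with brain metastases: multi-caller
    somatic variant consensus filtering with FFPE deamination artifact
    suppression, tumor mutational burden and matched-pair variant sharing,
    MHC class I neoantigen peptide enumeration with pluggable affinity
    prediction and binder classification, immune gene-signature metagene
    scoring with rank-based group comparison, TCR/BCR repertoire diversity
    via Shannon entropy, and multivariable Cox proportional-hazards
    survival association. Ships a seeded synthetic cohort generator with
    planted ground truth so every stage is testable without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    vcfR,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
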