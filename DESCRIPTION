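Package: methclass
Title: Tumor DNA Methylation Evidence for Classifying BRCA1 Variants of
    Uncertain Significance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a tumor-DNA-methylation pipeline for assessing the
    pathogenicity of BRCA1 unclassified variants. Methylation array probes
    that separate BRCA1-mutant from BRCA1-wild-type (BRCAx) familial breast
    tumors independently of estrogen-receptor status and grade are screened
    by rank-sum tests with false-discovery-rate control, refined by
    effect-size and SNP-confound filters, and assessed by consensus
    clustering. Validated markers feed a z-scored logistic model whose
    per-tumor probabilities of pathogenicity are converted to likelihood
    ratios, combined across independent tumors, and merged with
    sequence-bioinformatics priors (including calibrated splice-site score
    priors) into posterior probabilities and five-tier IARC classes. A
    synthetic-cohort generator emulating beta-valued methylation with
    confounded covariates and pyrosequencing dropout makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
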