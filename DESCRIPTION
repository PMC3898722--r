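Package: mirmeth
Title: Comparative-Ct qPCR Quantification and Hypermethylator Phenotype
    Scoring for Breast Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing TaqMan-style real-time PCR panels that
    profile DNMT3b-regulating microRNAs and methylation-sensitive biomarker
    genes in breast tumor cohorts. Implements comparative-Ct (2^-ddCt)
    relative quantification against a reference assay and a normal-tissue
    calibrator group, median-based binarization of expression into
    gene-expression and miR scores, rule-based hypermethylator phenotype
    classification, per-miR diagnostic threshold optimization by correct
    assignments (sensitivity, specificity, PPV, NPV), association statistics
    (subtype summaries, unpaired t-tests, Pearson correlations), and a
    synthetic cohort generator with latent hypermethylator ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
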