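Package: hepaqtl
Title: Liver eQTL Mapping, Splicing QTLs, Tissue Specificity and Correlation-Corrected Omnibus TWAS
Version: 0.1.0
Authors@R: person("Hepaqtl", "Developers", email = "hepaqtl@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for building a liver expression quantitative
    trait locus (eQTL) resource: sample-level quality control including
    genotype-expression swap detection, covariate-adjusted cis and trans
    eQTL mapping with eGene permutation p-values and allelic fold-change
    fits, exon-usage splicing QTL testing, pharmacogene-set enrichment with
    heterogeneity tests, rank-based tissue-specificity scoring, and a
    directional omnibus transcriptome-wide association (TWAS) statistic that
    corrects for correlation among expression reference panels. All stages
    are exercised on synthetic cohorts generated in-package with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
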