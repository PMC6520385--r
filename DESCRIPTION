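Package: propscreen
Title: Differentiation-Propensity Marker Screening for Pluripotent Stem Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for genes whose expression in undifferentiated
    human induced pluripotent stem cell (hiPSC) lines predicts the lines'
    propensity to differentiate into the three germ layers. Implements global
    scaling of expression microarrays with a three-step probe filter
    (present-call, one-way ANOVA, fold-range), comparative-Ct quantification of
    a trilineage qPCR marker panel, PCA summarisation and PC1-based ranking of
    cell lines, an exact permutation-null Spearman rank-correlation screen with
    small-n critical values, inverse-correlation intersection of signed
    candidate sets, and HumanMethylation450-style differential-methylation
    analysis with Benjamini-Hochberg correction and seven-category genomic
    region summaries. A synthetic-data generator with rank-level marker
    planting makes every stage testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
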