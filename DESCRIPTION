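Package: iriq
Title: Intron Retention Quantification and Cohort Stratification for RNA-Seq
Version: 0.1.0
Authors@R:
    person("iriq", "maintainers", email = "iriq@example.org", role = c("aut", "cre"))
Description: Quantifies intron retention from region-level RNA-seq read
    counts. Derives constitutive (shared) exonic and intronic regions from
    GTF gene models, computes a per-gene Intron Retention Index (IRI; the
    ratio of shared-intronic to shared-exonic read density) and per-intron
    splicing ratios (intron RPKM over the mean RPKM of the two flanking
    exons), and screens case/control cohorts: Z-score hierarchical
    clustering, pairwise sample correlation, principal component analysis
    with book-end gene selection and hypergeometric gene-set enrichment,
    exact Mann-Whitney differential intron retention with volcano
    classification, and a seeded synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
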