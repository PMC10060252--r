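# iriq — intron retention quantification and cohort stratification

`iriq` is an R package for asking whether the **global intron-retention
(IR) profile** of a case/control RNA-seq cohort is shifted — the kind of
question raised in autoimmune-disease lymphocyte transcriptomics, where
patients can show genome-wide *decreased* IR alongside increased expression
of spliceosomal genes. It is aimed at analysts who have region-level read
counts (or can produce them) and want a tested, deterministic pipeline from
gene annotation to cohort-level statistics, without re-deriving the
quantification each time.

## What it computes

- **Shared (constitutive) regions** from a GTF: a base is shared-exonic iff
  exonic in every isoform covering it and covered by all isoforms of the
  gene; shared-intronic iff intronic in all; bases exonic in some isoforms
  only are ambiguous and excluded.
- **Intron Retention Index** per gene and sample,
  `IRI = (reads/base over shared introns) / (reads/base over shared exons)`,
  analyzed as log2(IRI) on genes with shared-exonic RPKM > 1 and finite
  log2 in *every* sample (detectable-gene intersection).
- **Splicing ratio** per reference-isoform intron:
  `RPKM(intron) / mean(RPKM of the two flanking exons)`.
- **Cohort statistics**: per-sample log2 IRI histograms, pairwise Pearson
  correlation between samples, Z-score `(V - mu_i)/s_i` average-linkage
  hierarchical clustering, exact Mann–Whitney U group tests (full
  enumeration of the permutation null), and the correlation between
  per-gene IRI and expression fold changes with a 10-bin box summary.
- **PCA** of the standardized matrix (SVD of the centered data; fractions
  `f_k = sigma_k / sum(sigma_k)`), PC1 orientation, **book-end** gene
  selection (50 most-negative / 100 most-positive PC1 coefficients) and
  hypergeometric enrichment `P(X >= k)` against GMT gene sets.
- **Differential intron retention**: per-intron fold changes and exact
  Mann–Whitney p-values, volcano classes (`up`: log2 FC >= 1 and
  p <= 0.05; `down`: mirrored), dual-regulation and first-intron summaries.
- **Synthetic cohorts** with known ground truth (gene models, region
  counts, metadata), including presets for 14-vs-4 and 16-vs-4 designs
  with configured log2 IRI shifts and expression–IRI fold-change
  correlation.

## Worked example

A T-cell-like cohort (14 cases, 4 controls) at desk scale, with control
mean log2 IRI −6 shifting to −8 and fold-change correlation −0.34:

```r
library(iriq)

cfg    <- synth_preset("t_cell", seed = 7, n_genes = 500, nb_dispersion = 0)
models <- generate_gene_models(cfg)
cohort <- generate_cohort(models, cfg)

iri    <- lapply(cohort$counts, function(rc) compute_iri(cohort$models, rc))
groups <- setNames(cohort$metadata$group, cohort$metadata$sample_id)
cm     <- build_cohort_matrix(iri, groups, mode = "iri")
cm
#> <cohort_matrix> 500 genes x 18 samples (iri mode; 14 case, 4 control)

grp <- groups[cm$samples]
mean(cm$values[, grp == "control"]); mean(cm$values[, grp == "case"])
#> -6.02        # recovered control-group mean log2(IRI)
#> -7.98        # recovered case-group mean

group_mean_test(cm)$p
#> 0.00065      # exact two-sided Mann-Whitney on per-sample means
#>              # (= 2 / choose(18, 4): complete separation of the groups)

cme <- build_cohort_matrix(iri, groups, mode = "expression")
fold_change_coupling(fold_change_table(cm), fold_change_table(cme))$r
#> -0.319       # configured -0.34; n = 500 genes, se ~ 0.04

p <- orient_pc1(pca_cohort(cm))
100 * p$fractions[1:2]
#> 99.89  0.02  # PC1 carries the group shift at this noiseless setting

book_ends <- select_book_ends(p, n_neg = 50, n_pos = 100)
```

The numbers above are what the code prints at seed 7. The recovered group
means sit within 0.05 of the configured −6.0/−8.0; the group test attains
the smallest p the 14-vs-4 exact null allows; PC1 absorbs essentially all
variation because the only between-sample structure in this noiseless
synthetic setting is the group shift.

The same stages run from the command line via a JSON config:

```sh
inst/cli/iriq all --config run.json          # simulate -> ... -> diffir
```

## Layout

- `R/` — gene models (`read_gtf`, `derive_shared_regions`,
  `enumerate_reference_introns`), quantification (`compute_iri`,
  `compute_splicing_ratios`, `build_cohort_matrix`), cohort statistics,
  PCA/enrichment, differential IR, synthetic data, pipeline stages.
- `tests/testthat/` — unit + property tests with independent oracles
  (per-base region classifier, naive UPGMA, brute-force Mann–Whitney,
  explicit covariance eigendecomposition) and `test-acceptance.R`.
- `vignettes/intron-retention-methods.Rmd` — the model, its assumptions,
  the synthetic world, and the numerical design choices.
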