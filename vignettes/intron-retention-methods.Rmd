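---
title: "Quantifying intron retention in case/control RNA-seq cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention in case/control RNA-seq cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iriq)
```

## The problem iriq addresses

Intron retention (IR) — the persistence of intronic sequence in mature
transcripts when an intron escapes splicing — is a regulated layer of gene
expression. In immune-disease transcriptomics the question is often not
whether one intron in one gene is retained, but whether the *global* IR
profile of a patient cohort is shifted relative to controls, and whether
that shift couples to expression changes. `iriq` implements that analysis
as a reusable pipeline on top of region-level read counts: it never touches
reads or alignments and instead consumes a plain table of counts over
annotation-derived regions, which makes every stage testable against
synthetic data with known truth.

## The quantities

**Shared regions.** For a gene with several isoforms, a base is
*shared-exonic* if it is covered by the span of every transcript and exonic
in all of them, and *shared-intronic* if covered by every span and exonic
in none. Bases that are exonic in some isoforms and intronic in others are
*ambiguous* and are excluded from both sets. This is the strictest reading
of "constitutive": it guarantees that intronic signal is never diluted by
sequence that some isoform expresses as exon. The exclusion of ambiguous
bases (rather than majority-vote assignment) is a design choice of this
package; the alternative assigns arbitrary class to alternatively spliced
cassettes and biases the IR signal of exactly the genes where splicing is
interesting.

**Intron Retention Index.** Per gene and sample,

$$\mathrm{IRI} = \frac{\text{reads per base over shared introns}}
                     {\text{reads per base over shared exons}},$$

reported as log2(IRI). Because numerator and denominator share the library
normalization, IRI is invariant to sequencing depth; only the density ratio
matters. A gene is *detectable* when its shared-exonic RPKM exceeds 1
(excluding noisy low-expression genes) **and** both densities are positive,
so log2(IRI) is finite. The positivity condition is implied by working on a
log scale; no pseudocounts are used anywhere — undefined values are
excluded, not imputed. Cohort matrices retain exactly the genes detectable
in *every* sample, so all downstream statistics are computed on a common
gene set.

**Splicing ratio.** Per intron of a designated reference isoform,

$$\mathrm{SR} = \frac{\mathrm{RPKM}(\text{intron})}
                    {\tfrac12\left[\mathrm{RPKM}(\text{exon}_{5'}) +
                     \mathrm{RPKM}(\text{exon}_{3'})\right]},$$

low values meaning efficient splicing. The reference isoform is the
transcript with the most exons (ties: longer span, then lexicographic
transcript id) — annotation sources rarely say which isoform per-intron
analyses should use, so the package picks the one that maximizes the number
of analyzable introns and makes the choice deterministic. Intron ordinals
count in 5'→3' transcription order, so "first intron" is strand-aware.

**Cohort statistics.** Standardization uses the per-gene Z-score
$Z_i^s = (V_i^s - \mu_i)/s_i$ with the sample mean and (n−1) standard
deviation across samples; zero-variance genes are dropped and listed.
Clustering is average-linkage (UPGMA) on Euclidean distances. Group
location tests use the **exact** two-sided Mann–Whitney U: for the designs
this package targets (14–16 cases vs 4 controls) the full set of
$\binom{n}{k}$ group assignments is enumerated with mid-ranks, which *is*
the permutation distribution of the rank-sum statistic. Larger untied
designs use the classical count recursion (`stats::pwilcox`, identical to
enumeration); only large tied designs fall back to the tie-corrected normal
approximation. The two-sided p is twice the smaller tail, capped at 1.

**PCA.** Principal components of the gene–gene covariance
$C^{(ij)} = \langle \Delta g_i^s \Delta g_j^s \rangle$ are obtained by SVD
of the row-centered (by default row-standardized) matrix; the
$N_g \times N_g$ covariance is never materialized and at most $N_s - 1$
eigenvalues are nonzero. Variance fractions $f_k = \sigma_k / \sum \sigma_k$
are over all nonzero eigenvalues, and are invariant to the covariance
denominator (we use $N_s - 1$). PC1 is oriented so the majority of gene
coefficients are positive; with that convention the default book-end sizes
are asymmetric (50 most-negative, 100 most-positive coefficients), matching
the situation where ~90% of genes load positively. Book-end sets are tested
against GMT gene-set collections with the upper-tail hypergeometric
probability $P(X \ge k)$; collection sets are intersected with the
detectable population before counting $K$, since genes outside the
analyzed population cannot be drawn. Raw p-values carry the significance
flag (threshold 0.05); a Benjamini–Hochberg column is reported alongside
but not used for flagging, favoring fidelity to common practice in
enrichment reports while making the corrected values available.

**Differential IR.** Per intron, fold change is the ratio of group means of
linear splicing ratios; classes are `up` (log2 FC ≥ 1 and p ≤ 0.05), `down`
(log2 FC ≤ −1 and p ≤ 0.05), else `ns`. The |FC| ≥ 2 threshold is applied
on the log2 axis. Introns without a defined ratio in every sample, or with
a zero control mean, are excluded and counted — never assigned infinite
fold changes. Label swap maps FC → 1/FC, keeps p, and swaps classes
exactly; this is a tested invariant.

## The synthetic world

The generator emits the *stated* cohort designs, not tuned ones: presets
`t_cell` (14 cases / 4 controls, control mean log2 IRI −6.0 shifting to
−8.0, 7645 genes, fold-change correlation −0.34) and `b_cell` (16 / 4,
−3.9 → −5.2, 3621 genes, −0.062). Per gene, control log2 IRI and log2
expression are Gaussian (gene-to-gene sds of 1 by default — the spread of
typical log2 IRI histograms); the per-gene log2 fold changes of expression
and IRI are drawn *jointly* from a bivariate normal (sds 0.5) so that the
configured expression–IRI correlation holds exactly in the generative law.
This is why the configuration exposes `iri_fc_sd` (the sd of the case
shift) rather than an independent case-group sd: an independently drawn
case level cannot guarantee the fold-change correlation. Counts are drawn
negative-binomially (dispersion 0.05 by default; 0 = Poisson) around
expression × length × depth for exonic regions and around exonic density ×
IRI × planted effect for intronic regions, so the true IRI holds in
expectation and only counting noise perturbs estimates. The `deep` preset
(5000 expected reads per kb per RPKM unit, i.e. a library of 5 × 10⁹ in
RPKM arithmetic) makes per-gene log2-IRI noise < 0.05 for essentially all
genes; `moderate` and `shallow` scale that down by 100× and 2500×.

What the generator does **not** emulate: read-level artifacts (fragment
length, positional bias, mappability), within-group biological variability
beyond count noise, overlapping genes, and sequence content. A green
recovery test therefore establishes that the estimators are unbiased and
correctly plumbed at the stated designs — not that they are robust to
alignment pathologies.

## Numerical choices and edge cases

- Coordinates are 0-based half-open everywhere; GTF's 1-based closed
  convention is converted only at the reader boundary.
- Interval arithmetic is delegated to IRanges; a per-base brute-force
  classifier in the test suite verifies equivalence on random gene models.
- Clustering is backed by `stats::hclust`; an O(n³) naive average-linkage
  oracle in the tests checks merge heights, which are tie-invariant.
- Exact enumeration is capped at 2 × 10⁵ assignments; 15-vs-15 and larger
  untied designs use `pwilcox`, which evaluates the same null. The
  "≤ 30 samples" enumeration rule alone would make 15-vs-15 infeasible
  (C(30,15) ≈ 1.5 × 10⁸ assignments in interpreted R).
- Book-end ties at either cutoff are broken by gene identifier order and
  reported; PC1 orientation at an exact 50/50 coefficient split keeps the
  sign and warns.
- Histogram binning defaults to 60 equal-width bins over the pooled range
  (no binning convention is standard for log2 IRI densities); bin edges
  are configurable.
- Pipeline configs are JSON (the only declarative format with a parser in
  the package's dependency footprint); all intermediate artifacts are TSV,
  BED, GTF, GMT or Newick so any stage can run on user files.

## Known limitations

- Expression RPKM is computed over shared-exonic regions, not effective
  transcript length, for internal consistency with the IRI denominator;
  values differ from isoform-aware quantifiers on genes with long
  alternative exons.
- Region counts follow the "overlap by ≥ 1 base increments the region"
  contract; junction-read metrics (e.g. intron retention coefficients) are
  out of scope.
- Overlapping genes are processed independently — no cross-gene masking.
- The exact Mann–Whitney with 4 controls has a coarse null (minimum
  two-sided p of 2/C(n, 4)), so volcano screens at p ≤ 0.05 are
  conservative; the null-cohort type-I property in the test suite reflects
  this.
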