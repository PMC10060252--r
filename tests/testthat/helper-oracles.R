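# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (per-base loops, O(n^3) clustering, full
# permutation enumeration) and never call the code paths they check.

# --- fixtures ---------------------------------------------------------------

# gene model from a list of exon data.frames (0-based half-open)
make_gene <- function(gene_id, exon_sets, strand = "+", chrom = "chr1") {
  txs <- lapply(seq_along(exon_sets), function(i)
    new_transcript(paste0(gene_id, ".T", i),
                   data.frame(start = exon_sets[[i]][, 1],
                              end = exon_sets[[i]][, 2])))
  new_gene_model(gene_id, chrom, strand, txs)
}

ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# random small gene model for property tests
random_gene <- function(gene_id, n_tx = sample(1:5, 1)) {
  n_ex <- sample(2:8, 1)
  bounds <- sort(sample(0:400, 2 * n_ex))
  full <- matrix(bounds, ncol = 2, byrow = TRUE)
  sets <- lapply(seq_len(n_tx), function(i) {
    keep <- sort(sample(n_ex, sample(seq_len(n_ex), 1)))
    full[keep, , drop = FALSE]
  })
  make_gene(gene_id, sets, strand = sample(c("+", "-"), 1))
}

# region_counts straight from densities: every region of a prepared gene
# gets count = density * length (deterministic, no noise)
counts_from_densities <- function(gene, exon_density, intron_density,
                                  sample_id = "s1", library_size = 1e6) {
  region_rows <- function(df, class, density) {
    if (nrow(df) == 0) return(NULL)
    data.frame(gene_id = gene$gene_id, region_class = class,
               chrom = gene$chrom, start = df$start, end = df$end,
               count = density * (df$end - df$start))
  }
  rows <- rbind(region_rows(gene$shared_exons, "shared_exon", exon_density),
                region_rows(gene$shared_introns, "shared_intron",
                            intron_density))
  region_counts(sample_id, library_size, rows)
}

# --- per-base shared-region oracle ------------------------------------------

# classify every base of the union span: "exon", "intron", "ambiguous",
# "uncovered"; returns a character vector indexed by base (0-based offset+1)
per_base_classes <- function(gene) {
  lo <- min(vapply(gene$transcripts, function(t) min(t$exons$start), 0))
  hi <- max(vapply(gene$transcripts, function(t) max(t$exons$end), 0))
  bases <- lo:(hi - 1L)
  status <- vapply(bases, function(b) {
    per_tx <- vapply(gene$transcripts, function(t) {
      if (b < min(t$exons$start) || b >= max(t$exons$end)) return("out")
      if (any(b >= t$exons$start & b < t$exons$end)) "exon" else "intron"
    }, "")
    if (any(per_tx == "out")) return("uncovered")
    if (all(per_tx == "exon")) return("exon")
    if (all(per_tx == "intron")) return("intron")
    "ambiguous"
  }, "")
  names(status) <- bases
  status
}

# expand 0-based half-open intervals to the set of covered bases
bases_of <- function(df) {
  if (nrow(df) == 0) return(integer())
  unlist(Map(function(s, e) s:(e - 1L), df$start, df$end))
}

# --- naive average-linkage clustering ---------------------------------------

# O(n^3) UPGMA on a distance matrix; returns sorted merge heights
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

# --- brute-force exact Mann-Whitney -----------------------------------------

# two-sided exact p by explicit enumeration of which pooled positions go to x
brute_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(length(pooled), nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# --- constructed PCA spectra ------------------------------------------------

# centered genes x samples matrix with prescribed variance weights on
# mutually orthogonal sample factors (row means are exactly zero because
# every factor is orthogonal to the all-ones sample vector)
spectrum_matrix <- function(weights, n_genes, n_samples, seed = 1) {
  set.seed(seed)
  k <- length(weights)
  u <- qr.Q(qr(matrix(rnorm(n_genes * k), n_genes, k)))
  vbase <- cbind(1, matrix(rnorm(n_samples * k), n_samples, k))
  v <- qr.Q(qr(vbase))[, -1, drop = FALSE]   # orthonormal, orthogonal to 1
  x <- u %*% diag(sqrt(weights), k) %*% t(v)
  dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

# --- misc -------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson r from the textbook formula
naive_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

groups_of <- function(cohort) {
  setNames(cohort$metadata$group, cohort$metadata$sample_id)
}

iri_tables_of <- function(cohort) {
  lapply(cohort$counts, function(rc) compute_iri(cohort$models, rc))
}

ratio_long_of <- function(cohort) {
  data.table::rbindlist(lapply(cohort$counts, function(rc)
    data.table::data.table(sample_id = rc$sample_id,
                           compute_splicing_ratios(cohort$models, rc))))
}
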