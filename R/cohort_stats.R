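# Sample-level descriptive statistics and clustering on cohort matrices.

#' Per-gene Z-score standardization
#'
#' Z_i^s = (V_i^s - mu_i) / s_i with the per-gene mean mu_i and sample
#' standard deviation s_i (denominator N_s - 1) taken across samples. Rows
#' with zero standard deviation are excluded and listed.
#'
#' @param x a `cohort_matrix` or a numeric matrix (genes x samples).
#' @return list with `z` (standardized matrix) and `dropped` (row names with
#'   s_i = 0), class `zscore_matrix`.
#' @export
zscore_matrix <- function(x) {
  v <- if (inherits(x, "cohort_matrix")) x$values else as.matrix(x)
  mu <- rowMeans(v)
  s <- apply(v, 1L, stats::sd)
  keep <- s > 0
  z <- (v[keep, , drop = FALSE] - mu[keep]) / s[keep]
  structure(list(z = z, dropped = rownames(v)[!keep]),
            class = "zscore_matrix")
}

#' Per-sample log2 IRI histograms
#'
#' Density histograms of per-gene log2 IRI, one per sample, on a common set
#' of bin edges (default: `bins` equal-width bins over the pooled range),
#' plus a per-sample mean/sd summary.
#'
#' @param cm a `cohort_matrix` in `"iri"` mode.
#' @param bins either a single bin count or a vector of bin edges.
#' @return list with `edges`, `density` (bins x samples matrix; each column
#'   integrates to 1), and `summary` (data.table: sample, group, mean, sd).
#' @export
log2_iri_histogram <- function(cm, bins = 60) {
  stopifnot(inherits(cm, "cohort_matrix"))
  if (cm$mode != "iri") stop("histogram requires a cohort matrix in iri mode")
  v <- cm$values
  if (length(unique(as.vector(v))) < 2L)
    stop("fewer than 2 distinct values")
  edges <- if (length(bins) == 1L)
    seq(min(v), max(v), length.out = bins + 1L) else sort(bins)
  dens <- vapply(cm$samples, function(s) {
    h <- graphics::hist(v[, s], breaks = edges, plot = FALSE)
    h$density
  }, numeric(length(edges) - 1L))
  summ <- data.table::data.table(
    sample = cm$samples, group = unname(cm$groups[cm$samples]),
    mean = colMeans(v), sd = apply(v, 2L, stats::sd))
  list(edges = edges, density = dens, summary = summ)
}

#' Pairwise Pearson correlation between samples
#'
#' Correlation of per-gene value vectors (log2 IRI or expression) over the
#' common gene rows, for every pair of samples. Constant sample vectors get
#' NA rows/columns with a warning.
#'
#' @param cm a `cohort_matrix` or numeric matrix (genes x samples).
#' @return symmetric N_s x N_s matrix with unit diagonal.
#' @export
pairwise_sample_correlation <- function(cm) {
  v <- if (inherits(cm, "cohort_matrix")) cm$values else as.matrix(cm)
  if (nrow(v) < 3L) stop("need at least 3 genes")
  const <- apply(v, 2L, stats::sd) == 0
  r <- suppressWarnings(stats::cor(v))
  if (any(const)) {
    warning("constant sample vector(s): ",
            paste(colnames(v)[const], collapse = ", "))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Average-linkage hierarchical clustering
#'
#' Agglomerative clustering with Euclidean distance and average (UPGMA)
#' linkage, on either the sample columns or the gene rows of a standardized
#' matrix.
#'
#' @param z a `zscore_matrix`, `cohort_matrix`, or numeric matrix.
#' @param axis `"samples"` (cluster columns) or `"genes"` (cluster rows).
#' @return an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(z, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  v <- if (inherits(z, "zscore_matrix")) z$z
       else if (inherits(z, "cohort_matrix")) z$values
       else as.matrix(z)
  m <- if (axis == "samples") t(v) else v
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Serialize a dendrogram as a Newick string
#'
#' @param hc an [stats::hclust] object.
#' @param digits branch-length digits.
#' @return single Newick string (heights become branch lengths).
#' @export
dendrogram_newick <- function(hc, digits = 6) {
  lab <- hc$labels
  node_h <- c()
  build <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%s", lab[-i], format(parent_h, digits = digits))
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%s",
              build(hc$merge[i, 1L], h), build(hc$merge[i, 2L], h),
              format(parent_h - h, digits = digits))
    }
  }
  n <- nrow(hc$merge)
  top <- hc$height[n]
  paste0(sub(":[^:]*$", "", build(n, top)), ";")
}

#' Mann-Whitney test on per-sample mean values
#'
#' Compares the per-sample means of the cohort matrix (e.g. mean log2 IRI
#' per sample) between case and control groups with the exact two-sided
#' Mann-Whitney U test ([exact_mann_whitney()]).
#'
#' @param cm a `cohort_matrix` with both groups non-empty.
#' @return list: `p`, `statistic`, `method`, `sample_means` (named), and the
#'   two group mean-of-means.
#' @export
group_mean_test <- function(cm) {
  stopifnot(inherits(cm, "cohort_matrix"))
  means <- colMeans(cm$values)
  grp <- cm$groups[cm$samples]
  if (!all(c("case", "control") %in% grp))
    stop("both groups must be non-empty")
  mw <- exact_mann_whitney(means[grp == "case"], means[grp == "control"])
  list(p = mw$p, statistic = mw$statistic, method = mw$method,
       sample_means = means,
       case_mean = mean(means[grp == "case"]),
       control_mean = mean(means[grp == "control"]))
}

#' Per-gene case/control fold changes
#'
#' Fold change is the ratio of the group means of the linear-scale values
#' (IRI or RPKM): mean(case) / mean(control). For an `"iri"`-mode matrix the
#' stored log2 values are exponentiated first. Genes whose control mean is
#' not positive get NA.
#'
#' @param cm a `cohort_matrix`.
#' @return data.table: `gene_id`, `case_mean`, `control_mean`, `fc`,
#'   `log2_fc`.
#' @export
fold_change_table <- function(cm) {
  stopifnot(inherits(cm, "cohort_matrix"))
  v <- cm$values
  if (cm$mode == "iri") v <- 2^v
  grp <- cm$groups[cm$samples]
  case_mean <- rowMeans(v[, grp == "case", drop = FALSE])
  control_mean <- rowMeans(v[, grp == "control", drop = FALSE])
  fc <- ifelse(control_mean > 0, case_mean / control_mean, NA_real_)
  data.table::data.table(gene_id = cm$genes, case_mean = case_mean,
                         control_mean = control_mean, fc = fc,
                         log2_fc = ifelse(!is.na(fc) & fc > 0, log2(fc),
                                          NA_real_))
}

#' Correlation between IRI and expression fold changes
#'
#' Pearson correlation (with two-sided p from the t transform) of per-gene
#' log2 fold changes of IRI against expression, plus a 10-bin box summary:
#' genes are sorted by IRI fold change and split into `n_bins` equal-count
#' bins (remainder genes go to the leftmost bins); each bin reports the
#' quartiles/whiskers of the expression log2 fold change and its mean IRI
#' log2 fold change.
#'
#' @param iri_fc,expr_fc [fold_change_table()] outputs for the IRI and
#'   expression cohort matrices (matched on `gene_id`).
#' @param n_bins number of equal-count bins (default 10).
#' @return list: `r`, `p`, `n`, `dropped`, `bins` (data.table).
#' @export
fold_change_coupling <- function(iri_fc, expr_fc, n_bins = 10) {
  m <- merge(iri_fc[, .(gene_id, iri_log2_fc = log2_fc)],
             expr_fc[, .(gene_id, expr_log2_fc = log2_fc)],
             by = "gene_id")
  n0 <- nrow(m)
  m <- m[is.finite(iri_log2_fc) & is.finite(expr_log2_fc)]
  dropped <- n0 - nrow(m)
  if (dropped > 0)
    message("fold_change_coupling: dropped ", dropped,
            " gene(s) with undefined fold changes")
  if (nrow(m) < 3L) stop("need at least 3 genes with defined fold changes")
  ct <- stats::cor.test(m$iri_log2_fc, m$expr_log2_fc, method = "pearson")
  data.table::setorder(m, iri_log2_fc)
  n <- nrow(m)
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n - base * n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  m[, bin := rep(seq_len(n_bins), times = sizes)]
  bins <- m[, {
    bs <- grDevices::boxplot.stats(expr_log2_fc)
    .(n = .N, iri_log2_fc_mean = mean(iri_log2_fc),
      expr_median = stats::median(expr_log2_fc),
      expr_q1 = stats::quantile(expr_log2_fc, 0.25, names = FALSE),
      expr_q3 = stats::quantile(expr_log2_fc, 0.75, names = FALSE),
      expr_whisker_lo = bs$stats[1L], expr_whisker_hi = bs$stats[5L])
  }, by = bin]
  list(r = unname(ct$estimate), p = ct$p.value, n = n, dropped = dropped,
       bins = bins[])
}
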