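# PCA of standardized cohort matrices across samples, book-end gene
# selection on PC1, and hypergeometric gene-set enrichment.

#' Principal component analysis of a cohort matrix
#'
#' Eigen-structure of the gene-gene covariance C^(ij) = <dg_i dg_j> (sample
#' covariance with denominator N_s - 1), obtained by singular value
#' decomposition of the row-centered matrix -- the N_g x N_g covariance is
#' never materialized, so at most N_s - 1 nonzero eigenvalues exist.
#' Fractions f_k = sigma_k / sum(sigma_k) are over all nonzero eigenvalues.
#'
#' @param x a `cohort_matrix` or numeric matrix (genes x samples).
#' @param standardize Z-score gene rows first (the default, matching PCA on
#'   standardized values); otherwise rows are only centered.
#' @return a `pca_result`: `eigenvalues` (sigma_k, descending), `fractions`
#'   (f_k), `components` (genes x k matrix of gene coefficients P_k),
#'   `projections` (samples x k coordinates), `genes`, `samples`,
#'   `dropped` (zero-variance genes when standardizing), `pc1_flipped`.
#' @export
pca_cohort <- function(x, standardize = TRUE) {
  v <- if (inherits(x, "cohort_matrix")) x$values else as.matrix(x)
  if (ncol(v) < 3L) stop("need at least 3 samples")
  dropped <- character()
  if (standardize) {
    zs <- zscore_matrix(v)
    v <- zs$z
    dropped <- zs$dropped
  }
  if (nrow(v) < 2L) stop("fewer than 2 usable gene rows")
  centered <- v - rowMeans(v)
  if (all(abs(centered) < 1e-12)) stop("zero-variance matrix")
  sv <- svd(centered)
  ns <- ncol(v)
  eig <- sv$d^2 / (ns - 1)
  keep <- which(eig > max(eig) * 1e-12)
  keep <- keep[seq_len(min(length(keep), ns - 1L))]
  eig <- eig[keep]
  comp <- sv$u[, keep, drop = FALSE]
  rownames(comp) <- rownames(v)
  proj <- sv$v[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = length(keep))
  rownames(proj) <- colnames(v)
  colnames(comp) <- colnames(proj) <- paste0("PC", seq_along(keep))
  structure(list(eigenvalues = eig, fractions = eig / sum(eig),
                 components = comp, projections = proj,
                 genes = rownames(v), samples = colnames(v),
                 dropped = dropped, pc1_flipped = FALSE),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d genes, %d samples, %d component(s)\n",
              length(x$genes), length(x$samples), length(x$eigenvalues)))
  cat("  variance fractions:",
      paste0(sprintf("%.2f%%", 100 * utils::head(x$fractions, 3L)),
             collapse = ", "), "...\n")
  invisible(x)
}

#' Orient PC1 so most gene coefficients are positive
#'
#' Flips the sign of PC1 (component and sample projections) when the
#' majority of gene coefficients are negative; an exact 50/50 split keeps
#' the sign with a warning. The flip is recorded in `pc1_flipped`.
#'
#' @param p a `pca_result`.
#' @return the (possibly flipped) `pca_result`.
#' @export
orient_pc1 <- function(p) {
  stopifnot(inherits(p, "pca_result"))
  pos <- sum(p$components[, 1L] > 0)
  neg <- sum(p$components[, 1L] < 0)
  if (pos == neg) {
    warning("PC1 coefficients split exactly 50/50; keeping sign")
    return(p)
  }
  if (neg > pos) {
    p$components[, 1L] <- -p$components[, 1L]
    p$projections[, 1L] <- -p$projections[, 1L]
    p$pc1_flipped <- TRUE
  }
  p
}

#' Select book-end genes on PC1
#'
#' The `n_neg` genes with the most negative PC1 coefficients and the `n_pos`
#' genes with the most positive coefficients. Ties at either cutoff are
#' broken by gene identifier order (and reported via a message).
#'
#' @param p a `pca_result` (orient with [orient_pc1()] first if desired).
#' @param n_neg,n_pos set sizes (defaults 50 and 100).
#' @return list with `negative_set`, `positive_set` (character vectors) and
#'   `orientation` (`pc1_flipped` flag of the input).
#' @export
select_book_ends <- function(p, n_neg = 50, n_pos = 100) {
  stopifnot(inherits(p, "pca_result"))
  coef <- p$components[, 1L]
  ids <- p$genes
  if (length(ids) < n_neg + n_pos)
    stop("need at least ", n_neg + n_pos, " genes")
  asc <- order(coef, ids)
  neg <- ids[asc][seq_len(n_neg)]
  desc <- order(-coef, ids)
  pos <- ids[desc][seq_len(n_pos)]
  if (n_neg > 0 && n_neg < length(ids) &&
      coef[asc][n_neg] == coef[asc][n_neg + 1L])
    message("select_book_ends: tie at the negative cutoff broken by gene id")
  if (n_pos > 0 && n_pos < length(ids) &&
      coef[desc][n_pos] == coef[desc][n_pos + 1L])
    message("select_book_ends: tie at the positive cutoff broken by gene id")
  list(negative_set = neg, positive_set = pos, orientation = p$pc1_flipped)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT format error at line ", bad[1L],
         ": need name, description and at least one gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric probability of observing at least k genes from
#' a set in a subset of size n drawn from a population of size N containing
#' K set members: p = sum_{j >= k} C(K,j) C(N-K, n-j) / C(N,n). Collection
#' sets are intersected with the population before counting K. Raw p-values
#' carry the paper-style significance flag at `alpha`; a Benjamini-Hochberg
#' q-value column is provided alongside.
#'
#' @param subset character vector, must be a subset of `population`.
#' @param population character vector of all eligible genes.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha significance threshold on the raw p (default 0.05).
#' @return data.table sorted by p: `set`, `N`, `K`, `n`, `k`, `p`,
#'   `significant`, `q`.
#' @export
hypergeom_enrichment <- function(subset, population, collection,
                                 alpha = 0.05) {
  population <- unique(population)
  subset <- unique(subset)
  if (length(population) == 0L) stop("empty population")
  if (!all(subset %in% population))
    stop("subset must be contained in the population")
  N <- length(population)
  n <- length(subset)
  res <- data.table::rbindlist(lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], population)
    K <- length(members)
    k <- length(intersect(members, subset))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.table::data.table(set = nm, N = N, K = K, n = n, k = k, p = p)
  }))
  res[, significant := p < alpha]
  res[, q := stats::p.adjust(p, method = "BH")]
  data.table::setorder(res, p, set)
  res[]
}
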