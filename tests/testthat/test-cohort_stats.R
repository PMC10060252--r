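# cohort_stats: Z-scores, histograms, correlations, clustering, fold changes

make_cm <- function(v, groups, mode = "iri") {
  structure(list(values = v, genes = rownames(v), samples = colnames(v),
                 groups = groups, mode = mode, n_common = nrow(v)),
            class = "cohort_matrix")
}

test_that("zscore rows have mean 0 / sd 1 and zero-sd rows are listed", {
  set.seed(10)
  v <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  v[3, ] <- 7
  z <- zscore_matrix(v)
  expect_equal(z$dropped, "g3")
  expect_equal(unname(rowMeans(z$z)), rep(0, 7), tolerance = 1e-10)
  expect_equal(unname(apply(z$z, 1, sd)), rep(1, 7), tolerance = 1e-10)
  # idempotence up to tolerance
  z2 <- zscore_matrix(z$z)
  expect_equal(z2$z, z$z, tolerance = 1e-10)
})

test_that("log2 IRI histograms integrate to 1 and recover sample means", {
  set.seed(11)
  v <- matrix(rnorm(4000, -6, 1), 1000, 4,
              dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:4)))
  v[, 3:4] <- v[, 3:4] - 2
  cm <- make_cm(v, setNames(c("control", "control", "case", "case"),
                            paste0("s", 1:4)))
  h <- log2_iri_histogram(cm, bins = 60)
  widths <- diff(h$edges)
  for (s in 1:4)
    expect_equal(sum(h$density[, s] * widths), 1, tolerance = 1e-9)
  expect_equal(h$summary$mean, unname(colMeans(v)))
  expect_lt(abs(h$summary$mean[1] - -6), 0.1)
  expect_lt(abs(h$summary$mean[3] - -8), 0.1)
  # identical samples give identical densities
  v2 <- cbind(v[, 1], v[, 1], v[, 2])
  colnames(v2) <- paste0("s", 1:3)
  cm2 <- make_cm(v2, setNames(c("case", "case", "control"), paste0("s", 1:3)))
  h2 <- log2_iri_histogram(cm2, bins = 30)
  expect_equal(h2$density[, 1], h2$density[, 2])
  # degenerate matrix
  cmc <- make_cm(matrix(-6, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3])),
                 setNames(c("case", "case", "control"), LETTERS[1:3]))
  expect_error(log2_iri_histogram(cmc), "distinct")
})

test_that("pairwise correlations: duplicates, negation, formula oracle", {
  set.seed(12)
  v <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("g", 1:4),
                                               c("a", "b", "c")))
  v[, 2] <- v[, 1]
  v[, 3] <- -v[, 1]
  r <- pairwise_sample_correlation(v)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)

  v2 <- matrix(c(1, 4, 2, 8, 3, 5, 9, 2, 7, 1, 6, 4), 4, 3,
               dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  r2 <- pairwise_sample_correlation(v2)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(r2[i, j], naive_pearson(v2[, i], v2[, j]))
  expect_equal(r2, t(r2))
  expect_equal(diag(r2), setNames(rep(1, 3), c("a", "b", "c")))
  # positive semidefinite up to tolerance
  expect_gte(min(eigen(r2, symmetric = TRUE)$values), -1e-10)

  vc <- v2; vc[, 2] <- 5
  expect_warning(rc <- pairwise_sample_correlation(vc), "constant")
  expect_true(all(is.na(rc["b", c("a", "c")])))
  expect_equal(rc["b", "b"], 1)
})

test_that("average-linkage clustering matches the naive UPGMA oracle", {
  # two close points and one far: first merge joins the close pair
  m <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  hc <- hierarchical_cluster(m, axis = "genes")
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))
  expect_equal(hc$height[1], 1)
  expect_equal(hc$height[2], mean(c(10, 9)))

  # duplicates merge at height 0
  md <- rbind(a = c(1, 1), b = c(1, 1), c = c(3, 3))
  expect_equal(hierarchical_cluster(md, axis = "genes")$height[1], 0)

  set.seed(13)
  for (i in 1:5) {
    x <- matrix(rnorm(6 * 4), 6, 4,
                dimnames = list(paste0("it", 1:6), paste0("d", 1:4)))
    hc <- hierarchical_cluster(x, axis = "genes")
    expect_equal(sort(hc$height), naive_average_linkage_heights(dist(x)),
                 info = paste("case", i))
  }
  # sample-axis clustering transposes
  hs <- hierarchical_cluster(t(m), axis = "samples")
  expect_equal(sort(hs$height), sort(hc_heights <- hierarchical_cluster(
    m, axis = "genes")$height))
})

test_that("dendrogram newick serialization is parseable and height-true", {
  set.seed(14)
  x <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  hc <- hierarchical_cluster(x, axis = "genes")
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, ";$")
  for (s in rownames(x)) expect_match(nwk, s, fixed = TRUE)
  expect_equal(sum(gregexpr("(", nwk, fixed = TRUE)[[1]] > 0), 4L)
})

test_that("fold changes are ratios of linear group means", {
  # gA linear: case (2,4), control (1,2); gB: case (8,16), control (1,2)
  v <- matrix(log2(c(2, 8,  4, 16,  1, 1,  2, 2)), nrow = 2,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  cm <- make_cm(v, setNames(c("case", "case", "control", "control"),
                            paste0("s", 1:4)))
  fc <- fold_change_table(cm)
  expect_equal(fc$fc, c(2, 8))
  expect_equal(fc$log2_fc, c(1, 3))
  # expression mode uses values as-is (linear)
  cme <- make_cm(2^v, setNames(c("case", "case", "control", "control"),
                               paste0("s", 1:4)), mode = "expression")
  expect_equal(fold_change_table(cme)$fc, c(2, 8))
  # zero control mean -> NA
  v0 <- 2^v; v0["gA", 3:4] <- 0
  cm0 <- make_cm(v0, setNames(c("case", "case", "control", "control"),
                              paste0("s", 1:4)), mode = "expression")
  expect_true(is.na(fold_change_table(cm0)$fc[1]))
})

test_that("fold-change coupling: exact anti-linearity, null, bins", {
  ids <- sprintf("g%04d", 1:1000)
  set.seed(15)
  lfc <- rnorm(1000)
  iri_fc <- data.table::data.table(gene_id = ids, fc = 2^lfc, log2_fc = lfc)
  expr_fc <- data.table::data.table(gene_id = ids, fc = 2^-lfc,
                                    log2_fc = -lfc)
  cp <- fold_change_coupling(iri_fc, expr_fc)
  expect_equal(cp$r, -1, tolerance = 1e-12)

  # independent fold changes: |r| small
  expr0 <- data.table::data.table(gene_id = ids, fc = 1,
                                  log2_fc = rnorm(1000))
  cp0 <- fold_change_coupling(iri_fc, expr0)
  expect_lt(abs(cp0$r), 0.1)
  expect_gt(cp0$p, 1e-6)

  # 10 equal-count bins; remainder genes go to the leftmost bins
  cp3 <- fold_change_coupling(iri_fc[1:103], expr0[1:103])
  expect_equal(cp3$bins$n, c(11L, 11L, 11L, rep(10L, 7)))
  expect_equal(sum(cp3$bins$n), 103L)
  expect_true(all(diff(cp3$bins$iri_log2_fc_mean) > 0))

  # invariant to gene order relabeling
  perm <- sample(1000)
  cpp <- fold_change_coupling(iri_fc[perm], expr0)
  expect_equal(cpp$r, cp0$r)
})
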