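# differential_ir: group tests on splicing ratios, volcano classes,
# dual regulation

# long ratio table from a matrix of introns x samples
ratio_long <- function(m, samples) {
  data.table::rbindlist(lapply(seq_len(nrow(m)), function(i) {
    key <- strsplit(rownames(m)[i], "\\|")[[1]]
    data.table::data.table(sample_id = samples, gene_id = key[1],
                           ordinal = as.integer(key[2]), ratio = m[i, ])
  }))
}

two_group <- function(n_case, n_control) {
  samples <- c(sprintf("ca%02d", seq_len(n_case)),
               sprintf("co%02d", seq_len(n_control)))
  groups <- setNames(rep(c("case", "control"), c(n_case, n_control)),
                     samples)
  list(samples = samples, groups = groups)
}

test_that("fold change, exact p, and classification contracts", {
  g <- two_group(16, 4)
  m <- rbind(
    "gA|1" = c(rep(0.4, 16), rep(0.1, 4)),             # 4x up, separated
    "gB|1" = c(seq(0.1, 0.25, length.out = 16) + 0.001,
               seq(0.1, 0.25, length.out = 4)),        # ns: tiny difference
    "gC|1" = rep(0.2, 20))                             # identical groups
  rec <- differential_test(ratio_long(m, g$samples), g$groups)
  a <- rec[gene_id == "gA"]
  expect_equal(a$fold_change, 4)
  expect_equal(a$p, 2 / choose(20, 4))
  expect_equal(a$class, "up")
  expect_equal(rec[gene_id == "gC"]$fold_change, 1)
  expect_equal(rec[gene_id == "gC"]$class, "ns")
  # large fold change without significance stays ns
  b <- rec[gene_id == "gB"]
  expect_equal(b$class, "ns")
})

test_that("fold-change gate: fc >= 2 with p > 0.05 is ns", {
  g <- two_group(5, 4)
  # case mean 3x control but heavily overlapping -> p large
  m <- rbind("gD|1" = c(9, 0.1, 0.1, 0.2, 5.6, 1, 1, 1, 1))
  rec <- differential_test(ratio_long(m, g$samples), g$groups)
  expect_gt(rec$fold_change, 2)
  expect_gt(rec$p, 0.05)
  expect_equal(rec$class, "ns")
})

test_that("exclusions: incomplete introns and zero control means", {
  g <- two_group(3, 2)
  m <- rbind("gA|1" = c(1, 1, 1, 2, 2),
             "gB|1" = c(1, 1, 1, 0, 0),     # control mean 0
             "gC|1" = c(1, 1, NA, 2, 2))    # missing in one sample
  expect_message(
    expect_message(rec <- differential_test(ratio_long(m, g$samples),
                                            g$groups),
                   "without a defined ratio"),
    "zero control mean")
  expect_equal(rec$gene_id, "gA")
  expect_error(differential_test(ratio_long(m, g$samples),
                                 setNames(rep("case", 5), g$samples)),
               "group")
})

test_that("label swap inverts fold changes, keeps p, swaps classes", {
  set.seed(30)
  g <- two_group(6, 6)
  m <- matrix(rexp(12 * 12, 5), 12, 12,
              dimnames = list(sprintf("g%02d|%d", 1:12,
                                      rep(1:3, 4)), NULL))
  m[1:3, 1:6] <- m[1:3, 1:6] * 8
  rec <- differential_test(ratio_long(m, g$samples), g$groups)
  swapped <- setNames(ifelse(g$groups == "case", "control", "case"),
                      names(g$groups))
  rec2 <- differential_test(ratio_long(m, g$samples), swapped)
  expect_equal(rec2$fold_change, 1 / rec$fold_change)
  expect_equal(rec2$p, rec$p)
  expect_equal(rec2$class,
               c(up = "down", down = "up", ns = "ns")[rec$class],
               ignore_attr = TRUE)
  # classification is a pure function of the inputs
  expect_identical(differential_test(ratio_long(m, g$samples), g$groups), rec)
})

test_that("volcano and dual-regulation summaries do set algebra", {
  rec <- data.table::data.table(
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gD"),
    ordinal = c(1L, 2L, 1L, 2L, 1L, 2L),
    fold_change = c(4, 0.2, 4, 4, 1, 0.3),
    log2_fc = log2(c(4, 0.2, 4, 4, 1, 0.3)),
    p = c(0.01, 0.01, 0.01, 0.01, 0.9, 0.01),
    class = c("up", "down", "up", "up", "ns", "down"))
  vt <- volcano_table(rec)
  expect_equal(vt[c("total", "up", "down", "up_genes", "down_genes")],
               list(total = 6L, up = 3L, down = 2L, up_genes = 2L,
                    down_genes = 2L))
  dual <- dual_regulation_summary(rec)
  expect_equal(dual$genes_with_both, "gA")
  expect_equal(dual$frac_first_up, 1)
  expect_equal(dual$frac_first_down, 0)
  # no dual genes -> fractions absent
  dual0 <- dual_regulation_summary(rec[gene_id != "gA"])
  expect_length(dual0$genes_with_both, 0)
  expect_true(is.na(dual0$frac_first_up))
  # no significant introns
  vt0 <- volcano_table(rec[class == "ns"])
  expect_equal(vt0$up + vt0$down, 0L)
})

test_that("null cohort keeps the p <= 0.05 fraction below 0.075", {
  cfg <- synth_config(seed = 31, n_genes = 260, n_case = 16, n_control = 4,
                      coverage = "moderate", nb_dispersion = 0.05,
                      control_log2_iri_mean = -3, case_log2_iri_mean = -3,
                      fraction_shifted = 0, iri_fc_sd = 0, expr_fc_sd = 0,
                      isoform_fraction = 0)
  co <- generate_cohort(generate_gene_models(cfg), cfg)
  rec <- differential_test(ratio_long_of(co), groups_of(co))
  expect_gt(nrow(rec), 800)
  expect_lte(mean(rec$p <= 0.05), 0.075)
})

test_that("planted effects are recovered at high power", {
  cfg <- synth_config(seed = 32, n_genes = 150, n_case = 14, n_control = 4,
                      coverage = "deep", nb_dispersion = 0,
                      control_log2_iri_mean = -4, case_log2_iri_mean = -4,
                      fraction_shifted = 0, iri_fc_sd = 0, expr_fc_sd = 0,
                      isoform_fraction = 0,
                      planted = list(frac_up = 0.08, frac_down = 0.12,
                                     effect_size = 4))
  co <- generate_cohort(generate_gene_models(cfg), cfg)
  rec <- differential_test(ratio_long_of(co), groups_of(co))
  truth <- co$truth$introns
  n_up_planted <- sum(truth$truth_class == "up")
  n_down_planted <- sum(truth$truth_class == "down")
  vt <- volcano_table(rec)
  expect_lte(abs(vt$up - n_up_planted), 5)
  expect_lte(abs(vt$down - n_down_planted), 5)
  merged <- merge(rec, truth, by = c("gene_id", "ordinal"))
  called <- merged[class != "ns"]
  sens <- mean(merged[truth_class != "null"]$class != "ns")
  fdr <- if (nrow(called)) mean(called$truth_class == "null") else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})
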