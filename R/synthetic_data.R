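# Seeded synthetic cohorts with known ground truth.
#
# The generator emits gene models (GTF-writable) and two-group region-level
# count tables whose generative law fixes: per-gene control log2 IRI, the
# case-group shift, per-gene expression, the correlation between expression
# and IRI log2 fold changes (drawn jointly from a bivariate normal), and
# planted per-intron retention effects. True IRI is enforced in expectation
# (intronic density = exonic density x IRI), so only counting noise
# perturbs estimates; the "deep" preset makes that noise negligible.

.coverage_depth <- c(deep = 5000, moderate = 50, shallow = 2)

#' Synthetic cohort configuration
#'
#' @param seed RNG seed (gene models use `seed`, the cohort `seed + 1`).
#' @param n_genes number of genes.
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param exon_length,intron_length inclusive base-pair ranges.
#' @param n_case,n_control group sizes.
#' @param coverage `"deep"` (expected exonic coverage ~hundreds of reads per
#'   base, log2-IRI noise < 0.05), `"moderate"`, or `"shallow"`.
#' @param control_log2_iri_mean,control_log2_iri_sd gene-level log2 IRI
#'   distribution in the control group.
#' @param case_log2_iri_mean target case-group mean log2 IRI; shifted genes
#'   receive the difference to the control mean.
#' @param fraction_shifted fraction of genes receiving the case shift.
#' @param expr_log2_mean,expr_log2_sd gene-level log2 RPKM distribution.
#' @param expr_fc_sd,iri_fc_sd standard deviations of the per-gene log2 fold
#'   changes in expression and IRI.
#' @param expr_iri_fc_correlation correlation of the two fold-change noise
#'   components (in [-1, 1]); exact in the generative law when
#'   `fraction_shifted` is 0 or 1.
#' @param planted list with `frac_up`, `frac_down`, `effect_size`:
#'   fractions of reference introns given a multiplicative case-group
#'   splicing-ratio effect (x effect_size / / effect_size).
#' @param nb_dispersion negative-binomial dispersion of region counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param isoform_fraction fraction of genes with a second, exon-skipping
#'   isoform (exercises ambiguous-region logic).
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_genes = 200L,
                         exons_per_gene = c(2L, 8L),
                         exon_length = c(100L, 300L),
                         intron_length = c(500L, 2000L),
                         n_case = 14L, n_control = 4L,
                         coverage = c("deep", "moderate", "shallow"),
                         control_log2_iri_mean = -6, control_log2_iri_sd = 1,
                         case_log2_iri_mean = -6, fraction_shifted = 1,
                         expr_log2_mean = 6, expr_log2_sd = 1,
                         expr_fc_sd = 0.5, iri_fc_sd = 0.5,
                         expr_iri_fc_correlation = 0,
                         planted = list(frac_up = 0, frac_down = 0,
                                        effect_size = 4),
                         nb_dispersion = 0.05,
                         isoform_fraction = 0.2) {
  coverage <- match.arg(coverage)
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1,
              length(exons_per_gene) == 2, exons_per_gene[1] >= 2,
              exons_per_gene[2] >= exons_per_gene[1],
              exon_length[1] >= 1, intron_length[1] >= 1,
              fraction_shifted >= 0, fraction_shifted <= 1,
              isoform_fraction >= 0, isoform_fraction <= 1,
              abs(expr_iri_fc_correlation) <= 1,
              nb_dispersion >= 0,
              planted$frac_up >= 0, planted$frac_down >= 0,
              planted$frac_up + planted$frac_down <= 1,
              planted$effect_size > 0)
  })
  structure(cfg, class = "synth_config")
}

#' Cohort presets named after the study designs they emulate
#'
#' `"t_cell"`: 14 cases vs 4 controls, control mean log2 IRI -6.0 shifting
#' to -8.0, fold-change correlation -0.34, 7645 genes. `"b_cell"`: 16 vs 4,
#' -3.9 shifting to -5.2, correlation -0.062, 3621 genes.
#'
#' @param name `"t_cell"` or `"b_cell"`.
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_preset <- function(name = c("t_cell", "b_cell"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    t_cell = list(n_genes = 7645L, n_case = 14L, n_control = 4L,
                  control_log2_iri_mean = -6, case_log2_iri_mean = -8,
                  expr_iri_fc_correlation = -0.34),
    b_cell = list(n_genes = 3621L, n_case = 16L, n_control = 4L,
                  control_log2_iri_mean = -3.9, case_log2_iri_mean = -5.2,
                  expr_iri_fc_correlation = -0.062))
  over <- list(...)
  do.call(synth_config, utils::modifyList(base, over))
}

#' Generate synthetic gene models
#'
#' Deterministic under `config$seed`. Genes selected for a second isoform
#' get at least 3 exons and an exon-skipping transcript, producing an
#' ambiguous region for the shared-region logic.
#'
#' @param config a [synth_config()].
#' @return named list of `gene_model` objects (shared regions unset).
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cursor <- 1000L
  models <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%05d", g)
    has_iso <- stats::runif(1) < config$isoform_fraction
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
    if (has_iso) n_ex <- max(n_ex, 3L)
    ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                     replace = TRUE)
    in_len <- if (n_ex > 1L)
      sample(config$intron_length[1]:config$intron_length[2], n_ex - 1L,
             replace = TRUE) else integer()
    starts <- ends <- integer(n_ex)
    pos <- cursor
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + ex_len[i]
      pos <- ends[i] + if (i < n_ex) in_len[i] else 0L
    }
    strand <- sample(c("+", "-"), 1L)
    exons <- data.table::data.table(start = starts, end = ends)
    txs <- list(new_transcript(paste0(gid, ".T1"), exons))
    if (has_iso) {
      skip <- (2:(n_ex - 1L))[sample.int(n_ex - 2L, 1L)]  # internal exon
      txs <- c(txs, list(new_transcript(paste0(gid, ".T2"), exons[-skip])))
    }
    models[[g]] <- new_gene_model(gid, "chr1", strand, txs)
    cursor <- pos + 10000L
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models
}

#' Write gene models to GTF (1-based closed, exon features)
#'
#' @param models list of `gene_model` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(g) {
    unlist(lapply(g$transcripts, function(t) {
      sprintf('%s\tiriq\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
              g$chrom, t$exons$start + 1L, t$exons$end, g$strand,
              g$gene_id, t$transcript_id)
    }))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Draw joint per-gene fold changes
#'
#' The per-gene log2 fold changes of expression and IRI are drawn from a
#' bivariate normal: `de = expr_fc_sd * (rho z1 + sqrt(1-rho^2) z2)`,
#' `di = shift * shifted + iri_fc_sd * z1`, with
#' `shift = case_log2_iri_mean - control_log2_iri_mean` applied to the
#' `fraction_shifted` genes. This is the code path [generate_cohort()] uses.
#'
#' @param config a [synth_config()].
#' @param n number of genes (default `config$n_genes`).
#' @param seed optional seed; by default the current RNG state is used.
#' @return data.table: `gene_id`, `log2_expr_fc`, `log2_iri_fc`, `shifted`.
#' @export
sample_fold_changes <- function(config, n = config$n_genes, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  rho <- config$expr_iri_fc_correlation
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  di_noise <- config$iri_fc_sd * z1
  de <- config$expr_fc_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  shifted <- stats::runif(n) < config$fraction_shifted
  shift <- config$case_log2_iri_mean - config$control_log2_iri_mean
  data.table::data.table(
    gene_id = sprintf("G%05d", seq_len(n)),
    log2_expr_fc = de,
    log2_iri_fc = shift * shifted + di_noise,
    shifted = shifted)
}

# Region table template for one cohort: one row per counted region, with
# the density rule ("exon" regions at exonic density, intron regions at
# exonic density x IRI x effect).
.region_template <- function(models) {
  data.table::rbindlist(lapply(models, function(g) {
    ri <- g$reference_introns
    rows <- list(
      data.table::data.table(gene_id = g$gene_id, region_class = "shared_exon",
                             chrom = g$chrom, start = g$shared_exons$start,
                             end = g$shared_exons$end, kind = "exon"),
      data.table::data.table(gene_id = g$gene_id,
                             region_class = "shared_intron",
                             chrom = g$chrom, start = g$shared_introns$start,
                             end = g$shared_introns$end, kind = "intron"))
    if (nrow(ri) > 0L) {
      rows <- c(rows, list(
        data.table::data.table(gene_id = g$gene_id,
                               region_class = paste0("intron#", ri$ordinal),
                               chrom = g$chrom, start = ri$start, end = ri$end,
                               kind = "intron"),
        data.table::data.table(gene_id = g$gene_id,
                               region_class = paste0("flank#", ri$ordinal, "#up"),
                               chrom = g$chrom, start = ri$upstream_start,
                               end = ri$upstream_end, kind = "exon"),
        data.table::data.table(gene_id = g$gene_id,
                               region_class = paste0("flank#", ri$ordinal, "#down"),
                               chrom = g$chrom, start = ri$downstream_start,
                               end = ri$downstream_end, kind = "exon")))
    }
    data.table::rbindlist(rows)
  }))
}

#' Generate a two-group region-count cohort with ground truth
#'
#' Exonic region counts are drawn negative-binomially (Poisson when
#' `nb_dispersion = 0`) around expression x length x depth; intronic counts
#' around exonic density x true IRI (x planted per-intron effect in the
#' case group). Library size is `depth * 1e6` reads so estimated RPKM
#' matches the configured expression in expectation.
#'
#' @param models output of [generate_gene_models()] (or any gene models).
#' @param config the same [synth_config()].
#' @return list: `counts` (named list of [region_counts()]), `metadata`
#'   (data.table sample_id/group), `truth` (list with `genes` and `introns`
#'   tables), `models` (prepared), `library_size`, `config`.
#' @export
generate_cohort <- function(models, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  models <- prepare_models(models)
  gene_ids <- vapply(models, `[[`, "", "gene_id")
  n <- length(models)
  depth <- .coverage_depth[[config$coverage]]
  library_size <- depth * 1e6

  e_g <- stats::rnorm(n, config$expr_log2_mean, config$expr_log2_sd)
  i_g <- stats::rnorm(n, config$control_log2_iri_mean,
                      config$control_log2_iri_sd)
  fc <- sample_fold_changes(config, n)
  gene_truth <- data.table::data.table(
    gene_id = gene_ids,
    control_log2_iri = i_g, case_log2_iri = i_g + fc$log2_iri_fc,
    control_rpkm = 2^e_g, case_rpkm = 2^(e_g + fc$log2_expr_fc),
    log2_expr_fc = fc$log2_expr_fc, log2_iri_fc = fc$log2_iri_fc,
    shifted = fc$shifted)

  regions <- .region_template(models)
  regions[, len := end - start]
  regions[, gidx := match(gene_id, gene_ids)]

  # plant per-intron effects on the reference introns
  introns <- unique(regions[grepl("^intron#", region_class),
                            .(gene_id, region_class)])
  introns[, ordinal := as.integer(sub("^intron#", "", region_class))]
  n_int <- nrow(introns)
  n_up <- round(config$planted$frac_up * n_int)
  n_down <- round(config$planted$frac_down * n_int)
  introns[, truth_class := "null"]
  if (n_up + n_down > 0) {
    idx <- sample.int(n_int, n_up + n_down)
    introns[idx[seq_len(n_up)], truth_class := "up"]
    if (n_down > 0) introns[idx[n_up + seq_len(n_down)], truth_class := "down"]
  }
  introns[, effect := data.table::fifelse(
    truth_class == "up", config$planted$effect_size,
    data.table::fifelse(truth_class == "down",
                        1 / config$planted$effect_size, 1))]
  regions <- merge(regions,
                   introns[, .(gene_id, region_class, effect)],
                   by = c("gene_id", "region_class"), all.x = TRUE)
  regions[is.na(effect), effect := 1]
  data.table::setorder(regions, gidx, region_class, start)

  sample_ids <- c(sprintf("control_%02d", seq_len(config$n_control)),
                  sprintf("case_%02d", seq_len(config$n_case)))
  group <- c(rep("control", config$n_control), rep("case", config$n_case))
  names(group) <- sample_ids

  warned <- FALSE
  counts <- stats::setNames(vector("list", length(sample_ids)), sample_ids)
  for (si in seq_along(sample_ids)) {
    is_case <- group[si] == "case"
    dens_e <- 2^(e_g + if (is_case) fc$log2_expr_fc else 0) * depth / 1000
    iri <- 2^(i_g + if (is_case) fc$log2_iri_fc else 0)
    d <- dens_e[regions$gidx] *
      ifelse(regions$kind == "intron",
             iri[regions$gidx] * (if (is_case) regions$effect else 1), 1)
    mu <- d * regions$len
    if (!warned && config$coverage == "deep" &&
        any(mu[regions$kind == "exon"] < 1)) {
      warning("deep coverage preset yields expected exon counts < 1 for ",
              "some regions")
      warned <- TRUE
    }
    cnt <- if (config$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    else stats::rpois(length(mu), mu)
    counts[[si]] <- region_counts(
      sample_ids[si], library_size,
      data.table::data.table(gene_id = regions$gene_id,
                             region_class = regions$region_class,
                             chrom = regions$chrom, start = regions$start,
                             end = regions$end, count = cnt))
  }

  list(counts = counts,
       metadata = data.table::data.table(sample_id = sample_ids,
                                         group = unname(group)),
       truth = list(genes = gene_truth,
                    introns = introns[, .(gene_id, ordinal, truth_class,
                                          effect)]),
       models = models, library_size = library_size, config = config)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `counts.tsv` (long region-count table), `library_sizes.tsv`,
#' `metadata.tsv`, `truth_genes.tsv`, `truth_introns.tsv` and `models.gtf`
#' under `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- data.table::rbindlist(lapply(cohort$counts, function(rc)
    data.table::data.table(sample_id = rc$sample_id, rc$counts)))
  paths <- c(counts = file.path(dir, "counts.tsv"),
             library_sizes = file.path(dir, "library_sizes.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_introns = file.path(dir, "truth_introns.tsv"),
             gtf = file.path(dir, "models.gtf"))
  data.table::fwrite(long, paths["counts"], sep = "\t")
  data.table::fwrite(
    data.table::data.table(sample_id = names(cohort$counts),
                           library_size = cohort$library_size),
    paths["library_sizes"], sep = "\t")
  data.table::fwrite(cohort$metadata, paths["metadata"], sep = "\t")
  data.table::fwrite(cohort$truth$genes, paths["truth_genes"], sep = "\t")
  data.table::fwrite(cohort$truth$introns, paths["truth_introns"], sep = "\t")
  write_gtf(cohort$models, paths["gtf"])
  invisible(paths)
}
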