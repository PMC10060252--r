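# Stage orchestration: each stage reads/writes plain-text artifacts so any
# stage can also be run on user-provided files.

.stage_order <- c("simulate", "regions", "quantify", "cohort", "pca",
                  "enrich", "diffir")

#' Read a pipeline run configuration (JSON)
#'
#' Recognized top-level keys: `seed`, `outdir`, input paths (`gtf`,
#' `counts`, `library_sizes`, `metadata`, `gene_sets`, `gene_list`),
#' `synth` (preset name plus [synth_config()] overrides for the simulate
#' stage) and `params` (stage parameters: `rpkm_threshold`, `bins`,
#' `n_neg`, `n_pos`, `fc_threshold`, `p_threshold`, `pca_standardize`).
#'
#' @param path JSON file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$outdir)) stop("run config must set 'outdir'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$params)) cfg$params <- list()
  structure(cfg, class = "run_config")
}

.param <- function(config, name, default) {
  v <- config$params[[name]]
  if (is.null(v)) default else v
}

.resolve <- function(config, key, default_rel) {
  p <- config[[key]]
  if (is.null(p)) p <- file.path(config$outdir, default_rel)
  p
}

.require_input <- function(path, producer) {
  if (!file.exists(path))
    stop("missing input ", path, "; run stage '", producer, "' first")
  path
}

.write_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("iriq")),
    config_hash = unname(tools::md5sum(
      {tf <- tempfile(); jsonlite::write_json(unclass(config), tf,
                                              auto_unbox = TRUE); tf})),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  path <- file.path(config$outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.read_groups <- function(meta_path) {
  meta <- data.table::fread(meta_path)
  stopifnot(all(c("sample_id", "group") %in% names(meta)))
  stats::setNames(meta$group, meta$sample_id)
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (synthetic cohort), `regions` (shared regions and
#' reference introns as BED), `quantify` (per-sample IRI and splicing-ratio
#' tables), `cohort` (cohort matrices, correlations, clustering, group
#' test, fold changes), `pca` (components, projections, book-ends),
#' `enrich` (hypergeometric enrichment of the book-end sets), `diffir`
#' (differential intron retention), or `all` (chain in order). Each stage
#' writes its outputs plus a `manifest_<stage>.json` with input/output
#' hashes under `config$outdir`.
#'
#' @param name stage name.
#' @param config a [read_run_config()] object (or equivalent list).
#' @return named vector of the stage's output paths (for `all`, of the last
#'   stage), invisibly.
#' @export
run_stage <- function(name = c("simulate", "regions", "quantify", "cohort",
                               "pca", "enrich", "diffir", "all"),
                      config) {
  name <- match.arg(name)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (name == "all") {
    stages <- .stage_order
    if (is.null(config$gene_sets)) stages <- setdiff(stages, "enrich")
    for (s in stages) out <- run_stage(s, config)
    return(invisible(out))
  }
  switch(name,
         simulate = .stage_simulate(config),
         regions = .stage_regions(config),
         quantify = .stage_quantify(config),
         cohort = .stage_cohort(config),
         pca = .stage_pca(config),
         enrich = .stage_enrich(config),
         diffir = .stage_diffir(config))
}

.stage_simulate <- function(config) {
  sy <- config$synth
  if (is.null(sy)) sy <- list()
  preset <- sy$preset
  sy$preset <- NULL
  sy$seed <- config$seed
  cfg <- if (is.null(preset)) do.call(synth_config, sy)
         else do.call(synth_preset, c(list(name = preset), sy))
  models <- generate_gene_models(cfg)
  cohort <- generate_cohort(models, cfg)
  paths <- write_cohort(cohort, file.path(config$outdir, "simulated"))
  .write_manifest(config, "simulate", character(), paths)
  invisible(paths)
}

.stage_regions <- function(config) {
  gtf <- .require_input(.resolve(config, "gtf", "simulated/models.gtf"),
                        "simulate")
  models <- prepare_models(read_gtf(gtf))
  dir <- file.path(config$outdir, "regions")
  dir.create(dir, showWarnings = FALSE)
  paths <- c(shared_exons = file.path(dir, "shared_exons.bed"),
             shared_introns = file.path(dir, "shared_introns.bed"),
             reference_introns = file.path(dir, "reference_introns.bed"))
  write_regions_bed(models, "shared_exons", paths["shared_exons"])
  write_regions_bed(models, "shared_introns", paths["shared_introns"])
  write_regions_bed(models, "reference_introns", paths["reference_introns"])
  .write_manifest(config, "regions", gtf, paths)
  invisible(paths)
}

.stage_quantify <- function(config) {
  gtf <- .require_input(.resolve(config, "gtf", "simulated/models.gtf"),
                        "simulate")
  counts <- .require_input(.resolve(config, "counts",
                                    "simulated/counts.tsv"), "simulate")
  libs <- .require_input(.resolve(config, "library_sizes",
                                  "simulated/library_sizes.tsv"), "simulate")
  models <- prepare_models(read_gtf(gtf))
  rcs <- read_region_counts(counts, libs)
  thr <- .param(config, "rpkm_threshold", 1)
  iri <- data.table::rbindlist(lapply(rcs, function(rc)
    data.table::data.table(sample_id = rc$sample_id,
                           compute_iri(models, rc, rpkm_threshold = thr))))
  sr <- data.table::rbindlist(lapply(rcs, function(rc)
    data.table::data.table(sample_id = rc$sample_id,
                           compute_splicing_ratios(models, rc))))
  dir <- file.path(config$outdir, "quantify")
  dir.create(dir, showWarnings = FALSE)
  paths <- c(iri = file.path(dir, "iri.tsv"),
             splicing_ratios = file.path(dir, "splicing_ratios.tsv"))
  data.table::fwrite(iri, paths["iri"], sep = "\t")
  data.table::fwrite(sr, paths["splicing_ratios"], sep = "\t")
  .write_manifest(config, "quantify", c(gtf, counts, libs), paths)
  invisible(paths)
}

.load_cohort_matrices <- function(config) {
  iri_path <- .require_input(file.path(config$outdir, "quantify", "iri.tsv"),
                             "quantify")
  meta <- .require_input(.resolve(config, "metadata",
                                  "simulated/metadata.tsv"), "simulate")
  groups <- .read_groups(meta)
  iri <- data.table::fread(iri_path)
  tables <- split(iri, by = "sample_id", sorted = TRUE, keep.by = FALSE)
  list(iri = build_cohort_matrix(tables, groups, mode = "iri"),
       expr = build_cohort_matrix(tables, groups, mode = "expression"),
       inputs = c(iri_path, meta))
}

.stage_cohort <- function(config) {
  cms <- .load_cohort_matrices(config)
  cm <- cms$iri
  dir <- file.path(config$outdir, "cohort")
  dir.create(dir, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "log2_iri_matrix.tsv"),
             correlation = file.path(dir, "sample_correlation.tsv"),
             dendrogram = file.path(dir, "sample_dendrogram.nwk"),
             summary = file.path(dir, "sample_summary.tsv"),
             group_test = file.path(dir, "group_test.json"),
             fc = file.path(dir, "fold_changes.tsv"),
             coupling = file.path(dir, "fc_coupling.json"),
             coupling_bins = file.path(dir, "fc_coupling_bins.tsv"))
  data.table::fwrite(
    data.table::data.table(gene_id = cm$genes, cm$values),
    paths["matrix"], sep = "\t")
  pc <- pairwise_sample_correlation(cm)
  data.table::fwrite(data.table::data.table(sample_id = rownames(pc), pc),
                     paths["correlation"], sep = "\t")
  hc <- hierarchical_cluster(zscore_matrix(cm), axis = "samples")
  writeLines(dendrogram_newick(hc), paths["dendrogram"])
  hist <- log2_iri_histogram(cm, bins = .param(config, "bins", 60))
  data.table::fwrite(hist$summary, paths["summary"], sep = "\t")
  gt <- group_mean_test(cm)
  jsonlite::write_json(gt[c("p", "statistic", "method", "case_mean",
                            "control_mean")],
                       paths["group_test"], auto_unbox = TRUE, digits = NA)
  iri_fc <- fold_change_table(cm)
  expr_fc <- fold_change_table(cms$expr)
  fcs <- merge(iri_fc[, .(gene_id, iri_fc = fc, iri_log2_fc = log2_fc)],
               expr_fc[, .(gene_id, expr_fc = fc, expr_log2_fc = log2_fc)],
               by = "gene_id")
  data.table::fwrite(fcs, paths["fc"], sep = "\t")
  cp <- fold_change_coupling(iri_fc, expr_fc)
  jsonlite::write_json(cp[c("r", "p", "n", "dropped")], paths["coupling"],
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(cp$bins, paths["coupling_bins"], sep = "\t")
  .write_manifest(config, "cohort", cms$inputs, paths)
  invisible(paths)
}

.stage_pca <- function(config) {
  cms <- .load_cohort_matrices(config)
  p <- orient_pc1(pca_cohort(cms$iri,
                             standardize = .param(config, "pca_standardize",
                                                  TRUE)))
  be <- select_book_ends(p, n_neg = .param(config, "n_neg", 50),
                         n_pos = .param(config, "n_pos", 100))
  dir <- file.path(config$outdir, "pca")
  dir.create(dir, showWarnings = FALSE)
  paths <- c(fractions = file.path(dir, "variance_fractions.tsv"),
             components = file.path(dir, "components.tsv"),
             projections = file.path(dir, "projections.tsv"),
             book_ends = file.path(dir, "book_ends.tsv"))
  data.table::fwrite(
    data.table::data.table(component = paste0("PC", seq_along(p$fractions)),
                           eigenvalue = p$eigenvalues,
                           fraction = p$fractions),
    paths["fractions"], sep = "\t")
  data.table::fwrite(
    data.table::data.table(gene_id = rownames(p$components), p$components),
    paths["components"], sep = "\t")
  data.table::fwrite(
    data.table::data.table(sample_id = rownames(p$projections),
                           p$projections),
    paths["projections"], sep = "\t")
  data.table::fwrite(
    data.table::data.table(
      gene_id = c(be$negative_set, be$positive_set),
      set = c(rep("negative", length(be$negative_set)),
              rep("positive", length(be$positive_set)))),
    paths["book_ends"], sep = "\t")
  .write_manifest(config, "pca", cms$inputs, paths)
  invisible(paths)
}

.stage_enrich <- function(config) {
  be_path <- .require_input(file.path(config$outdir, "pca", "book_ends.tsv"),
                            "pca")
  gmt <- .require_input(.resolve(config, "gene_sets", "gene_sets.gmt"),
                        "enrich (provide 'gene_sets')")
  mat_path <- .require_input(file.path(config$outdir, "cohort",
                                       "log2_iri_matrix.tsv"), "cohort")
  population <- data.table::fread(mat_path)$gene_id
  be <- data.table::fread(be_path)
  collection <- read_gmt(gmt)
  res <- data.table::rbindlist(lapply(c("negative", "positive"), function(s)
    data.table::data.table(subset = s,
                           hypergeom_enrichment(be$gene_id[be$set == s],
                                                population, collection))))
  dir <- file.path(config$outdir, "enrich")
  dir.create(dir, showWarnings = FALSE)
  paths <- c(enrichment = file.path(dir, "enrichment.tsv"))
  data.table::fwrite(res, paths["enrichment"], sep = "\t")
  .write_manifest(config, "enrich", c(be_path, gmt, mat_path), paths)
  invisible(paths)
}

.stage_diffir <- function(config) {
  sr_path <- .require_input(file.path(config$outdir, "quantify",
                                      "splicing_ratios.tsv"), "quantify")
  meta <- .require_input(.resolve(config, "metadata",
                                  "simulated/metadata.tsv"), "simulate")
  groups <- .read_groups(meta)
  sr <- data.table::fread(sr_path)
  rec <- differential_test(sr, groups,
                           fc_threshold = .param(config, "fc_threshold", 2),
                           p_threshold = .param(config, "p_threshold", 0.05))
  dir <- file.path(config$outdir, "diffir")
  dir.create(dir, showWarnings = FALSE)
  paths <- c(volcano = file.path(dir, "volcano.tsv"),
             summary = file.path(dir, "summary.json"),
             dual = file.path(dir, "dual_regulation.tsv"))
  data.table::fwrite(rec, paths["volcano"], sep = "\t")
  vt <- volcano_table(rec)
  dual <- dual_regulation_summary(rec)
  jsonlite::write_json(c(vt, list(genes_with_both = length(dual$genes_with_both),
                                  frac_first_up = dual$frac_first_up,
                                  frac_first_down = dual$frac_first_down)),
                       paths["summary"], auto_unbox = TRUE, digits = NA)
  data.table::fwrite(
    data.table::data.table(gene_id = dual$genes_with_both),
    paths["dual"], sep = "\t")
  .write_manifest(config, "diffir", c(sr_path, meta), paths)
  invisible(paths)
}
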