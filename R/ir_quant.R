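# Region-level counts -> RPKM, per-gene IRI, per-intron splicing ratios,
# and the cohort matrix over the detectable-gene intersection.
#
# Region classes in a count table:
#   "shared_exon"  / "shared_intron"  -- constitutive regions (possibly
#                                        several rows per gene)
#   "intron#<k>"                      -- reference-isoform intron, ordinal k
#   "flank#<k>#up" / "flank#<k>#down" -- its flanking exons, transcription
#                                        order
# A region's count is the number of reads overlapping it by >= 1 base; a
# read overlapping both exon and intron increments both.

#' Reads per kilobase per million mapped reads
#'
#' @param count read count (non-negative, vectorized).
#' @param length region length in bases (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return RPKM = count / (length/1000) / (library_size/1e6).
#' @export
rpkm <- function(count, length, library_size) {
  if (any(length <= 0)) stop("rpkm: region length must be > 0")
  if (any(library_size <= 0)) stop("rpkm: library size must be > 0")
  count / (length / 1000) / (library_size / 1e6)
}

#' Construct a per-sample region count table
#'
#' @param sample_id sample identifier.
#' @param library_size total mapped reads (positive).
#' @param counts data.frame with columns `gene_id`, `region_class`, `chrom`,
#'   `start`, `end`, `count` (counts non-negative).
#' @return a `region_counts` object.
#' @export
region_counts <- function(sample_id, library_size, counts) {
  counts <- data.table::as.data.table(counts)
  need <- c("gene_id", "region_class", "chrom", "start", "end", "count")
  if (!all(need %in% names(counts)))
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  if (any(counts$count < 0)) stop("negative read count")
  if (!is.numeric(library_size) || library_size <= 0)
    stop("library_size must be a positive number")
  structure(list(sample_id = sample_id,
                 library_size = as.numeric(library_size),
                 counts = counts[, need, with = FALSE]),
            class = "region_counts")
}

# Total shared-region lengths per gene from prepared models.
.region_lengths <- function(models) {
  data.table::rbindlist(lapply(models, function(g) {
    if (is.null(g$shared_exons))
      stop("shared regions not derived for ", g$gene_id)
    data.table::data.table(
      gene_id = g$gene_id,
      exon_len = sum(g$shared_exons$end - g$shared_exons$start),
      intron_len = sum(g$shared_introns$end - g$shared_introns$start))
  }))
}

#' Per-gene Intron Retention Index for one sample
#'
#' IRI is the ratio of read density (reads per base) over shared intronic
#' regions to read density over shared exonic regions. A gene is detectable
#' when its shared-exonic RPKM exceeds 1 and both densities are positive
#' (so log2 IRI is finite). Genes without shared introns, or with zero
#' exonic density, yield undetectable records with `iri = NA` (never Inf).
#'
#' @param models prepared gene models ([prepare_models()]).
#' @param rc a [region_counts()] object.
#' @param rpkm_threshold expression filter on shared-exonic RPKM (default 1).
#' @return data.table with one row per gene: `gene_id`, `exonic_density`,
#'   `intronic_density`, `iri`, `log2_iri`, `gene_rpkm`, `detectable`.
#' @export
compute_iri <- function(models, rc, rpkm_threshold = 1) {
  stopifnot(inherits(rc, "region_counts"))
  lens <- .region_lengths(models)
  cc <- rc$counts[region_class %in% c("shared_exon", "shared_intron"),
                  .(reads = sum(count)), by = .(gene_id, region_class)]
  wide <- data.table::dcast(cc, gene_id ~ region_class,
                            value.var = "reads", fill = 0)
  for (col in c("shared_exon", "shared_intron"))
    if (!col %in% names(wide)) wide[, (col) := 0]
  out <- merge(lens, wide, by = "gene_id", all.x = TRUE)
  out[is.na(shared_exon), shared_exon := 0]
  out[is.na(shared_intron), shared_intron := 0]
  out[, exonic_density := ifelse(exon_len > 0, shared_exon / exon_len, NA_real_)]
  out[, intronic_density := ifelse(intron_len > 0,
                                   shared_intron / intron_len, NA_real_)]
  out[, gene_rpkm := ifelse(exon_len > 0,
                            rpkm(shared_exon, pmax(exon_len, 1),
                                 rc$library_size), NA_real_)]
  out[, iri := ifelse(!is.na(exonic_density) & exonic_density > 0 &
                        !is.na(intronic_density),
                      intronic_density / exonic_density, NA_real_)]
  out[, log2_iri := ifelse(!is.na(iri) & iri > 0, log2(iri), NA_real_)]
  out[, detectable := !is.na(gene_rpkm) & gene_rpkm > rpkm_threshold &
        !is.na(iri) & iri > 0 &
        !is.na(exonic_density) & exonic_density > 0]
  data.table::setorder(out, gene_id)
  out[, .(gene_id, exonic_density, intronic_density, iri, log2_iri,
          gene_rpkm, detectable)]
}

#' Per-intron splicing ratios for one sample
#'
#' The splicing ratio of a reference-isoform intron is its RPKM divided by
#' the arithmetic mean RPKM of its two flanking exons. Introns whose mean
#' flank RPKM is zero are omitted (a message reports how many).
#'
#' @inheritParams compute_iri
#' @return data.table: `gene_id`, `ordinal`, `intron_rpkm`,
#'   `flank_mean_rpkm`, `ratio`.
#' @export
compute_splicing_ratios <- function(models, rc) {
  stopifnot(inherits(rc, "region_counts"))
  cc <- rc$counts[grepl("^(intron|flank)#", region_class)]
  if (nrow(cc) == 0L)
    return(data.table::data.table(gene_id = character(), ordinal = integer(),
                                  intron_rpkm = numeric(),
                                  flank_mean_rpkm = numeric(),
                                  ratio = numeric()))
  parts <- data.table::tstrsplit(cc$region_class, "#", fixed = TRUE)
  cc[, `:=`(kind = parts[[1]], ordinal = as.integer(parts[[2]]),
            side = if (length(parts) >= 3) parts[[3]] else NA_character_)]
  cc[, len := end - start]
  cc[, region_rpkm := rpkm(count, len, rc$library_size)]
  agg <- cc[, .(region_rpkm = sum(count) / (sum(len) / 1000) /
                  (rc$library_size / 1e6)),
            by = .(gene_id, ordinal, kind, side)]
  introns <- agg[kind == "intron",
                 .(gene_id, ordinal, intron_rpkm = region_rpkm)]
  flanks <- agg[kind == "flank",
                .(flank_mean_rpkm = mean(region_rpkm)),
                by = .(gene_id, ordinal)]
  out <- merge(introns, flanks, by = c("gene_id", "ordinal"))
  dropped <- out[flank_mean_rpkm <= 0]
  if (nrow(dropped) > 0L)
    message("compute_splicing_ratios: omitted ", nrow(dropped),
            " intron(s) with zero mean flank RPKM")
  out <- out[flank_mean_rpkm > 0]
  out[, ratio := intron_rpkm / flank_mean_rpkm]
  data.table::setorder(out, gene_id, ordinal)
  out[]
}

#' Build a genes x samples cohort matrix over the detectable intersection
#'
#' Retains exactly the genes detectable in every sample and fills the matrix
#' with per-gene log2 IRI (`mode = "iri"`) or shared-exonic RPKM
#' (`mode = "expression"`).
#'
#' @param iri_tables named list (by sample id) of [compute_iri()] tables.
#' @param groups named character vector mapping sample id to `"case"` or
#'   `"control"`.
#' @param mode `"iri"` or `"expression"`.
#' @return a `cohort_matrix`: list with `values` (matrix), `genes`,
#'   `samples`, `groups`, `mode`, `detectable_counts`, `n_common`.
#' @export
build_cohort_matrix <- function(iri_tables, groups, mode = c("iri",
                                                             "expression")) {
  mode <- match.arg(mode)
  stopifnot(length(iri_tables) >= 1L, !is.null(names(iri_tables)))
  samples <- names(iri_tables)
  if (!all(samples %in% names(groups)))
    stop("groups must name every sample")
  detect <- lapply(iri_tables, function(t) t$gene_id[t$detectable])
  common <- detect[[1L]]
  for (s in seq_along(detect)[-1L]) {
    common <- intersect(common, detect[[s]])
    if (length(common) == 0L)
      stop("detectable-gene intersection emptied at sample ", samples[s])
  }
  common <- sort(common)
  col <- if (mode == "iri") "log2_iri" else "gene_rpkm"
  values <- vapply(iri_tables, function(t) {
    v <- t[[col]][match(common, t$gene_id)]
    v
  }, numeric(length(common)))
  values <- matrix(values, nrow = length(common),
                   dimnames = list(common, samples))
  structure(list(values = values, genes = common, samples = samples,
                 groups = groups[samples], mode = mode,
                 detectable_counts = lengths(detect),
                 n_common = length(common)),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d genes x %d samples (%s mode; %d case, %d control)\n",
              x$n_common, length(x$samples), x$mode,
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Read per-sample region count tables from TSV
#'
#' @param counts_path long TSV with columns `sample_id`, `gene_id`,
#'   `region_class`, `chrom`, `start`, `end`, `count`.
#' @param library_path TSV with columns `sample_id`, `library_size`.
#' @return named list of [region_counts()] objects.
#' @export
read_region_counts <- function(counts_path, library_path) {
  cnt <- data.table::fread(counts_path)
  lib <- data.table::fread(library_path)
  stopifnot(all(c("sample_id", "library_size") %in% names(lib)))
  miss <- setdiff(unique(cnt$sample_id), lib$sample_id)
  if (length(miss))
    stop("no library size for sample(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(cnt, by = "sample_id", sorted = TRUE), function(s) {
    region_counts(s$sample_id[1L],
                  lib$library_size[match(s$sample_id[1L], lib$sample_id)], s)
  })
  out
}
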