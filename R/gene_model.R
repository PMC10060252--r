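# Gene models: GTF input, shared (constitutive) region derivation, and
# reference-isoform intron enumeration.
#
# All coordinates inside the package are 0-based half-open; GTF's 1-based
# closed convention is converted at the reader boundary and nowhere else.

# 0-based half-open <-> IRanges (1-based closed) converters.
.zh_ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

.ir_zh <- function(ir) {
  data.table::data.table(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Construct a transcript
#'
#' @param transcript_id transcript identifier.
#' @param exons data.frame with 0-based half-open `start`/`end` columns;
#'   exons must be non-empty, non-overlapping and are sorted by `start`.
#' @return a `transcript` object.
#' @keywords internal
new_transcript <- function(transcript_id, exons) {
  exons <- data.table::as.data.table(exons)[, c("start", "end")]
  if (nrow(exons) == 0L) stop("transcript ", transcript_id, " has no exons")
  if (any(exons$start >= exons$end) || any(exons$start < 0L))
    stop("transcript ", transcript_id, " has an invalid exon interval")
  data.table::setorder(exons, start)
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("transcript ", transcript_id, " has overlapping exons")
  structure(list(transcript_id = transcript_id, exons = exons),
            class = "transcript")
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param transcripts list of [new_transcript()] objects.
#' @return a `gene_model` object; shared regions and reference introns are
#'   unset until [derive_shared_regions()] / [enumerate_reference_introns()].
#' @export
new_gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(length(transcripts) >= 1L, strand %in% c("+", "-", "."))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts,
                 shared_exons = NULL, shared_introns = NULL,
                 reference_introns = NULL),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s) %d transcript(s)\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  if (!is.null(x$shared_exons))
    cat(sprintf("  shared: %d exonic, %d intronic region(s)\n",
                nrow(x$shared_exons), nrow(x$shared_introns)))
  invisible(x)
}

.gtf_attr <- function(attrs, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  has <- grepl(pat, attrs)
  out <- rep(NA_character_, length(attrs))
  out[has] <- sub(paste0('^.*?(^|;)\\s*', key, '\\s+"([^"]*)".*$'), "\\2",
                  attrs[has], perl = TRUE)
  out
}

#' Read gene models from a GTF file
#'
#' Parses `exon` features and groups them into one [new_gene_model()] per
#' `gene_id`. GTF 1-based closed coordinates are converted to 0-based
#' half-open. Genes that appear only through non-exon features are skipped
#' with a warning. Malformed lines raise an error naming the line number.
#'
#' @param path path to a GTF file.
#' @return named list of `gene_model` objects (shared regions unset).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) stop("GTF format error: no records in ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("GTF format error at line ", lineno[bad[1L]],
         ": expected 9 tab-separated fields")
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  dt <- data.table::data.table(
    chrom = m[, 1L], feature = m[, 3L],
    start = suppressWarnings(as.integer(m[, 4L])),
    end = suppressWarnings(as.integer(m[, 5L])),
    strand = m[, 7L], attrs = m[, 9L], line = lineno)

  bad <- which(is.na(dt$start) | is.na(dt$end))
  if (length(bad))
    stop("GTF format error at line ", dt$line[bad[1L]],
         ": non-numeric coordinates")
  bad <- which(dt$end < dt$start | dt$start < 1L)
  if (length(bad))
    stop("GTF format error at line ", dt$line[bad[1L]],
         ": end < start (or start < 1)")

  dt[, `:=`(gene_id = .gtf_attr(attrs, "gene_id"),
            transcript_id = .gtf_attr(attrs, "transcript_id"))]
  all_genes <- unique(dt$gene_id[!is.na(dt$gene_id)])
  ex <- dt[feature == "exon"]
  bad <- which(is.na(ex$gene_id) | is.na(ex$transcript_id))
  if (length(bad))
    stop("GTF format error at line ", ex$line[bad[1L]],
         ": exon lacks gene_id/transcript_id attribute")

  skipped <- setdiff(all_genes, unique(ex$gene_id))
  if (length(skipped))
    warning("skipping ", length(skipped),
            " gene(s) with no exon records: ",
            paste(utils::head(skipped, 5L), collapse = ", "))

  # 1-based closed -> 0-based half-open
  ex[, start := start - 1L]
  models <- lapply(split(ex, by = "gene_id", sorted = TRUE), function(g) {
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L)
      stop("gene ", g$gene_id[1L], " spans multiple chromosomes/strands")
    txs <- lapply(split(g, by = "transcript_id", sorted = TRUE),
                  function(t) new_transcript(t$transcript_id[1L], t))
    strand <- g$strand[1L]
    if (!strand %in% c("+", "-")) strand <- "."
    new_gene_model(g$gene_id[1L], g$chrom[1L], strand, unname(txs))
  })
  models
}

#' Derive shared exonic and intronic regions of a gene
#'
#' A base is shared-exonic iff it is covered by the span of every transcript
#' of the gene and exonic in every transcript; shared-intronic iff covered by
#' every span and exonic in none. Bases exonic in some isoforms and intronic
#' in others are ambiguous and belong to neither set.
#'
#' @param gene a `gene_model`.
#' @return the gene with `shared_exons` and `shared_introns` set (0-based
#'   half-open, merged maximal intervals sorted by start).
#' @export
derive_shared_regions <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ex_sets <- lapply(gene$transcripts, function(t)
    IRanges::reduce(.zh_ir(t$exons$start, t$exons$end)))
  spans <- lapply(ex_sets, range)
  common <- Reduce(IRanges::intersect, spans)
  exon_all <- Reduce(IRanges::intersect, ex_sets)
  exon_all <- IRanges::intersect(exon_all, common)
  union_ex <- IRanges::reduce(do.call(c, ex_sets))
  intron_all <- IRanges::setdiff(common, union_ex)
  gene$shared_exons <- .ir_zh(IRanges::reduce(exon_all))
  gene$shared_introns <- .ir_zh(IRanges::reduce(intron_all))
  gene
}

# Reference isoform: most exons, then longest span, then smallest id.
.reference_transcript <- function(gene) {
  n_ex <- vapply(gene$transcripts, function(t) nrow(t$exons), 0L)
  span <- vapply(gene$transcripts,
                 function(t) as.numeric(max(t$exons$end) - min(t$exons$start)),
                 0)
  ids <- vapply(gene$transcripts, `[[`, "", "transcript_id")
  ord <- order(-n_ex, -span, ids)
  gene$transcripts[[ord[1L]]]
}

#' Enumerate introns of the reference isoform with flanking exons
#'
#' The reference isoform is the transcript with the most exons (ties broken
#' by longer span, then lexicographic transcript id). Ordinals count introns
#' in 5'->3' transcription order, so ordinal 1 on the minus strand is the
#' rightmost gap. Upstream/downstream flanks are in transcription order.
#'
#' @param gene a `gene_model` (shared regions need not be derived).
#' @return the gene with `reference_introns` set: a data.table with columns
#'   `ordinal`, `start`, `end`, `upstream_start`, `upstream_end`,
#'   `downstream_start`, `downstream_end`, `transcript_id`; zero rows for
#'   single-exon reference isoforms.
#' @export
enumerate_reference_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  tx <- .reference_transcript(gene)
  e <- tx$exons
  empty <- data.table::data.table(
    ordinal = integer(), start = integer(), end = integer(),
    upstream_start = integer(), upstream_end = integer(),
    downstream_start = integer(), downstream_end = integer(),
    transcript_id = character())
  if (nrow(e) < 2L) { gene$reference_introns <- empty; return(gene) }
  n <- nrow(e) - 1L
  ri <- data.table::data.table(
    start = e$end[seq_len(n)], end = e$start[seq_len(n) + 1L],
    left_start = e$start[seq_len(n)], left_end = e$end[seq_len(n)],
    right_start = e$start[seq_len(n) + 1L], right_end = e$end[seq_len(n) + 1L])
  if (identical(gene$strand, "-")) {
    ri <- ri[rev(seq_len(n))]
    out <- data.table::data.table(
      ordinal = seq_len(n), start = ri$start, end = ri$end,
      upstream_start = ri$right_start, upstream_end = ri$right_end,
      downstream_start = ri$left_start, downstream_end = ri$left_end)
  } else {
    out <- data.table::data.table(
      ordinal = seq_len(n), start = ri$start, end = ri$end,
      upstream_start = ri$left_start, upstream_end = ri$left_end,
      downstream_start = ri$right_start, downstream_end = ri$right_end)
  }
  out[, transcript_id := tx$transcript_id]
  gene$reference_introns <- out
  gene
}

#' Derive shared regions and reference introns for a list of gene models
#'
#' @param models list of `gene_model` objects, e.g. from [read_gtf()].
#' @return the list with shared regions and reference introns set.
#' @export
prepare_models <- function(models) {
  lapply(models, function(g)
    enumerate_reference_introns(derive_shared_regions(g)))
}

#' Write gene-model regions to BED6
#'
#' @param models prepared gene models (see [prepare_models()]).
#' @param type one of `"shared_exons"`, `"shared_introns"`,
#'   `"reference_introns"`. For reference introns the BED name field is
#'   `gene_id|ordinal`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(models, type = c("shared_exons",
                                               "shared_introns",
                                               "reference_introns"),
                              path) {
  type <- match.arg(type)
  rows <- data.table::rbindlist(lapply(models, function(g) {
    if (type == "reference_introns") {
      ri <- g$reference_introns
      if (is.null(ri)) stop("reference introns not derived for ", g$gene_id)
      if (nrow(ri) == 0L) return(NULL)
      data.table::data.table(chrom = g$chrom, start = ri$start, end = ri$end,
                             name = paste0(g$gene_id, "|", ri$ordinal),
                             score = 0L, strand = g$strand)
    } else {
      r <- g[[type]]
      if (is.null(r)) stop("shared regions not derived for ", g$gene_id)
      if (nrow(r) == 0L) return(NULL)
      data.table::data.table(chrom = g$chrom, start = r$start, end = r$end,
                             name = g$gene_id, score = 0L, strand = g$strand)
    }
  }))
  data.table::fwrite(rows, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
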