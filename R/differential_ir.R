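# Per-intron case/control comparison of splicing ratios: fold changes,
# exact Mann-Whitney p-values, volcano classification, and dual-regulation
# summaries.

#' Differential intron retention test
#'
#' For every reference intron with a defined splicing ratio in all samples
#' of both groups: fold change = mean(case) / mean(control) on linear
#' ratios, exact two-sided Mann-Whitney p ([exact_mann_whitney()]), and the
#' volcano class -- `up` iff log2 fold change >= log2(fc_threshold) and
#' p <= p_threshold, `down` iff log2 fold change <= -log2(fc_threshold) and
#' p <= p_threshold, else `ns`. Introns missing in some sample, or with a
#' zero control mean, are excluded (counts reported by message).
#'
#' @param ratios long table of per-sample splicing ratios: columns
#'   `sample_id`, `gene_id`, `ordinal`, `ratio` (e.g. stacked
#'   [compute_splicing_ratios()] outputs).
#' @param groups named character vector sample id -> `"case"`/`"control"`.
#' @param fc_threshold linear fold-change threshold (default 2; applied as
#'   |log2 FC| >= log2(threshold)).
#' @param p_threshold p-value threshold (default 0.05).
#' @return data.table: `gene_id`, `ordinal`, `mean_case_ratio`,
#'   `mean_control_ratio`, `fold_change`, `log2_fc`, `p`, `class`.
#' @export
differential_test <- function(ratios, groups, fc_threshold = 2,
                              p_threshold = 0.05) {
  ratios <- data.table::as.data.table(ratios)
  stopifnot(all(c("sample_id", "gene_id", "ordinal", "ratio") %in%
                  names(ratios)))
  samples <- sort(unique(ratios$sample_id))
  if (!all(samples %in% names(groups)))
    stop("groups must name every sample in the ratio table")
  grp <- groups[samples]
  if (!all(c("case", "control") %in% grp)) stop("empty group")
  n_samples <- length(samples)
  ratios <- ratios[!is.na(ratio)]
  complete <- ratios[, .N, by = .(gene_id, ordinal)][N == n_samples]
  n_incomplete <- ratios[, data.table::uniqueN(paste(gene_id, ordinal))] -
    nrow(complete)
  if (n_incomplete > 0)
    message("differential_test: excluded ", n_incomplete,
            " intron(s) without a defined ratio in every sample")
  ratios <- merge(ratios, complete[, .(gene_id, ordinal)],
                  by = c("gene_id", "ordinal"))
  case_ids <- samples[grp == "case"]
  ctrl_ids <- samples[grp == "control"]
  lg2t <- log2(fc_threshold)
  out <- ratios[, {
    x <- ratio[match(case_ids, sample_id)]
    y <- ratio[match(ctrl_ids, sample_id)]
    mc <- mean(x); m0 <- mean(y)
    if (m0 <= 0) {
      NULL
    } else {
      mw <- exact_mann_whitney(x, y)
      .(mean_case_ratio = mc, mean_control_ratio = m0,
        fold_change = mc / m0, p = mw$p)
    }
  }, by = .(gene_id, ordinal)]
  n_zero_ctrl <- nrow(complete) - nrow(out)
  if (n_zero_ctrl > 0)
    message("differential_test: excluded ", n_zero_ctrl,
            " intron(s) with zero control mean")
  if (nrow(out) == 0L)
    return(data.table::data.table(
      gene_id = character(), ordinal = integer(), mean_case_ratio = numeric(),
      mean_control_ratio = numeric(), fold_change = numeric(),
      log2_fc = numeric(), p = numeric(), class = character()))
  out[, log2_fc := log2(fold_change)]
  out[, class := data.table::fifelse(
    log2_fc >= lg2t & p <= p_threshold, "up",
    data.table::fifelse(log2_fc <= -lg2t & p <= p_threshold, "down", "ns"))]
  data.table::setorder(out, gene_id, ordinal)
  data.table::setcolorder(out, c("gene_id", "ordinal", "mean_case_ratio",
                                 "mean_control_ratio", "fold_change",
                                 "log2_fc", "p", "class"))
  out[]
}

#' Volcano summary counts
#'
#' @param records [differential_test()] output.
#' @return list: `total`, `up`, `down`, `up_genes`, `down_genes`.
#' @export
volcano_table <- function(records) {
  list(total = nrow(records),
       up = sum(records$class == "up"),
       down = sum(records$class == "down"),
       up_genes = data.table::uniqueN(records$gene_id[records$class == "up"]),
       down_genes = data.table::uniqueN(records$gene_id[records$class == "down"]))
}

#' Dual-regulation and first-intron summary
#'
#' Genes containing both significantly up- and down-regulated introns, and,
#' among those dual-regulated genes whose first intron (ordinal 1) was
#' tested, the fraction whose first intron is up- (and down-) regulated.
#'
#' @param records [differential_test()] output.
#' @return list: `genes_with_up`, `genes_with_down`, `genes_with_both`
#'   (character vectors), `first_intron_class` (data.table for dual genes),
#'   `frac_first_up`, `frac_first_down` (NA when no dual gene has a tested
#'   first intron).
#' @export
dual_regulation_summary <- function(records) {
  up <- unique(records$gene_id[records$class == "up"])
  down <- unique(records$gene_id[records$class == "down"])
  both <- sort(intersect(up, down))
  first <- records[ordinal == 1L & gene_id %in% both,
                   .(gene_id, class)]
  frac_up <- frac_down <- NA_real_
  if (nrow(first) > 0L) {
    frac_up <- mean(first$class == "up")
    frac_down <- mean(first$class == "down")
  }
  list(genes_with_up = sort(up), genes_with_down = sort(down),
       genes_with_both = both, first_intron_class = first,
       frac_first_up = frac_up, frac_first_down = frac_down)
}
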