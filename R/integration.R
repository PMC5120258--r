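#' Read a differential-expression table
#'
#' Tab-separated with a header; required columns `gene_id`, `log2fc`,
#' `pvalue`, `fdr`, `logcpm_normal` (the control-group log2 counts per
#' million; negative values mark lowly expressed genes).
#'
#' @param path File path.
#' @return The validated data.frame.
#' @export
read_de_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  req <- c("gene_id", "log2fc", "pvalue", "fdr", "logcpm_normal")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("DE table misses column(s): ", paste(miss, collapse = ", "))
  if (any(x$pvalue < 0 | x$pvalue > 1, na.rm = TRUE) ||
      any(x$fdr < 0 | x$fdr > 1, na.rm = TRUE)) {
    stop("pvalue/fdr must lie in [0, 1]")
  }
  x
}

#' Per-gene methylation change from associated segments
#'
#' For each gene, the mean of the mean methylation differences of the
#' segments it is associated with; genes whose segments were all discarded
#' by the CpG-coverage filter get no value.
#'
#' @param association Output of [associate_genes()] (columns `gene_id`,
#'   `segment`, indices into the segment table the summaries were built
#'   from).
#' @param segment_summaries Output of [segment_aggregate()] computed over
#'   the *same* segment table, carrying attribute-free row order; pass
#'   `segment_index` to say which original rows survived.
#' @param segment_index Integer vector mapping rows of `segment_summaries`
#'   to original segment indices; defaults to the `segment_index` attribute
#'   that [segment_aggregate()] records (falling back to row order).
#' @return Named numeric vector of per-gene mean differences.
#' @export
gene_meth_change <- function(association, segment_summaries,
                             segment_index = attr(segment_summaries, "segment_index")) {
  if (is.null(segment_index)) segment_index <- seq_len(nrow(segment_summaries))
  stopifnot(length(segment_index) == nrow(segment_summaries))
  val <- stats::setNames(segment_summaries$mean_value, segment_index)
  hit <- as.character(association$segment) %in% names(val)
  a <- association[hit, , drop = FALSE]
  if (nrow(a) == 0) return(stats::setNames(numeric(0), character(0)))
  means <- tapply(val[as.character(a$segment)], a$gene_id, mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Methylation-expression quadrant analysis
#'
#' Places genes into the four quadrants of the (methylation change,
#' expression change) plane: Q1 hypermethylated & up-regulated, Q2
#' hypermethylated & down-regulated, Q3 hypomethylated & down-regulated,
#' Q4 hypomethylated & up-regulated.  Restricted to genes of the focal set
#' that are significantly differentially expressed (`fdr < sig_fdr`) and,
#' optionally, lowly expressed in the controls (`logcpm_normal < 0`).
#' Genes with an exact zero on either axis are excluded from all quadrants.
#'
#' @param genes Character vector: the focal gene set.
#' @param dmeth Named numeric vector of per-gene methylation change.
#' @param de DE table (see [read_de_table()]).
#' @param sig_fdr Significance cutoff on FDR (default 0.05; set to 1 to
#'   disable the filter).
#' @param restrict_lowly Keep only genes with `logcpm_normal < 0`.
#' @return List with `counts` (named Q1..Q4), `fractions`, `n_genes`,
#'   `q1_mean_log2fc`, `q1_mean_dmeth`, and `empty` (TRUE when no gene
#'   survived the restriction).
#' @export
quadrant_analysis <- function(genes, dmeth, de, sig_fdr = 0.05,
                              restrict_lowly = FALSE) {
  d <- de[de$gene_id %in% genes & de$fdr < sig_fdr, , drop = FALSE]
  if (restrict_lowly) d <- d[d$logcpm_normal < 0, , drop = FALSE]
  d <- d[d$gene_id %in% names(dmeth), , drop = FALSE]
  dm <- dmeth[d$gene_id]
  fc <- d$log2fc
  nz <- dm != 0 & fc != 0 & !is.na(dm) & !is.na(fc)
  dm <- dm[nz]; fc <- fc[nz]
  counts <- c(Q1 = sum(dm > 0 & fc > 0), Q2 = sum(dm > 0 & fc < 0),
              Q3 = sum(dm < 0 & fc < 0), Q4 = sum(dm < 0 & fc > 0))
  n <- sum(counts)
  list(counts = counts,
       fractions = if (n > 0) counts / n else counts * NA_real_,
       n_genes = n,
       q1_mean_log2fc = if (counts["Q1"] > 0) mean(fc[dm > 0 & fc > 0]) else NA_real_,
       q1_mean_dmeth = if (counts["Q1"] > 0) mean(dm[dm > 0 & fc > 0]) else NA_real_,
       empty = n == 0)
}

#' Compare expression fold changes of a gene set against a background
#'
#' Two-sided rank-sum test on the log2 fold changes of the focal set versus
#' the background set (focal members are removed from the background
#' first).  Optionally restricted to lowly expressed genes.
#'
#' @param set_a Focal gene ids.
#' @param set_b Background gene ids.
#' @param de DE table.
#' @param restrict_lowly Keep only genes with `logcpm_normal < 0`.
#' @return List with `p_value`, `median_diff` (median log2fc of A minus
#'   median of B), `direction` (+1 / -1 / 0), `n_a`, `n_b`; the test is
#'   skipped (NA p) when either set has fewer than 2 genes after
#'   restriction.
#' @export
fc_group_comparison <- function(set_a, set_b, de, restrict_lowly = FALSE) {
  set_b <- setdiff(set_b, set_a)
  d <- de
  if (restrict_lowly) d <- d[d$logcpm_normal < 0, , drop = FALSE]
  a <- d$log2fc[d$gene_id %in% set_a]
  b <- d$log2fc[d$gene_id %in% set_b]
  if (length(a) < 2 || length(b) < 2) {
    return(list(p_value = NA_real_, median_diff = NA_real_, direction = NA,
                n_a = length(a), n_b = length(b), test_skipped = TRUE))
  }
  p <- stats::wilcox.test(a, b, alternative = "two.sided")$p.value
  md <- stats::median(a) - stats::median(b)
  list(p_value = p, median_diff = md, direction = sign(md),
       n_a = length(a), n_b = length(b), test_skipped = FALSE)
}

#' Recurrently up- and down-regulated genes across cancers
#'
#' A gene enters the up set when it is significantly differentially
#' expressed with positive log2 fold change in strictly more than
#' `min_fraction` of the supplied DE tables *and* in at least
#' `min_datasets` of them; the down set is symmetric.  A gene qualifying
#' for both directions (only possible with unusual inputs) is assigned to
#' the direction with the larger dataset count; ties are excluded.
#'
#' @param de_tables Named list of DE tables (one per cancer).
#' @param genes Gene ids to consider (e.g. FBS genes).
#' @param min_fraction Strict fraction of tables (default 0.5).
#' @param min_datasets Absolute minimum number of tables (default 10).
#' @param sig_fdr FDR cutoff for significance (default 0.05).
#' @return List with `up`, `down` (character vectors) and `counts`
#'   (data.frame `gene_id`, `n_up`, `n_down`).
#' @export
recurrence_sets <- function(de_tables, genes, min_fraction = 0.5,
                            min_datasets = 10, sig_fdr = 0.05) {
  stopifnot(length(de_tables) >= 1)
  n_tab <- length(de_tables)
  n_up <- stats::setNames(integer(length(genes)), genes)
  n_down <- n_up
  for (d in de_tables) {
    sig <- d[d$gene_id %in% genes & d$fdr < sig_fdr, , drop = FALSE]
    up <- unique(sig$gene_id[sig$log2fc > 0])
    down <- unique(sig$gene_id[sig$log2fc < 0])
    n_up[up] <- n_up[up] + 1L
    n_down[down] <- n_down[down] + 1L
  }
  qual_up <- n_up > min_fraction * n_tab & n_up >= min_datasets
  qual_down <- n_down > min_fraction * n_tab & n_down >= min_datasets
  both <- qual_up & qual_down
  up_set <- names(n_up)[qual_up & (!both | n_up > n_down)]
  down_set <- names(n_down)[qual_down & (!both | n_down > n_up)]
  list(up = up_set, down = down_set,
       counts = data.frame(gene_id = genes, n_up = unname(n_up),
                           n_down = unname(n_down),
                           stringsAsFactors = FALSE))
}
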