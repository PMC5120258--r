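#' Chromatin category map
#'
#' Groups the 15 Roadmap states into 8 chromatin categories: Bivalent
#' (TssBiv, BivFlnk, EnhBiv), Promoter (TssA, TssAFlnk), Transcribed
#' (TxFlnk, Tx, TxWk), Enhancer (Enh, EnhG), PolycombRepressed (ReprPC,
#' ReprPCWk), ZNF (ZNF/Rpts), Quiescent (Quies) and Heterochromatin (Het).
#'
#' @return Named character vector mapping each state to its category.
#' @export
chromatin_categories <- function() {
  c(TssA = "Promoter", TssAFlnk = "Promoter",
    TxFlnk = "Transcribed", Tx = "Transcribed", TxWk = "Transcribed",
    EnhG = "Enhancer", Enh = "Enhancer",
    `ZNF/Rpts` = "ZNF",
    Het = "Heterochromatin",
    TssBiv = "Bivalent", BivFlnk = "Bivalent", EnhBiv = "Bivalent",
    ReprPC = "PolycombRepressed", ReprPCWk = "PolycombRepressed",
    Quies = "Quiescent")
}

#' Relabel a segmentation with chromatin categories
#'
#' Replaces each state label by its category and coalesces book-ended
#' intervals carrying the same category; base coverage is unchanged.
#'
#' @param seg A [segmentation()] (or BED-like data.frame with a `state`
#'   column).
#' @param map Named state-to-category vector; must cover every state present.
#' @return data.frame `chrom`, `start`, `end`, `category`, sorted, with the
#'   input's `dataset_id` attribute preserved.
#' @export
categorize <- function(seg, map = chromatin_categories()) {
  unmapped <- setdiff(unique(seg$state), names(map))
  if (length(unmapped)) {
    stop("state(s) without a category mapping: ",
         paste(unmapped, collapse = ", "))
  }
  x <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                  category = unname(map[seg$state]), stringsAsFactors = FALSE)
  x <- .sort_intervals(x)
  if (nrow(x) > 1) {
    # coalesce runs of book-ended same-category intervals
    new_run <- c(TRUE, !(x$chrom[-1] == x$chrom[-nrow(x)] &
                         x$category[-1] == x$category[-nrow(x)] &
                         x$start[-1] == x$end[-nrow(x)])
                 )
    run <- cumsum(new_run)
    x <- data.frame(
      chrom = tapply(x$chrom, run, `[`, 1),
      start = as.integer(tapply(x$start, run, min)),
      end = as.integer(tapply(x$end, run, max)),
      category = tapply(x$category, run, `[`, 1),
      stringsAsFactors = FALSE
    )
    x <- .sort_intervals(x)
  }
  rownames(x) <- NULL
  attr(x, "dataset_id") <- attr(seg, "dataset_id")
  x
}

#' Per-category stability between a reference and a query segmentation
#'
#' For each chromatin category, the stability is the fraction of the
#' reference's bases of that category that carry the same category in the
#' query.  Bases covered by the reference but absent from the query's
#' coverage count as changed.  The statistic is directional: the normal
#' (reference) segmentation defines the denominator.
#'
#' @param reference,query Categorized segmentations (see [categorize()]).
#' @param pair_id Identifier recorded in the output.
#' @param categories Categories to report (default: all 8).
#' @return data.frame with `pair_id`, `category`, `stability` (NA when the
#'   category is absent from the reference) and `reference_bases`.
#' @export
pair_stability <- function(reference, query, pair_id = NA_character_,
                           categories = sort(unique(chromatin_categories()))) {
  res <- lapply(categories, function(cat) {
    ref_c <- reference[reference$category == cat, , drop = FALSE]
    qry_c <- query[query$category == cat, , drop = FALSE]
    nref <- covered_bases(ref_c)
    stab <- if (nref == 0) NA_real_ else overlap_bases(ref_c, qry_c) / nref
    data.frame(pair_id = pair_id, category = cat, stability = stab,
               reference_bases = nref, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Contrast category stability between cancer and normal pairs
#'
#' Given stability records for cancer pairs (cancer cell line vs cell of
#' origin) and for normal pairs (related normal cells), computes per
#' category the group mean stabilities and the difference
#' `delta = mean(normal) - mean(cancer)`, the z-score of each category's
#' delta against the mean/SD of all category deltas, and a two-sided
#' rank-sum p-value comparing the Bivalent stabilities of the cancer pairs
#' against the pooled other-category stabilities of the cancer pairs.
#' Categories observed in only one group are excluded from the z-score
#' distribution and reported with `NA` z.
#'
#' @param records data.frame of stacked [pair_stability()] rows with an
#'   additional `group` column (`"cancer"` or `"normal"`).
#' @param focus Category for the rank-sum contrast (default `"Bivalent"`).
#' @return List with `summary` (per-category data.frame: means, delta, z)
#'   and `focus_p` (the rank-sum p-value).
#' @export
compare_stability_groups <- function(records, focus = "Bivalent") {
  stopifnot(all(c("group", "category", "stability") %in% names(records)),
            all(records$group %in% c("cancer", "normal")))
  rec <- records[!is.na(records$stability), , drop = FALSE]
  cats <- sort(unique(rec$category))
  mean_of <- function(cat, grp) {
    v <- rec$stability[rec$category == cat & rec$group == grp]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  m_can <- vapply(cats, mean_of, 0, grp = "cancer")
  m_nor <- vapply(cats, mean_of, 0, grp = "normal")
  delta <- m_nor - m_can
  usable <- !is.na(delta)
  z <- rep(NA_real_, length(cats))
  if (sum(usable) >= 2) {
    s <- stats::sd(delta[usable])
    if (s > 0) z[usable] <- (delta[usable] - mean(delta[usable])) / s
    else z[usable] <- 0
  }
  summary <- data.frame(category = cats, mean_cancer = m_can,
                        mean_normal = m_nor, delta = delta, z = z,
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  foc <- rec$stability[rec$category == focus & rec$group == "cancer"]
  oth <- rec$stability[rec$category != focus & rec$group == "cancer"]
  focus_p <- if (length(foc) >= 1 && length(oth) >= 1) {
    stats::wilcox.test(foc, oth, alternative = "two.sided",
                       exact = (length(foc) + length(oth) <= 20 &&
                                !anyDuplicated(c(foc, oth))),
                       correct = TRUE)$p.value
  } else NA_real_
  list(summary = summary, focus_p = focus_p)
}
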