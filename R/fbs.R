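#' Support rules for merged-segment thresholds
#'
#' A frequently bivalent segment is a merged bivalent interval supported by a
#' minimum number of distinct cell types.  Two thresholds are used:
#' a fractional rule keeping segments whose support is *strictly greater*
#' than `fraction * n_inputs` (0.8 over 122 segmentations reproduces the "at
#' least 98 of 122" selection), and an absolute rule keeping
#' `support >= min_support` (120 of 122 for the classifier set; 7 of 8 for
#' the ESC comparison set).
#'
#' @param fraction Strict support fraction in (0, 1).
#' @param min_support Absolute minimum support count (>= 1).
#' @return A `support_rule` object.
#' @export
support_rule <- function(fraction = NULL, min_support = NULL) {
  if (is.null(fraction) == is.null(min_support)) {
    stop("give exactly one of `fraction` or `min_support`")
  }
  if (!is.null(fraction) && (fraction <= 0 || fraction >= 1)) {
    stop("fraction must lie in (0, 1)")
  }
  if (!is.null(min_support) && min_support < 1) {
    stop("min_support must be >= 1")
  }
  structure(list(fraction = fraction, min_support = min_support),
            class = "support_rule")
}

# does `support` (out of n_inputs) pass the rule?
.rule_passes <- function(rule, support, n_inputs) {
  stopifnot(inherits(rule, "support_rule"))
  if (!is.null(rule$fraction)) {
    support > rule$fraction * n_inputs
  } else {
    if (rule$min_support > n_inputs) {
      stop("min_support (", rule$min_support, ") exceeds n_inputs (",
           n_inputs, ")")
    }
    support >= rule$min_support
  }
}

#' Merge state intervals across segmentations with distinct-contributor counts
#'
#' Pools the intervals of the requested states from every input segmentation
#' and merges them (book-ended intervals merge, as in `bedtools merge` with
#' its distinct-count option).  Each merged segment records the set of
#' dataset ids that contributed at least one interval to its merge cluster;
#' `support` is the number of distinct contributors.
#'
#' @param segmentations List of [segmentation()] objects.
#' @param states Character vector of state mnemonics to pool (non-empty).
#' @return data.frame `chrom`, `start`, `end`, `support`, plus a list-column
#'   `contributors` of dataset-id character vectors; attribute `n_inputs`.
#' @export
count_distinct_merge <- function(segmentations, states = bivalent_states()) {
  stopifnot(length(segmentations) >= 1)
  if (length(states) == 0) stop("empty state subset")
  ids <- vapply(segmentations, dataset_id, "")
  if (anyDuplicated(ids)) stop("duplicate dataset ids among segmentations")
  pieces <- lapply(seq_along(segmentations), function(i) {
    s <- segmentations[[i]]
    s <- s[s$state %in% states, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(s)) s$dataset <- ids[i]
    s
  })
  pooled <- do.call(rbind, pieces[vapply(pieces, nrow, 0L) > 0])
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      support = integer(), stringsAsFactors = FALSE)
  empty$contributors <- list()
  if (is.null(pooled) || nrow(pooled) == 0) {
    attr(empty, "n_inputs") <- length(segmentations)
    return(empty)
  }
  gr <- .as_gr(pooled)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1, with.revmap = TRUE)
  red <- GenomicRanges::sort(red)
  out <- .from_gr(red)
  revmap <- S4Vectors::mcols(red)$revmap
  contrib <- lapply(as.list(revmap), function(ix) sort(unique(pooled$dataset[ix])))
  out$support <- lengths(contrib)
  out$contributors <- contrib
  attr(out, "n_inputs") <- length(segmentations)
  out
}

#' Threshold merged segments into a frequently-bivalent-segment set
#'
#' @param merged Output of [count_distinct_merge()].
#' @param n_inputs Number of segmentations the merge was computed over
#'   (defaults to the attribute recorded by [count_distinct_merge()]).
#' @param rule A [support_rule()]; the default, `support_rule(fraction =
#'   0.8)`, keeps segments bivalent in strictly more than 80% of inputs
#'   ("at least 98 of 122").
#' @param states State subset the merge was built from (metadata).
#' @return `fbs_set`: the passing rows of `merged`, with attributes
#'   `n_inputs`, `rule`, `states`.
#' @export
build_fbs <- function(merged, n_inputs = attr(merged, "n_inputs"),
                      rule = support_rule(fraction = 0.8),
                      states = bivalent_states()) {
  stopifnot(!is.null(n_inputs))
  keep <- .rule_passes(rule, merged$support, n_inputs)
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_inputs") <- n_inputs
  attr(out, "rule") <- rule
  attr(out, "states") <- states
  class(out) <- c("fbs_set", "data.frame")
  out
}

#' Conditional segment sets (bivalent in group A but not group B)
#'
#' Returns the segments of `merged_a` that pass `rule_a` and whose maximal
#' support among overlapping segments of `merged_b` *fails* `rule_b`
#' (a segment with no overlap in B has support 0 there).  Used for control
#' sets such as "bivalent in at least 3 ESC but in fewer than 12 normal
#' segmentations".
#'
#' @param merged_a,merged_b Outputs of [count_distinct_merge()] over the two
#'   input groups.
#' @param rule_a,rule_b [support_rule()]s evaluated against the respective
#'   group sizes.
#' @param n_a,n_b Group sizes (default: recorded attributes).
#' @return `fbs_set` of the qualifying `merged_a` segments.
#' @export
build_conditional_set <- function(merged_a, rule_a, merged_b, rule_b,
                                  n_a = attr(merged_a, "n_inputs"),
                                  n_b = attr(merged_b, "n_inputs")) {
  pass_a <- .rule_passes(rule_a, merged_a$support, n_a)
  cand <- merged_a[pass_a, , drop = FALSE]
  if (nrow(cand) == 0 || nrow(merged_b) == 0) {
    b_support <- rep(0L, nrow(cand))
  } else {
    hits <- GenomicRanges::findOverlaps(.as_gr(cand), .as_gr(merged_b))
    b_support <- rep(0L, nrow(cand))
    if (length(hits)) {
      mx <- tapply(merged_b$support[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), max)
      b_support[as.integer(names(mx))] <- as.integer(mx)
    }
  }
  keep <- !.rule_passes(rule_b, b_support, n_b)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_inputs") <- n_a
  attr(out, "rule") <- rule_a
  class(out) <- c("fbs_set", "data.frame")
  out
}

#' Active-promoter background set
#'
#' Merges the TssA (active promoter) intervals across all segmentations and
#' discards, whole, every merged segment that overlaps a frequently bivalent
#' segment.
#'
#' @param segmentations List of [segmentation()] objects.
#' @param fbs FBS interval table to exclude.
#' @param states States treated as active promoter (default `"TssA"`).
#' @return Sorted interval data.frame of background promoter segments.
#' @export
build_background_promoters <- function(segmentations, fbs, states = "TssA") {
  pooled <- do.call(rbind, lapply(segmentations, function(s) {
    s[s$state %in% states, c("chrom", "start", "end"), drop = FALSE]
  }))
  merged <- merge_intervals(pooled, max_gap = 0)
  subtract_intervals(merged, fbs)
}

#' Associate genes with segments
#'
#' A gene is associated with a segment when the segment overlaps the gene
#' body or its promoter region by at least one base.  The promoter is an
#' upstream extension of `promoter_window` nt: the gene window is
#' `[max(0, start - w), end)` on the + strand and `[start, end + w)` on the
#' - strand.
#'
#' @param segments Interval data.frame.
#' @param genes Gene model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param promoter_window Upstream extension in nt (default 1500).
#' @return data.frame with columns `gene_id`, `segment` (row index into
#'   `segments`); attribute `promoter_window`.
#' @export
associate_genes <- function(segments, genes, promoter_window = 1500) {
  stopifnot(promoter_window >= 0)
  empty <- data.frame(gene_id = character(), segment = integer(),
                      stringsAsFactors = FALSE)
  attr(empty, "promoter_window") <- promoter_window
  if (nrow(segments) == 0 || nrow(genes) == 0) return(empty)
  wstart <- ifelse(genes$strand == "+",
                   pmax(0L, genes$start - as.integer(promoter_window)),
                   genes$start)
  wend <- ifelse(genes$strand == "+",
                 genes$end, genes$end + as.integer(promoter_window))
  win <- data.frame(chrom = genes$chrom, start = wstart, end = wend)
  hits <- GenomicRanges::findOverlaps(.as_gr(win), .as_gr(segments))
  out <- data.frame(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    segment = S4Vectors::subjectHits(hits),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$segment), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "promoter_window") <- promoter_window
  out
}

#' Segment-level FBS coverage statistics
#'
#' For one segmentation, computes (i) the fraction of FBSs that overlap at
#' least one bivalent segment of the segmentation and (ii) the fraction of
#' the segmentation's bivalent segments that overlap at least one FBS.
#' Overlap is segment-level (>= 1 bp), not base-fraction.
#'
#' @param fbs FBS interval table.
#' @param seg A [segmentation()].
#' @param states States counted as bivalent in `seg` (default
#'   [bivalent_states()]).
#' @return List with `fraction_of_fbs_bivalent` and
#'   `fraction_of_bivalent_in_fbs` (the latter `NA` when `seg` has no
#'   bivalent segments).
#' @export
fbs_coverage_stats <- function(fbs, seg, states = bivalent_states()) {
  biv <- seg[seg$state %in% states, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(fbs) == 0) {
    return(list(fraction_of_fbs_bivalent = NA_real_,
                fraction_of_bivalent_in_fbs = NA_real_))
  }
  if (nrow(biv) == 0) {
    return(list(fraction_of_fbs_bivalent = 0,
                fraction_of_bivalent_in_fbs = NA_real_))
  }
  f1 <- mean(GenomicRanges::countOverlaps(.as_gr(fbs), .as_gr(biv)) > 0)
  f2 <- mean(GenomicRanges::countOverlaps(.as_gr(biv), .as_gr(fbs)) > 0)
  list(fraction_of_fbs_bivalent = f1, fraction_of_bivalent_in_fbs = f2)
}
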