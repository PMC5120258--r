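#' Construct a beta-value matrix
#'
#' Container for 450k-style methylation data: CpG site annotation, per-sample
#' beta values in [0, 1] (NA = not covered), and a tumor/control group label
#' per sample.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos` (0-based).
#' @param values Numeric matrix, sites x samples; rownames must equal
#'   `sites$site_id`, colnames are sample ids.
#' @param groups Named character vector (or 2-column data.frame
#'   `sample_id`/`group`) assigning each sample to `"tumor"` or `"control"`.
#' @return A `beta_matrix` list with elements `sites`, `values`, `groups`.
#' @export
beta_matrix <- function(sites, values, groups) {
  stopifnot(all(c("site_id", "chrom", "pos") %in% names(sites)),
            is.matrix(values), nrow(values) == nrow(sites))
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  if (any(sites$pos < 0)) stop("site positions must be >= 0")
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  if (!all(colnames(values) %in% names(groups))) {
    stop("every sample needs a group label")
  }
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("tumor", "control"))) {
    stop("groups must be 'tumor' or 'control'")
  }
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  rownames(values) <- sites$site_id
  structure(list(sites = sites, values = values, groups = groups),
            class = "beta_matrix")
}

#' Read a beta-value matrix from TSV
#'
#' The values file has a header row of sample ids and rows
#' `site_id  chrom  pos  <betas...>` with missing values written as `NA`.
#' The groups file is a two-column TSV `sample_id  group` with a header.
#'
#' @param values_path,groups_path File paths.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(values_path, groups_path) {
  x <- utils::read.table(values_path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  sites <- data.frame(site_id = as.character(x[[1]]), chrom = as.character(x[[2]]),
                      pos = as.integer(x[[3]]), stringsAsFactors = FALSE)
  values <- as.matrix(x[, -(1:3), drop = FALSE])
  g <- utils::read.table(groups_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  beta_matrix(sites, values, stats::setNames(g[[2]], g[[1]]))
}

#' Write a beta-value matrix to TSV
#'
#' @param bm A [beta_matrix()].
#' @param values_path,groups_path Output paths.
#' @export
write_beta_matrix <- function(bm, values_path, groups_path) {
  out <- cbind(bm$sites, as.data.frame(bm$values, check.names = FALSE))
  utils::write.table(out, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- data.frame(sample_id = names(bm$groups), group = unname(bm$groups))
  utils::write.table(g, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}

#' Read a per-CpG bedGraph track
#'
#' bedGraph intervals (chrom, start, end, value) are interpreted as per-site
#' values anchored at the interval start, the layout of WGBS-style CpG
#' methylation(-difference) tracks.
#'
#' @param path bedGraph file path (no header; `track` lines are skipped).
#' @return data.frame `chrom`, `pos`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = integer(), value = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[[`, "", 1L),
             pos = as.integer(vapply(f, `[[`, "", 2L)),
             value = as.numeric(vapply(f, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Per-CpG tumor-minus-control mean methylation difference
#'
#' Group means are taken over non-missing beta values per site; the
#' difference is mean(tumor) - mean(control).  Sites covered in only one
#' group get a missing difference.
#'
#' @param bm A [beta_matrix()] with at least one tumor and one control
#'   sample.
#' @return data.frame `site_id`, `chrom`, `pos`, `mean_tumor`,
#'   `mean_control`, `diff`, `n_tumor`, `n_control`.
#' @export
group_mean_diff <- function(bm) {
  stopifnot(inherits(bm, "beta_matrix"))
  tum <- bm$values[, bm$groups == "tumor", drop = FALSE]
  ctl <- bm$values[, bm$groups == "control", drop = FALSE]
  if (ncol(tum) == 0 || ncol(ctl) == 0) {
    stop("both tumor and control groups must be non-empty")
  }
  n_t <- rowSums(!is.na(tum))
  n_c <- rowSums(!is.na(ctl))
  m_t <- ifelse(n_t > 0, rowMeans(tum, na.rm = TRUE), NA_real_)
  m_c <- ifelse(n_c > 0, rowMeans(ctl, na.rm = TRUE), NA_real_)
  data.frame(site_id = bm$sites$site_id, chrom = bm$sites$chrom,
             pos = bm$sites$pos, mean_tumor = m_t, mean_control = m_c,
             diff = m_t - m_c, n_tumor = n_t, n_control = n_c,
             stringsAsFactors = FALSE)
}

# sites falling in [start, end) of each segment; returns integer segment
# index per site (NA if in no segment). Segments may not overlap.
.site_segment <- function(track, segments) {
  if (nrow(track) == 0 || nrow(segments) == 0) {
    return(rep(NA_integer_, nrow(track)))
  }
  sgr <- .as_gr(segments)
  pgr <- GenomicRanges::GRanges(track$chrom,
                                IRanges::IRanges(track$pos + 1L, track$pos + 1L))
  hits <- GenomicRanges::findOverlaps(pgr, sgr, select = "first")
  as.integer(hits)
}

#' Aggregate a per-CpG track over segments
#'
#' Unweighted mean of the non-missing per-site values falling inside each
#' segment (`[start, end)`).  Segments covering fewer than `min_cpgs` sites
#' are discarded; the number dropped is recorded in the `n_dropped`
#' attribute.
#'
#' @param track data.frame with `chrom`, `pos` and a value column.
#' @param segments Interval data.frame.
#' @param min_cpgs Minimum covered CpGs per reported segment (default 3).
#' @param value_col Name of the value column (default `"diff"`, falling back
#'   to `"value"`).
#' @return data.frame `chrom`, `start`, `end`, `n_cpgs`, `mean_value` (one
#'   row per surviving segment, in input order), with attribute `n_dropped`.
#' @export
segment_aggregate <- function(track, segments, min_cpgs = 3,
                              value_col = if ("diff" %in% names(track)) "diff" else "value") {
  .check_intervals(segments, "segments")
  vals <- track[[value_col]]
  ok <- !is.na(vals)
  idx <- .site_segment(track[ok, , drop = FALSE], segments)
  vals <- vals[ok][!is.na(idx)]
  idx <- idx[!is.na(idx)]
  n <- tabulate(idx, nbins = nrow(segments))
  s <- rep(0, nrow(segments))
  if (length(idx)) {
    sums <- tapply(vals, idx, sum)
    s[as.integer(names(sums))] <- sums
  }
  keep <- n >= min_cpgs
  out <- data.frame(chrom = segments$chrom[keep], start = segments$start[keep],
                    end = segments$end[keep], n_cpgs = n[keep],
                    mean_value = s[keep] / n[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "segment_index") <- which(keep)
  out
}

#' Binned methylation profile across segments and their flanks
#'
#' Each segment of length L is extended by `extension * L` on both sides and
#' the window split into `n_bins` equal bins (by default 300 bins of L/100
#' each: bins 1-100 left flank, 101-200 segment body, 201-300 right flank).
#' Per segment and bin, the mean of the covered site values is taken; the
#' profile value of a bin is the mean over segments with data in that bin
#' (bins without any data are NA, not 0).  Windows extending below position
#' 0 simply contribute no sites there.
#'
#' @param segments Interval data.frame (non-empty).
#' @param track Per-site value table (`chrom`, `pos`, value column).
#' @param extension Flank size as a fraction of segment length (default 1).
#' @param n_bins Total number of bins (default 300).
#' @param value_col Value column name.
#' @return data.frame `bin` (1..n_bins), `mean_value`, `n_segments`.
#' @export
border_profile <- function(segments, track, extension = 1, n_bins = 300,
                           value_col = if ("diff" %in% names(track)) "diff" else "value") {
  .check_intervals(segments, "segments")
  if (nrow(segments) == 0) stop("border_profile needs at least one segment")
  vals <- track[[value_col]]
  ok <- !is.na(vals)
  tr <- track[ok, , drop = FALSE]
  vals <- vals[ok]
  acc_sum <- matrix(0, nrow = nrow(segments), ncol = n_bins)
  acc_n <- matrix(0L, nrow = nrow(segments), ncol = n_bins)
  for (i in seq_len(nrow(segments))) {
    L <- segments$end[i] - segments$start[i]
    wstart <- segments$start[i] - extension * L
    binw <- L * (1 + 2 * extension) / n_bins
    onchrom <- tr$chrom == segments$chrom[i]
    if (!any(onchrom)) next
    b <- floor((tr$pos[onchrom] - wstart) / binw) + 1
    inwin <- b >= 1 & b <= n_bins
    if (!any(inwin)) next
    bb <- b[inwin]
    vv <- vals[onchrom][inwin]
    sums <- tapply(vv, bb, sum)
    cnts <- tapply(vv, bb, length)
    j <- as.integer(names(sums))
    acc_sum[i, j] <- sums
    acc_n[i, j] <- cnts
  }
  seg_mean <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  n_seg <- colSums(acc_n > 0)
  prof <- ifelse(n_seg > 0, colMeans(seg_mean, na.rm = TRUE), NA_real_)
  data.frame(bin = seq_len(n_bins), mean_value = prof, n_segments = n_seg)
}

#' Border profiles split by segment length
#'
#' Convenience wrapper partitioning the segments at a length threshold
#' (default 10,000 nt) before profiling, mirroring the short/long FBS
#' comparison.
#'
#' @inheritParams border_profile
#' @param threshold Length threshold in nt.
#' @return List with elements `short` and `long` (either may be NULL when
#'   its partition is empty).
#' @export
border_profile_by_length <- function(segments, track, threshold = 10000,
                                     extension = 1, n_bins = 300, ...) {
  len <- segments$end - segments$start
  short <- segments[len < threshold, , drop = FALSE]
  long <- segments[len >= threshold, , drop = FALSE]
  list(
    short = if (nrow(short)) border_profile(short, track, extension, n_bins, ...) else NULL,
    long = if (nrow(long)) border_profile(long, track, extension, n_bins, ...) else NULL
  )
}

#' Fate of bivalent chromatin between a normal and a cancer segmentation
#'
#' The union of bivalent bases (category TssBiv/BivFlnk/EnhBiv) of the two
#' inputs is partitioned at base level into `stable` (bivalent in both),
#' `lost` (bivalent only in the normal segmentation) and `new` (bivalent
#' only in the cancer segmentation).
#'
#' @param normal_seg,cancer_seg [segmentation()] objects.
#' @param states States counted as bivalent (default
#'   [bivalent_category_states()]).
#' @return Sorted data.frame `chrom`, `start`, `end`, `fate`.
#' @export
bivalency_fate <- function(normal_seg, cancer_seg,
                           states = bivalent_category_states()) {
  nb <- normal_seg[normal_seg$state %in% states,
                   c("chrom", "start", "end"), drop = FALSE]
  cb <- cancer_seg[cancer_seg$state %in% states,
                   c("chrom", "start", "end"), drop = FALSE]
  stable <- intersect_bases(nb, cb)
  lost <- setdiff_bases(nb, cb)
  new <- setdiff_bases(cb, nb)
  add_fate <- function(x, f) if (nrow(x)) cbind(x, fate = f) else NULL
  out <- rbind(add_fate(stable, "stable"), add_fate(lost, "lost"),
               add_fate(new, "new"))
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      fate = character(), stringsAsFactors = FALSE))
  }
  out <- .sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Methylation change by bivalency fate
#'
#' Aggregates a methylation-difference track over the stable/lost/new fate
#' intervals (>= `min_cpgs` covered CpGs each) and tests, two-sided rank-sum,
#' whether lost regions are differently methylated than stable ones.
#'
#' @param fates Output of [bivalency_fate()].
#' @param track Per-site difference table.
#' @param min_cpgs Minimum covered CpGs per aggregated interval.
#' @param value_col Value column name.
#' @return List with `summary` (per fate: `n_segments`, `mean_diff`),
#'   `p_lost_vs_stable` (NA with a `test_skipped` note when a fate has
#'   fewer than 2 aggregated segments) and `values` (per-fate aggregated
#'   means).
#' @export
fate_meth_comparison <- function(fates, track, min_cpgs = 3,
                                 value_col = if ("diff" %in% names(track)) "diff" else "value") {
  values <- lapply(c(stable = "stable", lost = "lost", new = "new"), function(f) {
    seg <- fates[fates$fate == f, , drop = FALSE]
    if (nrow(seg) == 0) return(numeric(0))
    segment_aggregate(track, seg, min_cpgs = min_cpgs,
                      value_col = value_col)$mean_value
  })
  summary <- data.frame(
    fate = names(values),
    n_segments = vapply(values, length, 0L),
    mean_diff = vapply(values, function(v) if (length(v)) mean(v) else NA_real_, 0),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  skipped <- length(values$lost) < 2 || length(values$stable) < 2
  p <- if (skipped) NA_real_
  else if (length(unique(c(values$lost, values$stable))) == 1) 1
  else suppressWarnings(
    stats::wilcox.test(values$lost, values$stable,
                       alternative = "two.sided")$p.value)
  list(summary = summary, p_lost_vs_stable = p, test_skipped = skipped,
       values = values)
}
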