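#' Roadmap 15-state mnemonics
#'
#' The state vocabulary of the ChromHMM 15-state core-marks model used by the
#' NIH Roadmap segmentations: active/flanking promoter (TssA, TssAFlnk),
#' transcription (TxFlnk, Tx, TxWk), enhancers (EnhG, Enh), ZNF/repeats,
#' heterochromatin (Het), bivalent chromatin (TssBiv, BivFlnk, EnhBiv),
#' Polycomb repression (ReprPC, ReprPCWk) and quiescent (Quies).
#'
#' @format Character vector of the 15 state mnemonics.
#' @export
roadmap_states <- c(
  "TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF/Rpts",
  "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies"
)

#' Bivalent state subsets
#'
#' `bivalent_states()` returns the two states used to build frequently
#' bivalent segments (bivalent promoter and bivalent enhancer);
#' `bivalent_category_states()` additionally includes flanking bivalent,
#' the grouping used for chromatin-category stability and bivalency fate.
#'
#' @return Character vector of state mnemonics.
#' @export
bivalent_states <- function() c("TssBiv", "EnhBiv")

#' @rdname bivalent_states
#' @export
bivalent_category_states <- function() c("TssBiv", "BivFlnk", "EnhBiv")

## ---- internal helpers -------------------------------------------------------

# data.frame (BED, 0-based half-open) -> GRanges (1-based closed)
.as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> BED data.frame
.from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

.check_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop(what, ": every interval must satisfy 0 <= start < end")
  }
  invisible(x)
}

#' Construct a genomic interval table
#'
#' Intervals use BED conventions throughout the package: 0-based start,
#' exclusive end, one row per interval.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions (`end > start`).
#' @param label Optional label (state or name) per interval.
#' @return A data.frame with columns `chrom`, `start`, `end` and optionally
#'   `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL) {
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(label)) x$label <- as.character(label)
  .check_intervals(x)
  x
}

## ---- segmentation I/O -------------------------------------------------------

#' Read a chromatin state segmentation from a BED file
#'
#' Reads a 4(+)-column tab-separated BED file of chromatin state intervals in
#' the Roadmap dialect.  State fields may carry a numeric prefix
#' (`"10_TssBiv"`), which is stripped; after stripping, every state must be
#' one of the 15 core-marks mnemonics.  Within each chromosome intervals must
#' be non-overlapping (a segmentation is a partition); they are returned
#' sorted.
#'
#' @param path Path to the BED file (may be empty).
#' @param dataset_id Identifier of the cell type / dataset.
#' @return A `segmentation`: data.frame with columns `chrom`, `start`, `end`,
#'   `state` and attribute `dataset_id`.
#' @export
read_segmentation <- function(path, dataset_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(segmentation(data.frame(chrom = character(), start = integer(),
                                   end = integer(), state = character(),
                                   stringsAsFactors = FALSE), dataset_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad)) {
    stop("malformed segmentation line ", bad[1], " in ", path,
         ": expected >= 4 tab-separated columns, got ", nf[bad[1]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  state <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop("malformed segmentation line ", bad[1], " in ", path,
         ": invalid coordinates (need 0 <= start < end)")
  }
  segmentation(data.frame(chrom = chrom, start = start, end = end,
                          state = state, stringsAsFactors = FALSE),
               dataset_id)
}

#' Build a segmentation object from an interval table
#'
#' Normalizes state mnemonics (strips a leading `<digits>_` prefix), checks
#' the 15-state vocabulary and the per-chromosome partition invariant
#' (sorted, non-overlapping), and attaches the dataset id.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `state`.
#' @param dataset_id Identifier string.
#' @return The validated, sorted segmentation data.frame with attribute
#'   `dataset_id` and class `segmentation`.
#' @export
segmentation <- function(x, dataset_id) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(x)))
  .check_intervals(x, "segmentation")
  x$state <- normalize_state(x$state)
  unknown <- setdiff(unique(x$state), roadmap_states)
  if (length(unknown)) {
    stop("unknown chromatin state(s) after mnemonic normalization: ",
         paste(unknown, collapse = ", "))
  }
  x <- .sort_intervals(x)
  if (nrow(x) > 1) {
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    ovl <- same & (x$start[-1] < x$end[-nrow(x)])
    if (any(ovl)) {
      i <- which(ovl)[1]
      stop("overlapping intervals within chromosome ", x$chrom[i + 1],
           " at rows ", i, "/", i + 1, ": a segmentation must be a partition")
    }
  }
  rownames(x) <- NULL
  attr(x, "dataset_id") <- dataset_id
  class(x) <- c("segmentation", "data.frame")
  x
}

#' @rdname segmentation
#' @export
dataset_id <- function(x) attr(x, "dataset_id")

#' Normalize a Roadmap state mnemonic
#'
#' Strips a leading `<digits>_` prefix (`"10_TssBiv"` -> `"TssBiv"`);
#' matching is case-sensitive after stripping.
#'
#' @param state Character vector of raw state fields.
#' @return Character vector of bare mnemonics.
#' @export
normalize_state <- function(state) sub("^[0-9]+_", "", state)

#' Write intervals as BED
#'
#' Tab-separated, no header; optional extra columns (e.g. a label in column 4
#' and a support count in column 5) are written in the order given.
#'
#' @param x Interval data.frame (`chrom`, `start`, `end`, ...).
#' @param path Output file path.
#' @param columns Extra column names to write after the coordinates.
#' @export
write_bed <- function(x, path, columns = intersect(c("label", "state", "support"), names(x))) {
  out <- x[, c("chrom", "start", "end", columns), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of plain intervals
#'
#' @param path Path to a tab-separated BED file (3+ columns, no header).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `label` (column 4).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (ncol(x) >= 4) names(x)[4] <- "label"
  .check_intervals(x, "BED")
  x
}

## ---- gene models ------------------------------------------------------------

#' Read gene models
#'
#' `read_genes_bed` reads a BED-like file with columns chrom, start, end,
#' gene_id, (score), strand.  `read_genes_gtf` reads a GTF and keeps
#' `gene` features, parsing only the `gene_id` attribute; GTF 1-based closed
#' coordinates are converted to 0-based half-open.
#'
#' @param path Path to the annotation file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_genes_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop("gene BED needs at least 4 columns (name in column 4)")
  strand <- if (ncol(x) >= 6) x[[6]] else "+"
  genes <- data.frame(gene_id = x[[4]], chrom = x[[1]], start = x[[2]],
                      end = x[[3]], strand = strand, stringsAsFactors = FALSE)
  .validate_genes(genes)
}

#' @rdname read_genes_bed
#' @export
read_genes_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[[3]] == "gene", FALSE)
  fields <- fields[keep]
  if (!length(fields)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  attrs <- vapply(fields, `[[`, "", 9L)
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?;?.*', "\\1", attrs)
  genes <- data.frame(
    gene_id = gid,
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    stringsAsFactors = FALSE
  )
  .validate_genes(genes)
}

.validate_genes <- function(genes) {
  if (any(genes$start >= genes$end)) stop("gene model with start >= end")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  genes
}

## ---- interval algebra -------------------------------------------------------

#' Merge genomic intervals
#'
#' Merges intervals on the same chromosome whose gap is at most `max_gap`
#' nucleotides; book-ended intervals merge at `max_gap = 0` (the default of
#' the standard merging tool).  Input may be unsorted and span several
#' chromosomes; output is sorted and non-overlapping, and for `max_gap = 0`
#' covers exactly the per-base union of the input.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`).
#' @param max_gap Maximum gap (nt, >= 0) bridged by a merge.
#' @return Sorted, non-overlapping interval data.frame.
#' @export
merge_intervals <- function(intervals, max_gap = 0) {
  .check_intervals(intervals)
  stopifnot(max_gap >= 0)
  if (nrow(intervals) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(.as_gr(intervals), min.gapwidth = max_gap + 1)
  .sort_intervals(.from_gr(GenomicRanges::sort(gr)))
}

#' Bases covered by both interval collections
#'
#' Total number of nucleotides covered by (the union of) `a` and (the union
#' of) `b`; symmetric in its arguments.
#'
#' @param a,b Interval data.frames.
#' @return Non-negative integer base count.
#' @export
overlap_bases <- function(a, b) {
  .check_intervals(a); .check_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  ga <- GenomicRanges::reduce(.as_gr(a))
  gb <- GenomicRanges::reduce(.as_gr(b))
  sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
}

#' Total covered bases of an interval collection
#'
#' @param a Interval data.frame.
#' @return Number of bases in the per-base union of `a`.
#' @export
covered_bases <- function(a) {
  .check_intervals(a)
  if (nrow(a) == 0) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(.as_gr(a))))
}

#' Whole-interval subtraction
#'
#' Returns the members of `a` that overlap no member of `b` by even a single
#' base.  This is whole-interval discarding, not base-level clipping: a
#' segment touching `b` anywhere is dropped entirely.
#'
#' @param a,b Interval data.frames.
#' @return Subset of the rows of `a`.
#' @export
subtract_intervals <- function(a, b) {
  .check_intervals(a); .check_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  hits <- GenomicRanges::countOverlaps(.as_gr(a), .as_gr(b))
  a[hits == 0, , drop = FALSE]
}

#' Base-level interval set operations
#'
#' `intersect_bases` and `setdiff_bases` return the base-level intersection
#' and difference of two interval collections as sorted interval tables.
#'
#' @param a,b Interval data.frames.
#' @return Sorted interval data.frame.
#' @export
intersect_bases <- function(a, b) {
  .check_intervals(a); .check_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  .from_gr(GenomicRanges::sort(GenomicRanges::intersect(
    GenomicRanges::reduce(.as_gr(a)), GenomicRanges::reduce(.as_gr(b)))))
}

#' @rdname intersect_bases
#' @export
setdiff_bases <- function(a, b) {
  .check_intervals(a); .check_intervals(b)
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end"), drop = FALSE])
  ga <- GenomicRanges::reduce(.as_gr(a))
  if (nrow(b) == 0) return(.from_gr(GenomicRanges::sort(ga)))
  .from_gr(GenomicRanges::sort(GenomicRanges::setdiff(ga, .as_gr(b))))
}
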