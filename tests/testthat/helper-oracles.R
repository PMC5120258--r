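# Brute-force oracles and random-fixture generators used across the suite.
# Every oracle works by explicit per-base / per-pair enumeration on small
# chromosomes (<= 10,000 nt) and is kept independent of the package's
# interval machinery.

# coverage bit vector of one chromosome's intervals (positions 1..maxpos
# represent bases 0..maxpos-1)
or_coverage <- function(x, maxpos) {
  v <- logical(maxpos)
  for (i in seq_len(nrow(x))) {
    if (x$end[i] > x$start[i]) v[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  v
}

# per-base merge oracle: runs of covered bases, bridging gaps <= max_gap
or_merge <- function(x, max_gap = 0, maxpos = 10000) {
  out <- NULL
  for (chrom in sort(unique(x$chrom))) {
    v <- or_coverage(x[x$chrom == chrom, ], maxpos)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
    if (nrow(runs) > 1 && max_gap > 0) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        if (runs$start[i] - merged$end[nrow(merged)] <= max_gap) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else merged <- rbind(merged, runs[i, ])
      }
      runs <- merged
    }
    if (nrow(runs)) out <- rbind(out, cbind(chrom = chrom, runs))
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  rownames(out) <- NULL
  out
}

or_overlap_bases <- function(a, b, maxpos = 10000) {
  total <- 0
  for (chrom in union(a$chrom, b$chrom)) {
    total <- total + sum(or_coverage(a[a$chrom == chrom, ], maxpos) &
                         or_coverage(b[b$chrom == chrom, ], maxpos))
  }
  total
}

# distinct-contributor oracle: merge pooled intervals per base, then count
# datasets whose intervals fall inside each merged cluster
or_distinct_merge <- function(pooled, maxpos = 10000) {
  merged <- or_merge(pooled, max_gap = 0, maxpos = maxpos)
  if (nrow(merged) == 0) return(cbind(merged, support = integer()))
  merged$support <- vapply(seq_len(nrow(merged)), function(i) {
    inside <- pooled$chrom == merged$chrom[i] &
      pooled$start >= merged$start[i] & pooled$end <= merged$end[i]
    length(unique(pooled$dataset[inside]))
  }, 0L)
  merged
}

# pairwise-comparison AUC with half-credit ties
or_auc <- function(score, label) {
  pos <- score[label == "cancer"]
  neg <- score[label == "normal"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# per-site scan aggregate oracle
or_segment_aggregate <- function(track, segments, min_cpgs = 3,
                                 value_col = "value") {
  res <- NULL
  for (i in seq_len(nrow(segments))) {
    v <- track[[value_col]][track$chrom == segments$chrom[i] &
                            track$pos >= segments$start[i] &
                            track$pos < segments$end[i]]
    v <- v[!is.na(v)]
    if (length(v) >= min_cpgs) {
      res <- rbind(res, data.frame(segment = i, n_cpgs = length(v),
                                   mean_value = mean(v)))
    }
  }
  res
}

# double-loop quadrant counting oracle
or_quadrants <- function(dm, fc) {
  counts <- c(Q1 = 0L, Q2 = 0L, Q3 = 0L, Q4 = 0L)
  for (i in seq_along(dm)) {
    if (is.na(dm[i]) || is.na(fc[i]) || dm[i] == 0 || fc[i] == 0) next
    q <- if (dm[i] > 0 && fc[i] > 0) "Q1" else if (dm[i] > 0) "Q2"
         else if (fc[i] < 0) "Q3" else "Q4"
    counts[q] <- counts[q] + 1L
  }
  counts
}

# random small interval fixtures on chromosomes <= 10,000 nt
rand_intervals <- function(n, chroms = c("cA", "cB"), maxpos = 10000) {
  start <- sample.int(maxpos - 1, n, replace = TRUE) - 1
  len <- sample.int(300, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = pmin(start + len, maxpos), stringsAsFactors = FALSE)
}

# random non-overlapping labeled segmentation covering part of one chromosome
rand_segmentation <- function(id, maxpos = 10000,
                              states = fbsmeth::roadmap_states) {
  cuts <- sort(sample.int(maxpos - 1, sample(5:25, 1)))
  bounds <- unique(c(0, cuts, maxpos))
  segmentation(data.frame(
    chrom = "cA", start = bounds[-length(bounds)], end = bounds[-1],
    state = sample(states, length(bounds) - 1, replace = TRUE),
    stringsAsFactors = FALSE), id)
}

rand_track <- function(n, maxpos = 10000, chroms = c("cA", "cB")) {
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(maxpos, n, replace = TRUE) - 1,
             value = round(stats::rnorm(n), 3), stringsAsFactors = FALSE)
}

# fast small simulation config reused by several test files
small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, chrom_lengths = c(chrS1 = 5e5),
                   n_celltypes = 10L, n_cancer_celltypes = 3L,
                   n_fbs_regions = 10L, n_decoy_regions = 10L,
                   fbs_length_range = c(2000, 8000), region_spacing = 10000,
                   n_genes = 80L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

write_lines <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
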