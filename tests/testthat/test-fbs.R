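seg_from <- function(id, chrom, start, end, state) {
  segmentation(data.frame(chrom = chrom, start = start, end = end,
                          state = state, stringsAsFactors = FALSE), id)
}

test_that("count_distinct_merge pools, merges, and counts contributors", {
  a <- seg_from("A", "c", c(0, 20), c(10, 30), c("TssBiv", "TssBiv"))
  b <- seg_from("B", "c", 5, 15, "EnhBiv")
  c_ <- seg_from("C", "c", 8, 12, "TssBiv")
  m <- count_distinct_merge(list(a, b, c_))
  expect_equal(m$start, c(0, 20))
  expect_equal(m$end, c(15, 30))
  expect_equal(m$support, c(3L, 1L))
  expect_equal(m$contributors[[1]], c("A", "B", "C"))
  expect_equal(m$contributors[[2]], "A")

  one <- count_distinct_merge(list(a))
  expect_equal(one$support, c(1L, 1L))
  trip <- count_distinct_merge(list(a, seg_from("B2", "c", c(0, 20), c(10, 30),
                                                c("TssBiv", "EnhBiv")),
                                    seg_from("C2", "c", c(0, 20), c(10, 30),
                                             c("EnhBiv", "TssBiv"))))
  expect_equal(trip$support, c(3L, 3L))
  expect_error(count_distinct_merge(list(a), states = character(0)), "empty")
})

test_that("non-bivalent states do not enter the bivalent merge", {
  a <- seg_from("A", "c", c(0, 100), c(50, 200), c("TssA", "TssBiv"))
  m <- count_distinct_merge(list(a))
  expect_equal(m$start, 100)
  # BivFlnk excluded from the FBS state pair by default
  b <- seg_from("B", "c", 0, 50, "BivFlnk")
  m2 <- count_distinct_merge(list(a, b))
  expect_equal(m2$start, 100)
})

test_that("build_fbs applies strict-fraction and absolute thresholds", {
  m <- data.frame(chrom = "c", start = c(0, 100), end = c(50, 150),
                  support = c(4L, 5L))
  m$contributors <- list(letters[1:4], letters[1:5])
  attr(m, "n_inputs") <- 5
  f <- build_fbs(m, rule = support_rule(fraction = 0.8))
  expect_equal(f$support, 5L)  # 4 = 0.8*5 is not "more than 80%"
  # at consortium scale: fraction 0.8 of 122 means support >= 98
  expect_true(fbsmeth:::.rule_passes(support_rule(fraction = 0.8), 98, 122))
  expect_false(fbsmeth:::.rule_passes(support_rule(fraction = 0.8), 97, 122))
  all_kept <- build_fbs(m, rule = support_rule(min_support = 1))
  expect_equal(nrow(all_kept), 2)
  expect_error(build_fbs(m, rule = support_rule(min_support = 6)), "exceeds")
  expect_error(support_rule(fraction = 1.2), "in \\(0, 1\\)")
})

test_that("raising the support threshold never adds segments", {
  set.seed(11)
  segs <- lapply(1:8, function(i) rand_segmentation(paste0("D", i)))
  m <- count_distinct_merge(segs)
  prev <- build_fbs(m, rule = support_rule(min_support = 1))
  for (k in 2:8) {
    cur <- build_fbs(m, rule = support_rule(min_support = k))
    expect_true(all(cur$start %in% prev$start))
    expect_lte(nrow(cur), nrow(prev))
    prev <- cur
  }
})

test_that("count_distinct_merge agrees with the per-base contributor oracle", {
  set.seed(23)
  for (rep in 1:50) {
    n_ds <- sample(2:5, 1)
    pooled <- NULL
    segs <- list()
    for (i in seq_len(n_ds)) {
      x <- rand_intervals(sample(1:6, 1), chroms = "cA", maxpos = 5000)
      x <- merge_intervals(x)  # per-dataset partition invariant
      segs[[i]] <- segmentation(cbind(x, state = "TssBiv"), paste0("D", i))
      pooled <- rbind(pooled, cbind(x, dataset = paste0("D", i)))
    }
    m <- count_distinct_merge(segs)
    o <- or_distinct_merge(pooled, maxpos = 5000)
    expect_equal(m$start, as.integer(o$start))
    expect_equal(m$end, as.integer(o$end))
    expect_equal(m$support, o$support)
  }
})

test_that("conditional sets keep group-A segments failing the group-B rule", {
  ma <- data.frame(chrom = "c", start = 0, end = 100, support = 4L)
  attr(ma, "n_inputs") <- 8
  mb <- data.frame(chrom = "c", start = 50, end = 150, support = 3L)
  attr(mb, "n_inputs") <- 20
  kept <- build_conditional_set(ma, support_rule(min_support = 3),
                                mb, support_rule(min_support = 12))
  expect_equal(nrow(kept), 1)
  mb$support <- 12L
  dropped <- build_conditional_set(ma, support_rule(min_support = 3),
                                   mb, support_rule(min_support = 12))
  expect_equal(nrow(dropped), 0)
  # absent from group B counts as support 0 -> kept under an upper bound
  mb_far <- data.frame(chrom = "c", start = 5000, end = 5100, support = 20L)
  attr(mb_far, "n_inputs") <- 20
  kept2 <- build_conditional_set(ma, support_rule(min_support = 3),
                                 mb_far, support_rule(min_support = 12))
  expect_equal(nrow(kept2), 1)
})

test_that("background promoters are merged TssA minus FBS overlaps", {
  a <- seg_from("A", "c", c(0, 100, 5000), c(50, 150, 5100),
                c("TssA", "TssA", "TssA"))
  b <- seg_from("B", "c", 150, 220, "TssA")
  fbs <- data.frame(chrom = "c", start = 10, end = 20)
  bg <- build_background_promoters(list(a, b), fbs)
  # [0,50) overlaps the FBS and is dropped whole; [100,150)+[150,220) merge
  expect_equal(bg$start, c(100, 5000))
  expect_equal(bg$end, c(220, 5100))
})

test_that("associate_genes applies stranded promoter windows", {
  segs <- data.frame(chrom = "c", start = c(3600, 8900, 0),
                     end = c(3700, 9100, 100))
  genes <- data.frame(gene_id = c("Gplus", "Gminus"), chrom = "c",
                      start = c(5000, 5000), end = c(8000, 8000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  assoc <- associate_genes(segs, genes, promoter_window = 1500)
  # + strand window [3500, 8000) catches segment 1; - strand window
  # [5000, 9500) catches segment 2; neither touches [0, 100)
  expect_equal(assoc$segment[assoc$gene_id == "Gplus"], 1L)
  expect_equal(assoc$segment[assoc$gene_id == "Gminus"], 2L)
  expect_false(3L %in% assoc$segment)
  # window clipped at position 0
  near0 <- data.frame(gene_id = "G0", chrom = "c", start = 100, end = 200,
                      strand = "+", stringsAsFactors = FALSE)
  a0 <- associate_genes(data.frame(chrom = "c", start = 0, end = 50),
                        near0, 1500)
  expect_equal(nrow(a0), 1)
})

test_that("associate_genes equals brute-force all-pairs overlap testing", {
  set.seed(31)
  for (rep in 1:20) {
    segs <- rand_intervals(sample(1:10, 1), maxpos = 8000)
    ng <- sample(1:10, 1)
    st <- sample.int(7000, ng) - 1
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(ng)),
                        chrom = sample(c("cA", "cB"), ng, replace = TRUE),
                        start = st, end = st + sample.int(800, ng),
                        strand = sample(c("+", "-"), ng, replace = TRUE),
                        stringsAsFactors = FALSE)
    w <- 300
    assoc <- associate_genes(segs, genes, w)
    expected <- NULL
    for (i in seq_len(ng)) for (j in seq_len(nrow(segs))) {
      ws <- if (genes$strand[i] == "+") max(0, genes$start[i] - w) else genes$start[i]
      we <- if (genes$strand[i] == "+") genes$end[i] else genes$end[i] + w
      if (genes$chrom[i] == segs$chrom[j] && ws < segs$end[j] &&
          segs$start[j] < we) {
        expected <- rbind(expected, data.frame(gene_id = genes$gene_id[i],
                                               segment = j))
      }
    }
    got <- assoc[order(assoc$gene_id, assoc$segment), ]
    if (is.null(expected)) {
      expect_equal(nrow(assoc), 0)
    } else {
      expected <- expected[order(expected$gene_id, expected$segment), ]
      expect_equal(got$gene_id, expected$gene_id)
      expect_equal(got$segment, expected$segment)
    }
  }
})

test_that("fbs_coverage_stats counts segment-level overlaps", {
  fbs <- data.frame(chrom = "c", start = c(0, 1000), end = c(100, 1100))
  seg_id <- seg_from("S", "c", c(0, 1000), c(100, 1100),
                     c("TssBiv", "EnhBiv"))
  ident <- fbs_coverage_stats(fbs, seg_id)
  expect_equal(ident$fraction_of_fbs_bivalent, 1.0)
  expect_equal(ident$fraction_of_bivalent_in_fbs, 1.0)

  seg_half <- seg_from("S", "c", 10, 20, "TssBiv")
  half <- fbs_coverage_stats(fbs, seg_half)
  expect_equal(half$fraction_of_fbs_bivalent, 0.5)
  expect_equal(half$fraction_of_bivalent_in_fbs, 1.0)

  seg_off <- seg_from("S", "c", 5000, 5100, "TssBiv")
  off <- fbs_coverage_stats(fbs, seg_off)
  expect_equal(off$fraction_of_fbs_bivalent, 0.0)
  expect_equal(off$fraction_of_bivalent_in_fbs, 0.0)

  seg_none <- seg_from("S", "c", 0, 100, "Quies")
  none <- fbs_coverage_stats(fbs, seg_none)
  expect_true(is.na(none$fraction_of_bivalent_in_fbs))
})
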