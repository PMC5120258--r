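test_that("packaged classifier regions match the published 14-segment table", {
  reg <- load_classifier_regions("fbs14")
  expect_equal(nrow(reg), 14)
  expect_equal(reg$chrom[1], "chr10")
  expect_equal(reg$start[1], 102979800)
  expect_equal(reg$end[1], 102995000)
  hoxb <- reg[reg$chrom == "chr17" & grepl("HOXB", reg$genes), ]
  expect_equal(hoxb$start[1], 46616400)
  expect_equal(hoxb$end[1], 46706600)
  expect_true(all(reg$support >= 120))
  expect_error(load_classifier_regions("promoter9"), "not packaged")
  expect_error(load_classifier_regions("enhancer12"), "not packaged")
})

test_that("sample_score is the region-mean to array-mean ratio with filters", {
  sites <- data.frame(site_id = sprintf("cg%02d", 1:12), chrom = "c",
                      pos = c(0, 10, 20, 100, 110, 120, 200, 210, 220,
                              500, 510, 520))
  regions <- data.frame(chrom = "c", start = c(0, 100, 200),
                        end = c(50, 150, 250))
  # flat 0.5 everywhere: ratio identity
  s <- sample_score(rep(0.5, 12), sites, regions)
  expect_equal(s$score, 1.0)
  expect_equal(s$n_segments_used, 3L)

  # region means {0.3, 0.3, 0.3}; background sites at 0.9 give an
  # array-wide mean of 0.45 -> score 0.3 / 0.45 = 2/3
  v <- c(rep(0.3, 9), rep(0.9, 3))
  expect_equal(sample_score(v, sites, regions)$score, 0.3 / 0.45)

  # only 2 regions with >= 3 covered CpGs -> discarded
  v4 <- rep(0.5, 12); v4[7:9] <- NA
  s4 <- sample_score(v4, sites, regions)
  expect_true(s4$discarded)
  expect_equal(s4$n_segments_used, 2L)
  # no covered sites at all
  s5 <- sample_score(rep(NA_real_, 12), sites, regions)
  expect_true(s5$discarded)
})

test_that("the score is invariant to rescaling a sample's betas", {
  set.seed(3)
  sites <- data.frame(site_id = sprintf("cg%03d", 1:60), chrom = "c",
                      pos = sort(sample.int(5000, 60)) - 1)
  regions <- data.frame(chrom = "c", start = c(0, 2000), end = c(1000, 3000))
  v <- runif(60, 0.2, 0.9)
  base <- sample_score(v, sites, regions, min_segments = 2)
  for (cc in c(0.1, 0.5, 0.9)) {
    expect_equal(sample_score(v * cc, sites, regions, min_segments = 2)$score,
                 base$score, tolerance = 1e-12)
  }
})

test_that("roc_auc reproduces hand counts and the pairwise oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.6, 0.7, 0.5),
               c("cancer", "cancer", "cancer", "normal", "normal"))
  expect_equal(r$auc, 5 / 6)
  expect_equal(roc_auc(c(2, 3, 0, 1),
                       c("cancer", "cancer", "normal", "normal"))$auc, 1.0)
  expect_equal(roc_auc(rep(1, 6), rep(c("cancer", "normal"), 3))$auc, 0.5)

  set.seed(29)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    score <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    label <- sample(c("cancer", "normal"), n, replace = TRUE)
    if (length(unique(label)) < 2) label[1:2] <- c("cancer", "normal")
    r <- roc_auc(score, label)
    expect_equal(r$auc, or_auc(score, label))
    # ROC points are monotone and bracket the unit square
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  score <- c(rnorm(30, 1.2, 0.4), rnorm(25, 0.9, 0.4))
  label <- rep(c("cancer", "normal"), c(30, 25))
  ours <- roc_auc(score, label)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = label, predictor = score, levels = c("normal", "cancer"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("subset_search enumerates all non-empty subsets with waived filters", {
  set.seed(53)
  n_sites <- 120
  sites <- data.frame(site_id = sprintf("cg%03d", 1:n_sites), chrom = "c",
                      pos = sort(sample.int(20000, n_sites)) - 1)
  regions <- data.frame(chrom = "c", start = seq(0, by = 4000, length.out = 5),
                        end = seq(0, by = 4000, length.out = 5) + 2000)
  # plant signal only in region 2
  in_r2 <- sites$pos >= regions$start[2] & sites$pos < regions$end[2]
  mk <- function(shift) {
    pmin(1, pmax(0, 0.3 + ifelse(in_r2, shift, 0) + rnorm(n_sites, 0, 0.02)))
  }
  vals <- cbind(sapply(1:12, function(i) mk(0.4)),
                sapply(1:12, function(i) mk(0)))
  colnames(vals) <- c(sprintf("T%02d", 1:12), sprintf("N%02d", 1:12))
  bm <- beta_matrix(sites, vals,
                    setNames(rep(c("tumor", "control"), each = 12),
                             colnames(vals)))
  res <- subset_search(bm, regions)
  expect_equal(nrow(res), 2^5 - 1)
  expect_true(all(res$filter_waived == (res$size < 3)))
  # best singleton is the planted region
  singles <- res[res$size == 1, ]
  expect_equal(singles$subset[which.max(singles$auc)], "2")
  # the full subset reproduces score_samples + roc_auc exactly
  sc <- score_samples(bm, regions)
  full_auc <- roc_auc(sc$score, ifelse(sc$label == "tumor", "cancer", "normal"))$auc
  expect_equal(res$auc[res$subset == "1,2,3,4,5"], full_auc)
  expect_error(subset_search(bm, regions[rep(1, 21), ]), "> 20")
})

test_that("subset counts scale as 2^n - 1", {
  sites <- data.frame(site_id = sprintf("cg%02d", 1:9), chrom = "c",
                      pos = c(0, 5, 9, 100, 105, 109, 200, 205, 209))
  regions <- data.frame(chrom = "c", start = c(0, 100, 200),
                        end = c(50, 150, 250))
  v <- matrix(runif(18, 0.1, 0.9), 9,
              dimnames = list(NULL, c("T1", "N1")))
  bm <- beta_matrix(sites, v, setNames(c("tumor", "control"), c("T1", "N1")))
  expect_equal(nrow(subset_search(bm, regions)), 7)
  expect_equal(nrow(subset_search(bm, regions[1, , drop = FALSE])), 1)
})

test_that("purity_crossing solves the noiseless line exactly", {
  purity <- seq(0.05, 1, by = 0.05)
  score <- 1 + purity          # noiseless: sigma = 0, band has zero width
  ctl <- rep(1.5, 50)          # threshold = 1.5
  pc <- purity_crossing(score, purity, ctl)
  expect_equal(pc$fn_threshold, 1.5)
  expect_equal(pc$crossing_purity, 0.5, tolerance = 1e-6)
  expect_equal(pc$slope, 1, tolerance = 1e-9)

  # negative slope with the threshold above the intercept: no crossing
  pc2 <- purity_crossing(2 - 0.5 * purity, purity, rep(2.5, 50))
  expect_true(is.na(pc2$crossing_purity))
  expect_error(purity_crossing(score, rep(0.5, 20), ctl), "degenerate")
  expect_error(purity_crossing(score[1:2], purity[1:2], ctl), "at least 3")
})

test_that("ordinal stage mapping collapses sub-stages and discards the rest", {
  expect_equal(map_ordinal_stage(c("Stage I", "Stage Ia", "Stage IIB",
                                   "Stage IV", "G2", "G4", "Stage X", "GX")),
               c(1L, 1L, 2L, 4L, 2L, 4L, NA, NA))
  inc <- ordinal_correlation(c(1, 1, 2, 2, 3, 3), 1,
                             c("Stage I", "Stage Ia", "Stage II",
                               "Stage IIb", "Stage III", "Stage IIIc"))
  expect_equal(inc$estimate, 1)

  # toy: stages {1,1,2,2,3,3}, values {1,2,2,3,3,4}: spearman by hand
  v <- c(1, 2, 2, 3, 3, 4); s <- c(1, 1, 2, 2, 3, 3)
  out <- ordinal_correlation(v, 1, s)
  expect_equal(out$estimate, cor(rank(v), rank(s)), tolerance = 1e-12)
  expect_gt(out$estimate, 0)

  const <- ordinal_correlation(1:5, 1, rep("Stage II", 5))
  expect_true(is.na(const$estimate))
  expect_equal(const$reason, "constant ordinal vector")
  # permuted values: near-zero correlation on average
  set.seed(61)
  est <- replicate(50, ordinal_correlation(sample(1:40), 1,
                                           rep(1:4, 10))$estimate)
  expect_lt(abs(mean(est)), 0.1)
})

test_that("score divides by purity before correlating", {
  score <- c(2, 2, 2, 2)
  purity <- c(1, 0.5, 0.25, 0.2)
  out <- ordinal_correlation(score, purity, c(1L, 2L, 3L, 4L))
  expect_equal(out$estimate, 1)  # score/purity increases with stage
})
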