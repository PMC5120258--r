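#' Load classifier region sets
#'
#' The `fbs14` variant returns the 14 frequently bivalent segments supported
#' by at least 120 of the 122 normal segmentations, shipped as a packaged
#' fixture with their contributor counts, associated gene names, and
#' single-region AUCs.  The bivalent-promoter (`promoter9`) and
#' bivalent-enhancer (`enhancer12`) variants have no published coordinates
#' and can only be reconstructed from segmentation inputs; requesting them
#' raises an explicit error.
#'
#' @param variant One of `"fbs14"`, `"promoter9"`, `"enhancer12"`.
#' @return data.frame `chrom`, `start`, `end`, `support`, `genes` (comma
#'   separated), `auc_single`.
#' @export
load_classifier_regions <- function(variant = c("fbs14", "promoter9", "enhancer12")) {
  variant <- match.arg(variant)
  if (variant != "fbs14") {
    stop("variant '", variant, "' is not packaged: its coordinates are not ",
         "published and must be rebuilt from segmentation inputs with ",
         "count_distinct_merge()/build_fbs()")
  }
  path <- system.file("extdata", "fbs14_classifier_regions.tsv",
                      package = "fbsmeth", mustWork = TRUE)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  x$chrom <- as.character(x$chrom)
  x
}

# per-sample per-region mean betas and covered-CpG counts.
# Returns list(region_means = samples x regions, n_cpgs = samples x regions,
#              array_mean = per-sample mean over all covered sites)
.region_stats <- function(values, sites, regions) {
  idx <- .site_segment(sites, regions)
  nreg <- nrow(regions)
  nsamp <- ncol(values)
  rm_ <- matrix(NA_real_, nsamp, nreg)
  nc <- matrix(0L, nsamp, nreg)
  obs <- !is.na(values)
  v0 <- ifelse(obs, values, 0)
  insites <- which(!is.na(idx))
  if (length(insites)) {
    g <- idx[insites]
    sums <- rowsum(v0[insites, , drop = FALSE], g)        # regions' x samples
    cnts <- rowsum(obs[insites, , drop = FALSE] * 1L, g)
    j <- as.integer(rownames(sums))
    rm_[, j] <- t(ifelse(cnts > 0, sums / cnts, NA_real_))
    nc[, j] <- t(cnts)
  }
  array_mean <- colSums(v0) / colSums(obs)
  list(region_means = rm_, n_cpgs = nc, array_mean = array_mean)
}

#' Relative descriptor methylation score for one sample
#'
#' The training-free cancer score: the mean over classifier regions of the
#' region-mean beta values, divided by the sample's mean beta over *all*
#' covered CpGs on the array.  Regions covering fewer than `min_cpgs` CpGs
#' are dropped; samples with fewer than `min_segments` surviving regions (or
#' a zero denominator) are flagged discarded.  The score is scale-invariant:
#' multiplying every beta of a sample by a constant leaves it unchanged.
#'
#' @param beta_values Numeric vector of beta values for one sample
#'   (NA = not covered), aligned with `sites`.
#' @param sites Site annotation data.frame (`chrom`, `pos`).
#' @param regions Classifier region intervals.
#' @param min_cpgs Minimum covered CpGs per region (default 3).
#' @param min_segments Minimum surviving regions per sample (default 3).
#' @return List with `score` (NA when discarded), `n_segments_used`,
#'   `discarded`, `reason`.
#' @export
sample_score <- function(beta_values, sites, regions, min_cpgs = 3,
                         min_segments = 3) {
  v <- matrix(beta_values, ncol = 1, dimnames = list(NULL, "s"))
  st <- .region_stats(v, sites, regions)
  valid <- st$n_cpgs[1, ] >= min_cpgs
  n_used <- sum(valid)
  den <- unname(st$array_mean[1])
  if (!is.finite(den)) {
    return(list(score = NA_real_, n_segments_used = 0L, discarded = TRUE,
                reason = "no covered sites"))
  }
  if (n_used < min_segments) {
    return(list(score = NA_real_, n_segments_used = as.integer(n_used),
                discarded = TRUE,
                reason = sprintf("only %d regions with >= %d covered CpGs",
                                 n_used, min_cpgs)))
  }
  if (den == 0) {
    return(list(score = NA_real_, n_segments_used = as.integer(n_used),
                discarded = TRUE, reason = "zero array-wide mean"))
  }
  num <- mean(st$region_means[1, valid])
  list(score = num / den, n_segments_used = as.integer(n_used),
       discarded = FALSE, reason = NA_character_)
}

#' Score every sample of a beta matrix
#'
#' Vectorized application of [sample_score()] over the columns of a
#' [beta_matrix()].
#'
#' @param bm A [beta_matrix()].
#' @param regions Classifier region intervals.
#' @param min_cpgs,min_segments Filters as in [sample_score()].
#' @return data.frame `sample_id`, `label` (the group), `score`,
#'   `n_segments_used`, `discarded`.
#' @export
score_samples <- function(bm, regions, min_cpgs = 3, min_segments = 3) {
  stopifnot(inherits(bm, "beta_matrix"))
  st <- .region_stats(bm$values, bm$sites, regions)
  valid <- st$n_cpgs >= min_cpgs
  n_used <- rowSums(valid)
  num <- rowSums(ifelse(valid, st$region_means, 0)) / n_used
  score <- unname(num / st$array_mean)
  discarded <- n_used < min_segments | !is.finite(st$array_mean) |
    st$array_mean == 0
  score[discarded] <- NA_real_
  data.frame(sample_id = colnames(bm$values), label = unname(bm$groups),
             score = score, n_segments_used = as.integer(n_used),
             discarded = discarded, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' ROC curve and AUC
#'
#' Cancer is the positive class; higher scores predict cancer.  The AUC is
#' the Mann-Whitney probability that a random cancer sample outscores a
#' random normal one, with ties half-credited, computed from ranks.  ROC
#' points are generated from descending score thresholds.
#'
#' @param score Numeric score vector (NAs/discarded samples dropped).
#' @param label Character vector, `"cancer"` or `"normal"`.
#' @return List with `auc` and `points` (data.frame `fpr`, `tpr`, monotone
#'   non-decreasing, starting at (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(score, label) {
  keep <- !is.na(score)
  score <- score[keep]; label <- label[keep]
  stopifnot(all(label %in% c("cancer", "normal")))
  pos <- label == "cancer"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both cancer and normal scores")
  r <- rank(score)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(s[length(s):1])[length(s):1]  # last index of each tied block
  points <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(auc = auc, points = points)
}

#' Exhaustive classifier-subset search
#'
#' Enumerates every non-empty subset of the classifier regions (2^n - 1;
#' refused for n > 20), rescores all samples per subset with the same
#' region/sample filters, and returns the AUC per subset, best first.  For
#' subsets of fewer than `min_segments` regions the per-sample filter is
#' waived down to the subset size (otherwise no sample could survive);
#' such rows are flagged.
#'
#' @param bm A [beta_matrix()].
#' @param regions Classifier region intervals (`<= 20` rows).
#' @param min_cpgs Minimum covered CpGs per region.
#' @param min_segments Nominal minimum surviving regions per sample.
#' @return data.frame `subset` (comma-separated region row indices), `size`,
#'   `auc`, `n_samples`, `filter_waived`, sorted by decreasing AUC.
#' @export
subset_search <- function(bm, regions, min_cpgs = 3, min_segments = 3) {
  n <- nrow(regions)
  if (n > 20) stop("refusing exhaustive search over ", n, " regions (> 20)")
  st <- .region_stats(bm$values, bm$sites, regions)
  valid <- st$n_cpgs >= min_cpgs
  means0 <- ifelse(valid, st$region_means, 0)
  den <- st$array_mean
  lab <- unname(bm$groups)
  lab <- ifelse(lab == "tumor", "cancer", "normal")
  n_subsets <- 2^n - 1
  subset_id <- character(n_subsets)
  size <- integer(n_subsets)
  aucs <- rep(NA_real_, n_subsets)
  n_samp <- integer(n_subsets)
  bits <- bitwShiftL(1L, 0:(n - 1))
  den_ok <- is.finite(den) & den > 0
  pos <- lab == "cancer"
  for (m in seq_len(n_subsets)) {
    subset <- which(bitwAnd(m, bits) != 0)
    s <- length(subset)
    ms <- min(min_segments, s)
    nvalid <- rowSums(valid[, subset, drop = FALSE])
    keep <- nvalid >= ms & den_ok
    subset_id[m] <- paste(subset, collapse = ",")
    size[m] <- s
    n_samp[m] <- sum(keep)
    n1 <- sum(pos & keep); n0 <- sum(!pos & keep)
    if (n1 > 0 && n0 > 0) {
      score <- (rowSums(means0[, subset, drop = FALSE])[keep] /
                  nvalid[keep]) / den[keep]
      r <- rank(score)
      aucs[m] <- (sum(r[pos[keep]]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  out <- data.frame(subset = subset_id, size = size, auc = aucs,
                    n_samples = n_samp, filter_waived = size < min_segments,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor-purity crossing of the score prediction band
#'
#' Fits an ordinary least-squares line of score on tumor purity and finds
#' the smallest purity in (0, 1] at which the lower bound of the `band`
#' prediction interval reaches the false-negative threshold.  The threshold
#' is anchored on the control score distribution as its `1 - fn_rate`
#' quantile (the cutoff at 5% false positives on controls, i.e. ~95% target
#' specificity).
#'
#' @param score Tumor sample scores.
#' @param purity Tumor cell content in [0, 1], same length (>= 3 pairs,
#'   non-constant).
#' @param control_scores Scores of control samples defining the threshold.
#' @param fn_rate Tolerated false-negative rate (default 0.05).
#' @param band Prediction-interval coverage (default 0.90).
#' @return List with `intercept`, `slope`, `sigma`, `fn_threshold`,
#'   `crossing_purity` (NA when the band never reaches the threshold in
#'   (0, 1]), `band`, `fn_rate`, and the fitted `model`.
#' @export
purity_crossing <- function(score, purity, control_scores, fn_rate = 0.05,
                            band = 0.90) {
  keep <- !is.na(score) & !is.na(purity)
  score <- score[keep]; purity <- purity[keep]
  if (length(score) < 3) stop("need at least 3 (score, purity) pairs")
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0, 1]")
  if (stats::var(purity) == 0) stop("degenerate purity spread: all equal")
  threshold <- stats::quantile(control_scores, 1 - fn_rate, names = FALSE,
                               na.rm = TRUE)
  df <- data.frame(purity = purity, score = score)
  fit <- stats::lm(score ~ purity, data = df)
  grid <- data.frame(purity = seq(1e-6, 1, length.out = 2001))
  lwr <- suppressWarnings(
    stats::predict(fit, grid, interval = "prediction", level = band)[, "lwr"])
  hit <- which(lwr >= threshold)
  crossing <- NA_real_
  if (length(hit)) {
    i <- hit[1]
    if (i == 1) {
      crossing <- grid$purity[1]
    } else {
      f <- function(p) suppressWarnings(
        stats::predict(fit, data.frame(purity = p),
                       interval = "prediction", level = band)[, "lwr"]) - threshold
      crossing <- stats::uniroot(f, c(grid$purity[i - 1], grid$purity[i]),
                                 tol = 1e-8)$root
    }
  }
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       sigma = stats::sigma(fit), fn_threshold = threshold,
       crossing_purity = crossing, band = band, fn_rate = fn_rate,
       model = fit)
}

#' Map tumor stage / grade labels to ordinal numbers
#'
#' Stage I/G1 -> 1 ... Stage IV/G4 -> 4; sub-stages (Stage Ia, Stage IIIc,
#' ...) collapse to their main stage.  Anything else maps to NA and is
#' discarded downstream.
#'
#' @param labels Character vector of pathologic stage or histologic grade
#'   labels.
#' @return Integer vector (NA for unmapped levels).
#' @export
map_ordinal_stage <- function(labels) {
  x <- trimws(toupper(as.character(labels)))
  x <- sub("^STAGE\\s+", "", x)
  x <- sub("[ABC]$", "", x)
  roman <- c(I = 1L, II = 2L, III = 3L, IV = 4L,
             G1 = 1L, G2 = 2L, G3 = 3L, G4 = 4L,
             `1` = 1L, `2` = 2L, `3` = 3L, `4` = 4L)
  out <- roman[x]
  unname(out)
}

#' Correlation of purity-normalized score with tumor stage or grade
#'
#' Correlates the relative descriptor methylation divided by tumor purity
#' with the ordinal stage/grade (rank-based by default, the natural choice
#' for ordinal levels; Pearson by flag).  Sub-stages are collapsed and
#' unmapped levels discarded before testing.
#'
#' @param score Tumor scores.
#' @param purity Tumor purities (same length); scores are divided by them.
#' @param stage Stage/grade labels (character) or pre-mapped integers.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `estimate`, `p_value`, `n`, `method`; `estimate` is NA
#'   (with `reason`) when fewer than 3 mapped pairs remain or the ordinal
#'   vector is constant.
#' @export
ordinal_correlation <- function(score, purity = 1, stage,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ord <- if (is.numeric(stage)) as.integer(stage) else map_ordinal_stage(stage)
  v <- score / purity
  keep <- !is.na(v) & !is.na(ord)
  v <- v[keep]; ord <- ord[keep]
  if (length(v) < 3) {
    return(list(estimate = NA_real_, p_value = NA_real_, n = length(v),
                method = method, reason = "fewer than 3 mapped pairs"))
  }
  if (length(unique(ord)) < 2) {
    return(list(estimate = NA_real_, p_value = NA_real_, n = length(v),
                method = method, reason = "constant ordinal vector"))
  }
  ct <- suppressWarnings(stats::cor.test(v, ord, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(v),
       method = method, reason = NA_character_)
}
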