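#' Configuration for the synthetic epigenome world
#'
#' Defaults emulate, at desk scale, the statistical structure the analyses
#' assume: many cell-type segmentations sharing planted frequently bivalent
#' regions next to less-shared decoys, low baseline methylation at bivalent
#' regions (mean beta 0.10) on a bimodal background, a configurable
#' hypermethylation effect (+0.07 mean beta) at a subset of planted regions
#' in tumors, mild global hypomethylation elsewhere (-0.05), purity mixing,
#' bivalency loss in cancer segmentations, and differential-expression
#' tables whose FBS genes carry a positive mean log2 fold-change shift
#' (+0.94) optionally coupled to each gene's methylation change.
#'
#' Support fractions are deterministic: a planted region is bivalent in
#' exactly `round(fraction * n_celltypes)` randomly chosen cell types, so a
#' planted set at fraction 0.9 is guaranteed to clear the 0.8 threshold and
#' decoys at 0.4 are guaranteed to fail it.
#'
#' @param seed Base RNG seed.
#' @param n_celltypes Number of normal cell-type segmentations.
#' @param n_cancer_celltypes Number of cancer segmentations.
#' @param chrom_lengths Named numeric vector of chromosome lengths (nt).
#' @param n_fbs_regions,fbs_length_range,fbs_support_fraction Planted
#'   frequently-bivalent regions: count, length range (nt), support
#'   fraction.
#' @param n_decoy_regions,decoy_support_fraction Decoy bivalent regions and
#'   their (low) support fraction.
#' @param region_spacing Minimum gap between planted regions (nt).
#' @param n_genes,gene_length_range,promoter_window Gene models.
#' @param cpg_rate_bivalent,cpg_rate_background CpG densities (sites/nt)
#'   inside planted/decoy regions and elsewhere.
#' @param n_tumor,n_normal Sample-group sizes for beta matrices.
#' @param mu_bivalent Control-group mean beta at bivalent regions.
#' @param background_high_mean,background_low_mean,background_high_prob
#'   Bimodal background beta mixture.
#' @param delta_hyper Tumor hypermethylation effect at affected regions
#'   (mean beta change).
#' @param affected_fraction Fraction of planted regions hypermethylated in
#'   tumors.
#' @param global_hypo_shift Tumor beta shift at background sites.
#' @param beta_concentration Concentration of the bounded (beta
#'   distribution) noise around site means.
#' @param bivalency_loss_prob Probability a planted region loses bivalency
#'   in a cancer segmentation.
#' @param cancer_new_bivalent_rate Per-filler-chunk probability of novel
#'   bivalency in cancer segmentations.
#' @param fbs_log2fc_shift,background_log2fc_shift,log2fc_sd True expression
#'   effect distribution for FBS and background genes.
#' @param de_replicates,de_replicate_sd Per-group replicate count and
#'   replicate SD used to generate DE p-values from a two-group test.
#' @param lowly_expressed_fraction Fraction of FBS genes with negative
#'   control logCPM.
#' @param rho Coupling in [0, 1] between a gene's methylation change and its
#'   log2 fold change (0 = independence).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_celltypes = 20L,
                       n_cancer_celltypes = 5L,
                       chrom_lengths = c(chrS1 = 2e6, chrS2 = 2e6),
                       n_fbs_regions = 25L,
                       fbs_length_range = c(3000, 15000),
                       fbs_support_fraction = 0.9,
                       n_decoy_regions = 25L,
                       decoy_support_fraction = 0.4,
                       region_spacing = 20000,
                       n_genes = 400L,
                       gene_length_range = c(2000, 30000),
                       promoter_window = 1500,
                       cpg_rate_bivalent = 1 / 150,
                       cpg_rate_background = 1 / 1500,
                       n_tumor = 50L,
                       n_normal = 50L,
                       mu_bivalent = 0.10,
                       background_high_mean = 0.85,
                       background_low_mean = 0.15,
                       background_high_prob = 0.70,
                       delta_hyper = 0.07,
                       affected_fraction = 0.8,
                       global_hypo_shift = -0.05,
                       beta_concentration = 80,
                       bivalency_loss_prob = 0.7,
                       cancer_new_bivalent_rate = 0.02,
                       fbs_log2fc_shift = 0.94,
                       background_log2fc_shift = 0,
                       log2fc_sd = 1.0,
                       de_replicates = 6L,
                       de_replicate_sd = 1.0,
                       lowly_expressed_fraction = 0.6,
                       rho = 0) {
  cfg <- as.list(environment())
  probs <- c(cfg$fbs_support_fraction, cfg$decoy_support_fraction,
             cfg$affected_fraction, cfg$bivalency_loss_prob,
             cfg$background_high_prob, cfg$lowly_expressed_fraction,
             cfg$cancer_new_bivalent_rate, cfg$rho)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$mu_bivalent + cfg$delta_hyper > 1) {
    stop("mu_bivalent + delta_hyper must be <= 1")
  }
  if (any(cfg$chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# frequency table of non-bivalent filler states (rough genome composition:
# quiescent-dominated, some weak transcription / repression)
.filler_states <- function() {
  c(Quies = 0.58, TxWk = 0.12, Tx = 0.05, ReprPCWk = 0.08, Het = 0.04,
    Enh = 0.04, TssA = 0.02, TssAFlnk = 0.015, TxFlnk = 0.005, EnhG = 0.005,
    `ZNF/Rpts` = 0.01, ReprPC = 0.035)
}

# lay out k non-overlapping regions of given lengths on [0, chrlen) with
# gaps >= spacing; returns data.frame(start, end)
.place_regions <- function(chrlen, lengths, spacing) {
  k <- length(lengths)
  if (k == 0) return(data.frame(start = integer(), end = integer()))
  free <- chrlen - sum(lengths) - (k + 1) * spacing
  if (free < 0) stop("infeasible packing: regions exceed chromosome length")
  cuts <- sort(stats::runif(k))
  gaps <- diff(c(0, cuts, 1)) * free + spacing
  starts <- integer(k)
  pos <- 0
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    starts[i] <- round(pos)
    pos <- pos + lengths[i]
  }
  data.frame(start = starts, end = starts + as.integer(lengths))
}

# split [start, end) into filler chunks with sampled states
.fill_gap <- function(chrom, start, end, mean_len = 5000, new_biv_rate = 0) {
  len <- end - start
  if (len <= 0) return(NULL)
  n <- max(1L, round(len / mean_len))
  cuts <- sort(sample.int(len - 1, min(n - 1, len - 1)))
  bounds <- c(start, start + cuts, end)
  states <- names(.filler_states())
  st <- sample(states, length(bounds) - 1, replace = TRUE,
               prob = .filler_states())
  if (new_biv_rate > 0) {
    flip <- stats::runif(length(st)) < new_biv_rate
    st[flip] <- sample(c("TssBiv", "EnhBiv"), sum(flip), replace = TRUE)
  }
  data.frame(chrom = chrom, start = bounds[-length(bounds)],
             end = bounds[-1], state = st, stringsAsFactors = FALSE)
}

# build one segmentation given regions (chrom/start/end/state) and a logical
# vector saying which regions are bivalent in this cell type
.build_segmentation <- function(id, regions, bivalent_here, chrom_lengths,
                                new_biv_rate = 0) {
  pieces <- list()
  for (chrom in names(chrom_lengths)) {
    r <- regions[regions$chrom == chrom, , drop = FALSE]
    bh <- bivalent_here[regions$chrom == chrom]
    r <- r[order(r$start), , drop = FALSE]
    bh <- bh[order(regions$start[regions$chrom == chrom])]
    pos <- 0
    for (i in seq_len(nrow(r))) {
      pieces[[length(pieces) + 1]] <-
        .fill_gap(chrom, pos, r$start[i], new_biv_rate = new_biv_rate)
      st <- if (bh[i]) r$state[i] else
        sample(names(.filler_states()), 1, prob = .filler_states())
      pieces[[length(pieces) + 1]] <-
        data.frame(chrom = chrom, start = r$start[i], end = r$end[i],
                   state = st, stringsAsFactors = FALSE)
      pos <- r$end[i]
    }
    pieces[[length(pieces) + 1]] <-
      .fill_gap(chrom, pos, chrom_lengths[[chrom]], new_biv_rate = new_biv_rate)
  }
  segmentation(do.call(rbind, pieces), id)
}

#' Simulate a synthetic epigenome world
#'
#' Generates, deterministically under the config seed: normal cell-type
#' segmentations in which each planted region is bivalent in exactly
#' `round(fbs_support_fraction * N)` cell types (decoys analogously at
#' their lower fraction) and the rest of the genome is filled with
#' non-bivalent states from a fixed frequency table; cancer segmentations
#' in which planted regions lose bivalency with probability
#' `bivalency_loss_prob` and novel bivalent chunks appear at a small rate;
#' gene models, one anchored on each planted region plus random background
#' genes; CpG sites dense in bivalent regions and sparse elsewhere; and a
#' truth record naming the planted regions, the hypermethylation-affected
#' subset, and the FBS-associated genes.
#'
#' @param config A [sim_config()].
#' @return List with `segmentations` (normal), `cancer_segmentations`,
#'   `genes`, `sites`, `truth`.  `truth` carries `regions` (with `type`,
#'   `support`, `affected`), `fbs_genes`, `gene_ids`, and the config.
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl <- config$chrom_lengths
  ntot <- config$n_fbs_regions + config$n_decoy_regions
  # distribute regions over chromosomes proportionally to length
  chrom_of <- sample(names(cl), ntot, replace = TRUE, prob = cl / sum(cl))
  lens <- round(stats::runif(ntot, config$fbs_length_range[1],
                             config$fbs_length_range[2]))
  regions <- do.call(rbind, lapply(names(cl), function(chrom) {
    ix <- which(chrom_of == chrom)
    if (!length(ix)) return(NULL)
    placed <- .place_regions(cl[[chrom]], lens[ix], config$region_spacing)
    data.frame(chrom = chrom, start = placed$start, end = placed$end,
               orig = ix, stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$orig), , drop = FALSE]
  regions$orig <- NULL
  rownames(regions) <- NULL
  type <- sample(rep(c("fbs", "decoy"),
                     c(config$n_fbs_regions, config$n_decoy_regions)))
  regions$region_id <- sprintf("R%03d", seq_len(ntot))
  regions$type <- type
  regions$state <- sample(c("TssBiv", "EnhBiv"), ntot, replace = TRUE)

  N <- config$n_celltypes
  n_sup <- ifelse(regions$type == "fbs",
                  round(config$fbs_support_fraction * N),
                  round(config$decoy_support_fraction * N))
  supporters <- lapply(n_sup, function(k) sort(sample.int(N, k)))
  regions$support <- n_sup

  ids <- sprintf("CT%02d", seq_len(N))
  segmentations <- lapply(seq_len(N), function(j) {
    biv_here <- vapply(supporters, function(s) j %in% s, FALSE)
    .build_segmentation(ids[j], regions, biv_here, cl)
  })

  # cancer segmentations: planted bivalency kept with prob 1 - q
  cids <- sprintf("CA%02d", seq_len(config$n_cancer_celltypes))
  cancer_segmentations <- lapply(seq_len(config$n_cancer_celltypes), function(j) {
    keep <- stats::runif(nrow(regions)) >= config$bivalency_loss_prob
    # only regions bivalent in the majority of normals are "normally bivalent"
    keep <- keep & regions$type == "fbs"
    .build_segmentation(cids[j], regions, keep, cl,
                        new_biv_rate = config$cancer_new_bivalent_rate)
  })

  # genes: one anchored on each fbs region, the rest placed at random
  fbs_rows <- which(regions$type == "fbs")
  glens <- round(stats::runif(config$n_genes, config$gene_length_range[1],
                              config$gene_length_range[2]))
  gchrom <- sample(names(cl), config$n_genes, replace = TRUE,
                   prob = cl / sum(cl))
  gstart <- integer(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    if (i <= length(fbs_rows)) {
      r <- regions[fbs_rows[i], ]
      gchrom[i] <- r$chrom
      # gene body overlaps the region
      gstart[i] <- max(0, r$start - round(glens[i] / 2))
    } else {
      gstart[i] <- floor(stats::runif(1, 0, cl[[gchrom[i]]] - glens[i]))
    }
  }
  genes <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
    chrom = gchrom, start = gstart, end = gstart + glens,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # CpG sites: dense inside planted/decoy regions, sparse background
  site_list <- list()
  for (i in seq_len(nrow(regions))) {
    L <- regions$end[i] - regions$start[i]
    k <- stats::rpois(1, L * config$cpg_rate_bivalent)
    if (k == 0) next
    pos <- regions$start[i] + sort(sample.int(L, min(k, L))) - 1L
    site_list[[length(site_list) + 1]] <-
      data.frame(chrom = regions$chrom[i], pos = pos,
                 class = regions$type[i], region_id = regions$region_id[i],
                 stringsAsFactors = FALSE)
  }
  for (chrom in names(cl)) {
    k <- stats::rpois(1, cl[[chrom]] * config$cpg_rate_background)
    pos <- sort(sample.int(cl[[chrom]], k)) - 1L
    r <- regions[regions$chrom == chrom, , drop = FALSE]
    inreg <- rep(FALSE, k)
    for (i in seq_len(nrow(r))) {
      inreg <- inreg | (pos >= r$start[i] & pos < r$end[i])
    }
    if (any(!inreg)) {
      site_list[[length(site_list) + 1]] <-
        data.frame(chrom = chrom, pos = pos[!inreg], class = "background",
                   region_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_list)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), , drop = FALSE]
  sites$site_id <- sprintf("cg%06d", seq_len(nrow(sites)))
  sites <- sites[, c("site_id", "chrom", "pos", "class", "region_id")]
  rownames(sites) <- NULL

  affected <- regions$type == "fbs" &
    seq_len(nrow(regions)) %in%
      sample(fbs_rows, round(config$affected_fraction * length(fbs_rows)))
  regions$affected <- affected

  assoc <- associate_genes(regions[fbs_rows, , drop = FALSE], genes,
                           config$promoter_window)
  truth <- list(regions = regions,
                fbs_genes = sort(unique(assoc$gene_id)),
                gene_ids = genes$gene_id,
                affected_region_ids = regions$region_id[affected],
                config = config)
  list(segmentations = segmentations,
       cancer_segmentations = cancer_segmentations,
       genes = genes, sites = sites, truth = truth)
}

#' Simulate tumor/control beta values with purity mixing
#'
#' Control betas are drawn from beta distributions around class baselines
#' (bivalent regions low, background bimodal); pure-tumor means shift by
#' `delta_hyper` at affected regions and by `global_hypo_shift` at
#' background sites.  An observed tumor sample with purity p is the mixture
#' `p * tumor_draw + (1 - p) * control_draw`, so purity 0 reproduces the
#' control distribution exactly.  Values stay in [0, 1] by construction of
#' the bounded noise.
#'
#' @param config A [sim_config()].
#' @param sites Site table from [simulate_world()].
#' @param truth Truth record from [simulate_world()].
#' @param purity Per-tumor-sample purity in [0, 1] (recycled; default 1).
#' @param seed RNG seed (default `config$seed + 1`).
#' @return A [beta_matrix()] with `n_tumor` tumor and `n_normal` control
#'   samples.
#' @export
simulate_betas <- function(config, sites, truth, purity = 1,
                           seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  purity <- rep_len(purity, config$n_tumor)
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0, 1]")
  set.seed(seed)
  ns <- nrow(sites)
  clamp <- function(x) pmin(0.995, pmax(0.005, x))
  base <- numeric(ns)
  isbg <- sites$class == "background"
  high <- stats::runif(ns) < config$background_high_prob
  base[isbg] <- ifelse(high[isbg], config$background_high_mean,
                       config$background_low_mean)
  base[!isbg] <- config$mu_bivalent
  site_mu <- clamp(base + stats::rnorm(ns, 0, 0.02))
  aff_ids <- truth$affected_region_ids
  affected_site <- !is.na(sites$region_id) & sites$region_id %in% aff_ids
  tumor_mu <- site_mu
  tumor_mu[affected_site] <- clamp(site_mu[affected_site] + config$delta_hyper)
  tumor_mu[isbg] <- clamp(site_mu[isbg] + config$global_hypo_shift)

  conc <- config$beta_concentration
  draw <- function(mu, n_col) {
    matrix(stats::rbeta(length(mu) * n_col, rep(mu, n_col) * conc,
                        (1 - rep(mu, n_col)) * conc),
           nrow = length(mu))
  }
  ctl <- draw(site_mu, config$n_normal)
  tum_pure <- draw(tumor_mu, config$n_tumor)
  tum_ctl <- draw(site_mu, config$n_tumor)
  tum <- sweep(tum_pure, 2, purity, `*`) +
    sweep(tum_ctl, 2, 1 - purity, `*`)
  values <- cbind(tum, ctl)
  colnames(values) <- c(sprintf("T%03d", seq_len(config$n_tumor)),
                        sprintf("N%03d", seq_len(config$n_normal)))
  groups <- stats::setNames(rep(c("tumor", "control"),
                                c(config$n_tumor, config$n_normal)),
                            colnames(values))
  beta_matrix(sites[, c("site_id", "chrom", "pos")], values, groups)
}

#' Simulate a differential-expression table
#'
#' True log2 fold changes are drawn with an FBS-gene mean shift
#' (`fbs_log2fc_shift`) and optional coupling `rho` to each gene's
#' methylation change; the reported log2fc, p-value and FDR come from a
#' two-group test on simulated per-gene replicates, so significance behaves
#' like a real differential-expression analysis rather than being assigned.
#' Control logCPM values are drawn so a configurable fraction of FBS genes
#' is lowly expressed.
#'
#' @param config A [sim_config()].
#' @param truth Truth record from [simulate_world()].
#' @param dmeth Optional named per-gene methylation change (e.g. from
#'   [gene_meth_change()]); when NULL, changes are drawn around
#'   `delta_hyper` for FBS genes and `global_hypo_shift` for others.
#' @param seed RNG seed (default `config$seed + 2`).
#' @return DE data.frame `gene_id`, `log2fc`, `pvalue`, `fdr`,
#'   `logcpm_normal`, plus the simulation column `dmeth`.
#' @export
simulate_de <- function(config, truth, dmeth = NULL,
                        seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  genes <- truth$gene_ids
  is_fbs <- genes %in% truth$fbs_genes
  ng <- length(genes)
  if (is.null(dmeth)) {
    dmeth <- stats::setNames(
      ifelse(is_fbs, stats::rnorm(ng, config$delta_hyper, 0.03),
             stats::rnorm(ng, config$global_hypo_shift, 0.03)),
      genes)
  }
  dm <- dmeth[genes]
  # standardize dmeth within gene class so rho is a within-class correlation
  zd <- numeric(ng)
  for (cls in list(is_fbs, !is_fbs)) {
    if (sum(cls) > 1 && stats::sd(dm[cls], na.rm = TRUE) > 0) {
      zd[cls] <- (dm[cls] - mean(dm[cls], na.rm = TRUE)) /
        stats::sd(dm[cls], na.rm = TRUE)
    }
  }
  zd[is.na(zd)] <- 0
  mu_fc <- ifelse(is_fbs, config$fbs_log2fc_shift,
                  config$background_log2fc_shift)
  true_fc <- mu_fc + config$log2fc_sd *
    (config$rho * zd + sqrt(1 - config$rho^2) * stats::rnorm(ng))
  nrep <- config$de_replicates
  sdr <- config$de_replicate_sd
  ctl_reps <- matrix(stats::rnorm(ng * nrep, 0, sdr), ng)
  tum_reps <- matrix(stats::rnorm(ng * nrep, true_fc, sdr), ng)
  m_t <- rowMeans(tum_reps); m_c <- rowMeans(ctl_reps)
  v_t <- apply(tum_reps, 1, stats::var); v_c <- apply(ctl_reps, 1, stats::var)
  sp <- sqrt(((nrep - 1) * v_t + (nrep - 1) * v_c) / (2 * nrep - 2))
  tstat <- (m_t - m_c) / (sp * sqrt(2 / nrep))
  pval <- 2 * stats::pt(-abs(tstat), df = 2 * nrep - 2)
  logcpm <- ifelse(is_fbs,
                   ifelse(stats::runif(ng) < config$lowly_expressed_fraction,
                          stats::rnorm(ng, -1.5, 1), stats::rnorm(ng, 2, 1)),
                   stats::rnorm(ng, 0.5, 2))
  data.frame(gene_id = genes, log2fc = m_t - m_c, pvalue = pval,
             fdr = stats::p.adjust(pval, "BH"), logcpm_normal = logcpm,
             dmeth = unname(dm), stringsAsFactors = FALSE)
}
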