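# fbsmeth

Bivalent chromatin — promoter or enhancer regions carrying both the
activating H3K4me3 and the repressing H3K27me3 histone mark — keeps
developmental genes lowly expressed but poised for activation. In normal
cells the DNA beneath bivalent chromatin is lowly methylated; in cancer it
is frequently hypermethylated, and the bivalent state itself is often lost.
`fbsmeth` packages the computations needed to study this phenomenon from
standard inputs: ChromHMM-style 15-state chromatin segmentations (Roadmap
BED dialect), 450k-style beta-value methylation matrices or WGBS-style
bedGraph tracks, gene annotations, and per-cancer differential-expression
tables.

The package covers five analysis stages, plus a seeded synthetic-data
generator so every stage is testable without consortium downloads:

1. **Frequently bivalent segments (FBS).** Bivalent intervals (states
   `TssBiv`, `EnhBiv`) from many cell-type segmentations are pooled and
   merged with distinct-contributor counting
   (`count_distinct_merge()`); an FBS is a merged segment supported by
   strictly more than a fraction *f* of the inputs (`build_fbs()`, default
   *f* = 0.8, i.e. "at least 98 of 122" at consortium scale). Conditional
   control sets (e.g. bivalent in ESCs but few differentiated cells),
   active-promoter backgrounds, and gene association via stranded
   1,500 nt promoter windows are included.
2. **Chromatin-category stability.** The 15 states collapse into 8
   categories (`chromatin_categories()`); for a (reference, query)
   segmentation pair the per-category stability is the fraction of
   reference bases whose category is unchanged (`pair_stability()`), and
   `compare_stability_groups()` contrasts cancer pairs with normal pairs
   (per-category z-scores of the stability difference, rank-sum test for
   the Bivalent category).
3. **Methylation profiling.** Per-CpG tumor−control mean differences
   (`group_mean_diff()`), segment aggregation with the ≥3-covered-CpG rule
   (`segment_aggregate()`), 300-bin border profiles with flanks scaled to
   each segment's length (`border_profile()`), and base-level
   stable/lost/new bivalency-fate classification with a lost-vs-stable
   methylation test (`bivalency_fate()`, `fate_meth_comparison()`).
4. **Training-free cancer score.** The *relative descriptor methylation*
   of a sample is

   score = mean over classifier regions of (region mean beta) / (mean beta over all covered CpGs)

   i.e. a methylation fold change in bivalent segments; no training step is
   involved. Regions with fewer than 3 covered CpGs and samples with fewer
   than 3 surviving regions are discarded. `roc_auc()` evaluates
   cancer-vs-normal separation (Mann–Whitney AUC, ties half-credited),
   `subset_search()` enumerates all 2^n − 1 region subsets,
   `purity_crossing()` finds the tumor purity at which the lower 90%
   prediction bound of the score reaches the 5% false-negative threshold,
   and `ordinal_correlation()` relates purity-normalized scores to tumor
   stage/grade. The published 14-region classifier set ships as a fixture
   (`load_classifier_regions("fbs14")`).
5. **Methylation–expression integration.** Per-gene methylation change
   (`gene_meth_change()`) against edgeR-style DE tables: quadrant
   statistics (Q1 = hypermethylated and up-regulated,
   `quadrant_analysis()`), fold-change comparisons against backgrounds
   (`fc_group_comparison()`), and recurrently up/down-regulated gene sets
   across cancers (`recurrence_sets()`).

## Worked example

```r
library(fbsmeth)

cfg   <- sim_config(seed = 11)          # defaults: 20 cell types, 25 planted
world <- simulate_world(cfg)            # regions, 25 decoys, 50+50 samples
fbs   <- build_fbs(count_distinct_merge(world$segmentations),
                   rule = support_rule(fraction = 0.8))
nrow(fbs)                               # 25 — exactly the planted regions
range(fbs$support)                      # 18 18  (= round(0.9 * 20) cell types)

bm  <- simulate_betas(cfg, world$sites, world$truth)
md  <- group_mean_diff(bm)
agg <- segment_aggregate(md, fbs)
mean(agg$mean_value)                    # 0.056 — mean FBS methylation gain
                                        # (+0.07 at the 80% affected regions)
sc  <- score_samples(bm, fbs)
roc_auc(sc$score, ifelse(sc$label == "tumor", "cancer", "normal"))$auc
# 1 — tumors and controls separate perfectly at purity 1

de <- simulate_de(cfg, world$truth)
q  <- quadrant_analysis(world$truth$fbs_genes,
                        setNames(de$dmeth, de$gene_id), de)
q$counts                                # Q1 Q2 Q3 Q4 = 28 0 0 0
round(q$q1_mean_log2fc, 2)              # 2.19 — significant FBS genes are
                                        # hypermethylated AND up-regulated
```

The 28 genes in Q1 are significantly differentially expressed FBS genes
that show both a positive methylation change and a positive log2 fold
change — the positive-dependence signature the quadrant statistic is
designed to detect. On real data the same calls consume
`read_segmentation()`, `read_beta_matrix()` / `read_bedgraph()`,
`read_genes_gtf()` and `read_de_table()` inputs instead of the simulator.

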