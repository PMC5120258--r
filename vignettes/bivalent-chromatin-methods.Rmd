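---
title: "Bivalent chromatin, DNA methylation and expression in cancer: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivalent chromatin, DNA methylation and expression in cancer: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbsmeth)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions, and the design
choices made where several readings were defensible. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
compute themselves.

## Coordinates and interval conventions

All coordinates are 0-based half-open (BED convention), everywhere,
including the packaged classifier table, whose printed coordinates are
ingested as-is and treated as half-open. State mnemonics are normalized by
stripping a leading `<digits>_` prefix; matching is case-sensitive
afterwards. `merge_intervals()` defaults to `max_gap = 0` and merges
book-ended intervals — the default behaviour of the standard merging tool —
so intervals from different cell types that touch end-to-start become one
segment. Whether book-ended bivalent intervals from different files should
merge is not fully determined by the method description; we follow the
merging tool's default (yes). `subtract_intervals()` discards *whole*
intervals on any (≥1 bp) overlap rather than clipping bases, matching the
description of the active-promoter background construction ("segments
overlapping … were discarded").

## Frequently bivalent segments

FBS construction pools `TssBiv` and `EnhBiv` intervals only; `BivFlnk` is
deliberately excluded here but *included* in the Bivalent category used for
stability and fate analyses — the two definitions serve different
purposes (building a conservative consensus region set vs. classifying all
bivalent-flavoured bases). A contributor is counted for a merged cluster
when any of its intervals was merged into that cluster (cluster-level
attribution, the distinct-count semantics of the merging tool), not by
per-base overlap.

The fractional support rule is strict: a segment passes `fraction = 0.8`
only when `support > 0.8 * n_inputs`, which reproduces "at least 98 of
122" at consortium scale and, e.g., excludes support 4 of 5. Absolute
rules (`min_support = k`) serve the classifier set (120 of 122) and the
ESC comparison set (7 of 8). For conditional sets (pass rule A in group A,
*fail* rule B in group B) a candidate segment's group-B support is the
maximum support among overlapping group-B segments, 0 when it overlaps
none. The ESC-derived sets are assumed to be merged within their group
before thresholding.

Gene association uses a stranded promoter extension (default 1,500 nt
upstream): window `[max(0, start − w), end)` on the plus strand,
`[start, end + w)` on the minus strand. Windows are clipped at position 0;
no clipping is applied at chromosome ends (lengths are not required
inputs). Association is any-overlap (≥1 bp); a gene may associate with
many segments and vice versa. Coverage statistics (fraction of FBSs
bivalent in a cell type, fraction of a cell type's bivalent segments in an
FBS) are segment-level any-overlap counts, not base fractions.

## Stability between paired segmentations

The 15 states collapse into 8 categories (Bivalent, Promoter, Transcribed,
Enhancer, PolycombRepressed, ZNF, Quiescent, Heterochromatin). Stability
is reference-directional: for category *c*,
`stability = bases(reference ∩ c ∩ query ∩ c) / bases(reference ∩ c)`,
with reference bases missing from the query's coverage counted as changed.
No symmetrization is applied, per the wording "relative to the normal
segmentation". The statistic is invariant to how either segmentation is
fragmented into adjacent intervals.

For the cancer-vs-normal contrast, each category's difference
`Δc = mean(normal) − mean(cancer)` is z-scored against the mean and SD of
all categories' differences. The exact published recipe (which categories
entered, sample vs. population SD) is unstated; we use the sample SD
(R's `sd`), which matches the worked value used in our tests (a single
Δ = 1 among 8 categories gives z ≈ 2.475), and document rather than claim
equivalence with the published z = 2.27. The accompanying rank-sum test
compares the Bivalent stabilities of the cancer pairs against the pooled
other-category stabilities of the cancer pairs, two-sided; it is exact for
≤ 20 untied observations and a tie-corrected normal approximation
otherwise.

## Methylation aggregation and profiles

Per-site differences are `mean(tumor) − mean(control)` over non-missing
beta values; a site covered in only one group is missing, not zero.
Segment aggregation is an **unweighted mean over covered CpGs** (not
base-weighted): the ≥3-covered-CpG discard rule is phrased in CpG counts,
and CpG-mean aggregation is standard array practice. WGBS-style inputs are
per-site bedGraph tracks and are treated identically.

Border profiles extend each segment by 100% of its own length on both
sides and split the window into 300 equal bins (so one bin = 1% of the
segment length; bins 1–100 left flank, 101–200 body, 201–300 right
flank). A site on a bin boundary belongs to the right-open bin containing
it (floor at assignment). Per bin, segment means are averaged across
segments *with data*; empty bins are missing, never zero. Windows that
would start below position 0 simply contribute no sites there. A
convenience wrapper partitions segments at 10,000 nt before profiling,
mirroring the short/long FBS comparison.

Bivalency fate operates at base level: the union of bivalent bases
(categories `TssBiv`, `BivFlnk`, `EnhBiv`) of the normal and cancer
segmentation is partitioned into stable/lost/new sub-intervals by set
algebra. Keeping segments whole would be ill-defined under partial
overlaps; the base-level partition is the only reading that satisfies the
conservation identities (stable + lost = normal bivalent bases,
stable + new = cancer bivalent bases), which the test suite checks on
random fixtures. Fate intervals are then aggregated like any other
segments (≥3 CpGs) before the lost-vs-stable rank-sum test; an all-tied
degenerate comparison reports p = 1.

## The training-free cancer score

For one sample, each classifier region's mean beta is computed over its
covered CpGs; regions with fewer than 3 covered CpGs are dropped, and the
score is the mean of the surviving region means divided by the sample's
mean beta over **all** covered CpGs on the array. Samples with fewer than
3 surviving regions, or a zero denominator, are discarded with a recorded
reason. The ratio form makes the score invariant to rescaling a sample's
betas, which is what makes it portable across arrays without training.
Cancer is the positive class: bivalent hypermethylation raises the
numerator.

AUC uses the Mann–Whitney convention (ties half-credit) computed from
ranks; ROC points come from descending-score thresholds. The subset search
enumerates all `2^n − 1` non-empty subsets (refused above n = 20). We
enumerate 16,383 subsets for 14 regions; the published count of 16,396 is
arithmetically inconsistent with 2^14 and is treated as a typo. For
subsets of size 1–2 the ≥3-region sample filter is waived down to the
subset size (otherwise no sample could survive); those rows are flagged.

The purity model is an OLS fit of score on tumor purity with a
**prediction** interval (not a confidence interval of the mean), per the
phrase "confidence interval prediction". The "5% false negative
threshold" is operationalized as the 95th percentile of the control score
distribution — the cutoff that keeps 5% false positives on controls,
equivalently the sensitivity anchor given the score's direction; the rate
is configurable. The crossing is the smallest purity in (0, 1] where the
lower prediction bound reaches the threshold, located on a 2001-point grid
and refined by root finding (tolerance 1e-8). With zero residual variance
the band has zero width and the crossing is the exact line solution. In
recovery experiments the estimator's target is therefore the *population
crossing of the lower prediction bound*,
`p* = (threshold − intercept + z_(1+band)/2 · σ) / slope`, not the
noiseless line crossing, and that is the reference our tests use.

Stage/grade correlation is rank-based (Spearman) by default — the natural
choice for ordinal levels; Pearson is available by flag since the
published analysis did not state which was used. Sub-stages collapse to
their main stage (Stage Ia → Stage I), grades G1–G4 map to 1–4, and
anything else is discarded. Fewer than 3 mapped pairs, or a constant
ordinal vector, yields a reported non-result rather than a number.

## Methylation–expression integration

Quadrants are sign-based on (per-gene methylation change, log2 fold
change): Q1 = both positive. Exact zeros on either axis are excluded from
all quadrants (they are measure-zero under the generator, and assigning
them to a side would bias the independence null). Significance filtering
uses FDR < 0.05 by default; the published analysis says "significantly
differentially expressed" without printing a cutoff, so the field default
is used and exposed as a parameter. DE tables are consumed, never fitted:
differential-expression estimation is an external, off-the-shelf step.
Background sets always exclude the focal genes. Recurrence sets require
significance with consistent direction in strictly more than
`min_fraction` of the tables *and* at least `min_datasets` tables,
counting all supplied tables (not only those where a gene was testable);
a gene qualifying in both directions is assigned to the direction with the
larger count.

## The synthetic-data generator

`simulate_world()` / `simulate_betas()` / `simulate_de()` emulate the
structure the analyses assume, at desk scale, deterministically under the
config seed (R's default integer-state generator; identical seeds give
bit-identical outputs on a given R version).

Effect sizes keep the published values: control mean beta at bivalent
regions 0.10; tumor hypermethylation +0.07 at 80% of planted regions;
global background shift −0.05 (bracketing the reported −0.06/−0.04 WGBS
means); FBS-gene mean log2 fold-change shift +0.94. Problem sizes are the
package's own choice of a tractable world: 20 normal cell types, 25
planted regions (length 3–15 kb, around the reported ~9.3 kb mean) plus 25
decoys on 2 × 2 Mb chromosomes, CpG densities of 1/150 nt in bivalent
regions vs 1/1500 nt outside (CpG-island-like enrichment), 50 tumor + 50
control samples. The test suite uses a further reduced world (1 × 0.5 Mb,
10 + 10 regions, 10 cell types) where many replicates are needed.

Support is deterministic by design: a planted region is bivalent in
exactly `round(f · N)` randomly chosen cell types rather than
Bernoulli(f) per cell type. This makes planted-set recovery at the 0.8
threshold a construction guarantee (0.9 · N supporters always exceed
0.8 · N) instead of a binomial gamble, which is what a recovery test needs
to be a test of the merge/threshold machinery rather than of sampling
noise. Beta noise is a beta distribution parameterized by mean and
concentration (default 80), keeping values in [0, 1] without clipping
artifacts; observed tumor values are the purity mixture
`p · tumor_draw + (1 − p) · control_draw`, so purity 0 reproduces the
control distribution exactly. Non-bivalent filler states are sampled from
a fixed, quiescent-dominated frequency table so the stability analyses see
a realistic category composition. DE p-values are produced by a two-group
t-test on simulated per-gene replicates (6 + 6, replicate SD 1), not
assigned directly, so the FDR column behaves like a real analysis; the
coupling knob `rho` correlates a gene's log2 fold change with its
methylation change within gene class (`rho = 0` gives exact
independence, the null used to check the quadrant statistic against
`P(Δ>0)·P(fc>0)`).

What the generator does **not** emulate: probe-level array artifacts and
normalization effects, spatial correlation of methylation beyond region
membership, copy-number or purity heterogeneity within a sample,
gene-length and GC biases in expression counts, and cross-cancer
correlation structure. Passing tests therefore demonstrate correctness of
the computations under the assumed structure, not robustness to every
real-data pathology.

## Calibration choices in the checks

Two checks needed an explicit calibration decision, made from closed-form
considerations before running them:

* **Classifier null arm.** Under exchangeable scores the Mann–Whitney AUC
  has SD `sqrt((n1+n2+1)/(12 n1 n2))` ≈ 0.058 at 50 + 50 — too wide for a
  [0.4, 0.6] band to hold in 95% of replicates. The null arm therefore
  uses 100 + 100 samples (SD ≈ 0.041, in-band probability ≈ 0.985); the
  power arm keeps 50 + 50 as specified for the +0.07 effect.
* **Purity-crossing recovery.** The noisy-recovery check compares
  estimates against the population crossing of the lower prediction bound
  (see above), the quantity the estimator is consistent for.

## Known limitations

* `segment_aggregate()` assigns a CpG to the first covering segment;
  segment tables are expected to be non-overlapping (FBS sets, fate
  partitions and categorized segmentations all are).
* The stability z-score and the purity threshold are documented
  operationalizations of ambiguous descriptions; both are parameterized
  rather than hard-coded where a different reading is defensible.
* The bivalent-promoter (9-region) and bivalent-enhancer (12-region)
  classifier variants have no published coordinates; they must be rebuilt
  from segmentation inputs and are refused with an explicit error when
  requested as fixtures.
* Genome builds are taken at face value: no liftover, no bigWig/bigBed or
  tabix support.
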