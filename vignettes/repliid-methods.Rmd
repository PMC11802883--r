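---
title: "Scoring pooled barcode ChIP screens: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled barcode ChIP screens: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliid)
```

## The measurement

The screen this package quantifies tracks the leading-strand DNA
polymerase (Pol epsilon) at a single barcoded replication origin across
thousands of pooled yeast strains at once. Each deletion strain carries a
unique 20-bp DNA barcode integrated next to a late-firing origin; after
synchronous release into S phase under hydroxyurea (HU), chromatin
immunoprecipitation (ChIP) of the tagged polymerase followed by barcode
amplicon sequencing reads out, per strain, how much polymerase sits at
the barcode. The abundance of a strain's barcode in the IP sample
relative to the input (total chromatin) sample is the occupancy score:
strains in which forks collapse or stall lose polymerase signal, strains
with persistently stalled forks accumulate it. Samples are taken at two
timepoints after release (40 and 80 min) so that slow or delayed forks
can be told apart from unstable ones. A population of ~1100 barcoded
wild-type strains rides along in the pool as the control.

## The quantification model

For each sample the pipeline counts reads per barcode by locating a
configurable anchor sequence and taking the next `L` bases
(`read_structure()`, `count_barcodes()`). Counting is exact by default;
an opt-in `hamming1` policy rescues reads whose extracted barcode has a
unique library neighbour at Hamming distance 1. Reads that cannot be
assigned are retained as QC tallies (`no_anchor`, `short_read`,
`unknown_barcode`, `ambiguous_correction`), never errors.

Scoring then proceeds per (timepoint, replicate):

1. **Absence filter.** A barcode whose input count falls strictly below
   0.0025% of that input sample's total reads is treated as absent from
   the pool and excluded (`filter_absent()`; `absence_fraction = 2.5e-5`).
   A barcode exactly at the cutoff is retained, because the rule excludes
   what is *below* the threshold.
2. **Median normalization.** Counts over the retained set are divided by
   their median (`median_normalize()`), making scores invariant to
   sequencing depth. Even-sized sets use the conventional midpoint
   median.
3. **IP/input ratio.** The occupancy score of barcode *b* is
   `ratio_b = IP_score_b / input_score_b` (`ip_over_input()`). The
   absence filter guarantees the denominator is positive; a barcode with
   zero IP reads gets ratio 0.
4. **Replicate averaging.** A gene is scored only if its barcode is
   retained in *every* replicate's input at *both* timepoints (the
   strict intersection of "overlapping ORFs"); ratios are combined by
   the arithmetic mean of raw ratios (`merge_replicates()`).
   Mean-of-log2-ratios is available as `replicate_combine =
   "mean_of_logs"`.
5. **Fold change.** `log2fc = log2(mean_ratio / B_t)` with a
   per-timepoint baseline `B_t` (`log2_fold_change()`). Zero mean ratios
   are floored to the smallest positive mean ratio in the table before
   the log and flagged in the output, so every fold change is finite
   while the flooring stays visible.
6. **Hit calling.** With threshold `tau = 1.25` (log2 units), mutants
   fall in exactly one of five classes (`classify_mutants()`):
   `down_both` (`fc40 < -tau` and `fc80 < -tau`), `up_both` (both
   `> tau`), `down_40_only` (`fc40 < -tau`, `fc80 >= -tau`),
   `down_80_only` (`|fc40| <= tau`, `fc80 < -tau`) and `other`. All
   comparisons are strict, so a fold change of exactly -1.25 is never
   "down". The four non-`other` classes are the interpretation buckets
   for unstable forks, persistent stalling, slowed forks and fast forks
   respectively.

### Design choices that were genuinely open

**Fold-change baseline.** Published fold changes of this kind do not
state what "fold change 1" is anchored to. Because the pool contains an
explicit wild-type control population, the default here centres each
timepoint on the median mean-ratio of the wild-type barcodes
(`baseline_policy = "wildtype_median"`), which makes the median
wild-type log2 fold change exactly 0. `all_median` (centre on the whole
table) and `none` (raw ratios) are provided for sensitivity analyses;
with well-behaved pools the three differ by a small additive constant.

**Replicate combination.** Averaging raw ratios and then taking the log
follows the stated procedure literally ("the ratios were averaged").
The alternative, averaging log ratios, is less sensitive to a single
high-ratio replicate; it is exposed as an option rather than the
default.

**Replicate agreement.** The screen's reproducibility statistic is
reported only as "R". `replicate_correlation()` defaults to Pearson
correlation of log2 ratios over the shared barcodes — ratios are
approximately log-normal, so correlating logs is the standard choice —
with Spearman on raw ratios as the option.

**Boundary conventions.** Absence filter: strictly below excludes,
exactly-at retains. Hit calls and the suppressor fold-change call:
strictly greater/less than the threshold. These all follow the wording
of the respective rules; the tests pin each boundary.

## Overlap enrichment

`overlap_enrichment()` compares a hit list against an annotation gene
set over a universe of scored genes. The published comparison of this
kind reports the annotated fraction among hits next to the genome-wide
annotated fraction *including* the hits; the 2x2 table therefore uses
`K - k` annotated non-hits, and the printed output says so. Percentages
are what such comparisons report; the exact hypergeometric test
(two-sided by summing tables with probability less than or equal to the
observed one, the standard convention and identical to `fisher.test`)
and the sample odds ratio are computed as an extension and labelled as
such.

## Suppressor-screen colony scoring

`suppressor_scores()` scores an arrayed double-mutant screen grown with
and without drug: colony sizes are normalized to the median size of
their plate (zeros included in the median; they normalize to 0), the
per-strain score is the treated/control ratio of normalized sizes,
strains with a zero normalized size in either condition are removed
before scoring, and a suppressor call requires score strictly above the
fold-change threshold (default 1.5). The output is sorted by descending
score — the waterfall order. Replicate plates, if supplied, are averaged
per strain; spatial (row/column/edge) corrections used by some array
tools are deliberately out of scope.

## The synthetic-data generator

No public generative model exists for these screens, so the generator's
noise model is the package's own and every knob is surfaced in
`simulation_params()`:

* **Library**: `n_mutants = 4500` and `n_wildtypes = 1100` by default,
  matching the composition of a full screening pool; barcodes of length
  20 drawn uniformly with a minimum pairwise Hamming distance of 3,
  mirroring the separation designed into real barcode libraries.
* **Abundance**: per-strain pool abundance is log-normal with
  `abundance_log_sd = 0.5` (natural-log scale) — strains in pooled
  collections differ in fitness, so a ~65% coefficient of variation is a
  realistic degree of pool imbalance.
* **Occupancy effects**: each mutant class multiplies its expected IP
  proportion by `2^effect` at each timepoint; default class proportions
  (15% `down_both`, 4% `up_both`, 5% each one-timepoint class) echo the
  hit structure of a real screen. The truth table's class labels are
  derived from the injected effects through the same ±1.25 rule used for
  calling, so truth and calls are commensurable.
* **Noise**: a per-(strain, replicate) log-normal factor
  (`replicate_noise_sd = 0.1`, shared between timepoints within a
  replicate) models biological replicate-to-replicate variation in IP
  recovery; read counts are multinomial at `read_depth = 2e6` per
  sample; each emitted read is `anchor + barcode + filler` with i.i.d.
  substitution errors at `base_error_rate = 0.002`, a typical Illumina
  amplicon error rate.

What the generator does **not** model: PCR duplicates and jackpotting,
GC or position-dependent error bias, indels, quality-score structure,
cross-sample index hopping, and any correlation between a mutant's pool
abundance and its occupancy effect. Passing the recovery tests therefore
shows the quantification is correct under multinomial sampling noise and
uniform substitution error — not that it is robust to every artefact of
real libraries.

## Validation scale and determinism

The package's own validation runs a scaled screen of 500 mutants + 100
wild types at 2 million reads per sample, two replicates — small enough
to run routinely, deep enough (~3000 reads per barcode) that a log2
effect of 2 stands more than ten standard errors clear of the call
threshold. Under those conditions the pipeline recovers injected
`down_both` strains with sensitivity and precision 1.0, calls nothing in
a zero-effect null, and the two simulated replicates correlate at
R ≈ 0.95. All generator functions are deterministic given their seed;
`run_screen_pipeline()` is deterministic given its inputs and writes a
run manifest (config snapshot, input checksums, per-sample QC, retained
counts, baselines, class tallies) sufficient to reproduce the run.

## Known limitations

* Reproducing a published full-scale screen additionally requires the
  deposited raw reads and the barcode-to-strain annotation of the
  physical library, plus that screen's (unstated) baseline convention;
  the pipeline exposes every convention as a parameter so such a
  reproduction is a configuration exercise, not a code change.
* The absence filter keys on each input sample's total read count; if
  counts tables are imported without their QC totals, the assigned sum
  stands in for the total and the cutoff shifts accordingly.
* One barcode per mutant means barcode-level and gene-level inference
  coincide; multi-barcode designs are only supported for the wild-type
  control population.
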