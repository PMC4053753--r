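---
title: "Methods: HELP methylation arrays, DMR calling and downstream integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HELP methylation arrays, DMR calling and downstream integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helpdmr)
```

## The assay and its observable

The HELP assay (HpaII tiny fragment Enrichment by Ligation-mediated PCR)
compares two digests of the same genomic DNA: HpaII cuts only unmethylated
CCGG sites, MspI cuts regardless of methylation. Both digests are amplified
and hybridized to a two-channel array whose unit locus is the
HpaII-amplifiable fragment (HAF): a stretch between two HpaII sites 200 to
2,000 bp apart. A fragment that is unmethylated amplifies in both digests;
a methylated fragment amplifies only in the MspI channel. The quantitative
observable is therefore the log2(HpaII/MspI) intensity ratio: high ratio =
hypomethylated, low ratio = methylated.

`helpdmr` implements the full path from probe-level intensities to
biological summaries:

1. **Summarization** — each fragment-channel-sample signal is a robust
   25% trimmed mean of its probe intensities (`trimmed_mean()`): probes are
   sorted, `floor(0.25 n)` dropped from each tail, the rest averaged.
2. **Background and status calls** — arrays carry random probes matching no
   HAF. Per array, the background threshold is their median plus 2.5 robust
   scale units (`background_threshold()`). A fragment whose MspI signal is
   within background failed to amplify ("failed": deletions, digestion or
   PCR failure); MspI above but HpaII within background means fully
   methylated ("methylated"); both above means "amplifying" and carries a
   usable ratio. The three statuses partition all (fragment, sample) pairs.
3. **Normalization** — amplifying log-ratios are quantile-normalized
   *within* each array across *samples* in sliding windows of fragment
   size-sorted data (`window_quantile_normalize()`), because PCR efficiency
   depends strongly on fragment length. Windows hold a fixed count of
   fragments (default 1,000), which makes them density-adaptive; they step
   by half a window, and a fragment covered by two windows gets the average
   of its windowed values.
4. **Centering** — each array's mean over amplifying loci is subtracted, so
   the sign of an entry classifies it (negative = methylated, positive =
   hypomethylated) and arrays are comparable.
5. **Testing** — a pooled-variance two-sample t-test per locus
   (`locus_differential_test()`), with `delta = mean(case) - mean(control)`
   so positive delta means *less* methylation in disease. DMRs are loci with
   p < 0.01 and |delta| > 0.5, ranked by |t| (`call_dmrs()`).
6. **Context** — RefSeq-style category assignment with promoter >
   5'UTR > 3'UTR > TTS > exon > intron > intergenic priority, enrichment
   against the array's own composition, chromatin-state overlap at >= 1 bp,
   and DHS enrichment against matched random loci (same count, same mean
   size, chromosomes sampled by length) with an add-one permutation p-value.
7. **Integration** — differential expression with a pooled 20th-percentile
   expression filter and Benjamini-Hochberg correction at adjusted p <
   0.05; sign concordance under the convention hypomethylated (in cases)
   pairs with up-regulated (in cases); replication concordance against
   signed absolute-methylation differences from an external platform; and
   Pearson correlation of absolute methylation percentages against relative
   log-ratios, expected negative.

## Design choices where the method description is open

Several steps admit more than one reasonable reading; the package fixes one
default and keeps the alternative behind a flag.

- **Robust scale ("MAD").** The background threshold uses the median
  absolute deviation about the median without the 1.4826 consistency
  factor, the standard robust scale. A mean-absolute-deviation convention is
  available (`processing_params(mad_type = "mean")`) since the phrase "mean
  absolute differences" is ambiguous.
- **Trim convention.** "25% trimmed" is interpreted per tail, matching
  `mean(x, trim = 0.25)` in R.
- **Window scheme.** "Density-dependent sliding windows" fixes neither size
  nor step; fixed-count windows (1,000 fragments, step 500) are
  density-adaptive by construction. The step is capped at the window size so
  the windows always tile the size-sorted fragments. With non-overlapping
  windows the normalization is exactly idempotent; overlap averaging makes
  it only approximately so, which the test suite checks explicitly.
- **Fold change.** "Fold change > 0.5" is applied to the difference of
  group means of log2(HpaII/MspI), the variable actually tested, since a 0.5
  log2 difference is about a 50% change of the ratio. A ratio-scale reading
  (2^|delta| - 1 > cutoff) is available via
  `processing_params(fold_change_scale = "ratio")`.
- **t-test.** Pooled variance by default — the classical reading of an
  unqualified "two-sample t-test" — with Welch behind `var_equal = FALSE`.
- **Missing loci.** A fragment failed in a sample contributes a missing
  value; loci missing in more than half of either group's samples are
  dropped before testing and counted in the QC attribute. The per-locus test
  additionally requires two observations per group.
- **Clustering.** The heatmap selection (p < 1.5e-4, |delta| >= 0.5) is
  clustered under squared Euclidean dissimilarity; only the dissimilarity is
  prescribed, so average linkage is used.
- **Annotation windows.** Promoter = TSS -1,000/+500 bp strand-aware, TTS
  window +/- 500 bp; these window sizes are not prescribed anywhere and are
  configurable arguments echoed in outputs. Priority puts small regulatory
  categories above gene-body categories so they are not swallowed.
- **Matched random loci** use a fixed size equal to the target mean rather
  than a size distribution, because only count and mean size are specified
  (defaults 4,751 loci of 443 bp).
- **Replication "confirmation".** A DMR gene is confirmed when the
  replication difference is nonzero, significant (p < 0.05 when p-values
  are present), and sign-matched — discovery hypomethylation (positive
  ratio delta) matches a negative absolute-methylation difference. The rule
  is caller-replaceable (`significance = function(tab) ...`) because
  "concordant regulation" has no unique operational definition.
  Multi-probe genes collapse to the probe with the largest |difference|.
- **Expression filter reference.** The 20th percentile is computed over all
  gene-level group means pooled, and genes qualify when their larger group
  mean is strictly above it. Under this reference distribution the filter
  can never remove every gene except in degenerate (constant) data.
- **Zero handling.** Intensities are floored at 1e-6 before logs; p = 0
  underflow is floored at 1e-300 for the volcano transform; permutation
  p-values use the add-one rule and cannot be 0.

## The synthetic experiment and what it does (not) emulate

`sim_config()` describes a complete synthetic HELP study with known planted
truth, and its defaults are the conditions the package is calibrated
against: 12 control vs 14 case arrays, 10,000 HAFs with sizes from a
log-normal truncated to [200, 2,000] bp with mean ~443 bp, 3 probes per
fragment, 2,000 random probes, 500 planted DMRs of magnitude 1.0 on the
log2 scale with 70% hypomethylated in cases, per-sample log-ratio noise sd
0.5, 2% failed fragments, a 10-label chromatin segmentation, 1,000 DHS
peaks of which 30% are planted on DMR loci, expression coupling at 40% of
DMR genes with 98% sign concordance, and a replication table concordant at
98%. Methylation maps to the ratio through `baseline - k * m` (defaults 1
and 2): the monotone decreasing link is all the assay semantics require.

Randomness is organized as one sub-stream per output table, derived from
the master seed, so identical configs give byte-identical files and
regenerating one table does not perturb the others. Fragments are placed
with 3-8 kb gaps and gene models extend 200-1,000 bp beyond their
fragment, so the TSS-nearest gene of a fragment is its own gene — the
planted methylation-expression coupling is then recoverable through the
annotation step rather than by private bookkeeping.

The generator deliberately does *not* model probe sequence content,
hybridization physics, dye bias, spatial artifacts, or bisulfite data.
Intensities are log-normal with multiplicative probe noise; failed
fragments and random probes draw every probe independently from a
low-mean log-normal background. Passing tests therefore demonstrate the
statistical behavior of the pipeline under a clean generative model —
calibration, power, direction recovery, enrichment detection — not
robustness to array artifacts, which real HELP experiments handle with
separate chip quality control.

## Verification strategy and problem sizes

The test suite runs entirely on generated data at sizes chosen to keep the
full run in minutes while retaining statistical power:

- brute-force oracle equivalence (100 randomized instances each) for the
  trimmed mean, the median/MAD threshold, single-window quantile
  normalization, Benjamini-Hochberg step-up, the pooled t-test against
  `stats::t.test`, and interval overlap against an O(n m) scan;
- type-I calibration on a 10,000-locus null study (12 vs 14): the p < 0.01
  fraction within three binomial sigmas of 1% and the empirical CDF within
  the 1% Kolmogorov-Smirnov band of uniformity;
- planted-truth recovery at the default study conditions: sensitivity,
  direction mix within the binomial interval of 70%, exact equality of the
  called set with an independent per-locus reimplementation, and
  sensitivity monotone over effect sizes 0.25-2.0 (200 planted DMRs in
  3,000 loci per effect size);
- enrichment behavior: random DMR subsets give RefSeq ratios consistent
  with 1, the planted DHS preference is detected at 999 permutations, and
  with no preference the permutation p is spread roughly uniformly over 50
  seeds;
- end-to-end determinism: identical config and seed reproduce every output
  file checksum, and all report counts re-derive from the on-disk tables.

`scripts/acceptance.R` repeats the study-scale run from scratch for an
arbitrary seed and writes the headline quantities (DMR count, hypomethylated
percentage, mean DMR size, sensitivity/FDR against the planted truth, null
false-positive rate, DHS overlap and permutation p, DMR-gene DE percentage,
sign concordance, replication concordance, MassArray-style correlation) as
JSON.

## Known limitations

- The windowed quantile normalization assumes most loci are unchanged
  between samples within a size window; very dense differential signal
  would be partially normalized away, as with any unsupervised
  between-sample alignment.
- DMRs are single HAFs; adjacent fragments are not merged into larger
  regions.
- The permutation null for DHS enrichment matches count and mean size but
  not local genomic covariates (GC, mappability), which do not exist in the
  synthetic genome; with real annotations a covariate-matched null would be
  stricter.
- UTR categories require gene models with coding bounds; without them UTR
  intervals are absorbed into `exon` (with a message).
- All interval inputs must share one genome assembly; the package performs
  no liftover.
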