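---
title: "Methods: mining serial-passage xenograft microarray data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining serial-passage xenograft microarray data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenomine)
```

## The problem

Human tumor cell lines grown subcutaneously in immunocompromised mice are a
workhorse of cancer drug development, but two things complicate reading
their transcriptomes off a human expression array. First, the transcriptome
is not static: serial in vivo passage (P1 → P4 → P10) can change the
expression of hundreds to thousands of transcripts, and in the extreme a
late-passage "xenograft" can consist entirely of proliferating host
(mouse) cells. Second, the sample is a mixture: mouse stroma contributes
RNA that cross-hybridizes with a subset of the human probe sets and
masquerades as human up-regulation — especially in analyses of the
in vitro → in vivo (P0 → P1) transition, where stromal genes dominate the
top of the fold-change list.

`xenomine` implements the full analysis chain for this setting: probe-level
preprocessing, detection calls, QC that catches host outgrowth, an
empirical cross-hybridization mask, a per-model passage-stability metric,
masked transition ranking, over-representation statistics, and the in vivo
efficacy arithmetic used to validate expression-based predictions. A
synthetic cohort generator with a ground-truth channel makes every stage
testable without any array downloads.

## Preprocessing model

Arrays carry ~11 probe pairs per probe set; each pair has a perfect-match
(PM) and a mismatch (MM) probe. The pipeline follows the standard
robust-multi-array path on PM values:

1. **Median scaling.** Each array is scaled so its median PM intensity is
   500 units (`scale_to_median()`), the chip-wide setting used across the
   cohort this package models.
2. **Quantile normalization.** All samples are forced onto the vector of
   row means of the column order statistics (`quantile_normalize()`);
   within-sample ranks are untouched and ties get the mean of the
   reference values they span. The operation is idempotent.
3. **Median polish.** Per probe set, the additive model
   `log2(PM_ij) = mu + probe_i + sample_j + eps` is fitted by Tukey's
   alternating median sweeps (`median_polish_summarize()`, tolerance 0.01
   on the residual L1 change, at most 10 sweeps — the common practice
   defaults); probe-set expression is `mu + sample_j`.

Background correction defaults to "none" (a minimum-shift option exists).
The full normal-exponential convolution is deliberately not implemented:
every downstream statistic in this workflow is relative (fold changes,
ranks, counts), and the vignette section on limitations describes the one
systematic consequence — additive background compresses fold changes of
low-abundance transcripts.

**Detection calls.** Present/Marginal/Absent calls are a within-sample
test and are therefore computed on median-scaled, *not*
quantile-normalized intensities. Per probe pair the discrimination score
`R = (PM - MM)/(PM + MM)` is tested one-sided against the threshold
`tau = 0.015` with a Wilcoxon signed-rank test; `p < 0.04` gives P,
`0.04 <= p < 0.06` gives M, else A. The constants are the platform's
published defaults, exposed in `detection_params()`. For up to 12 probe
pairs the null distribution is exact, computed by generating-function
convolution over the doubled midranks (so the platform norm of 11 pairs
always takes the exact path); beyond that a normal approximation with tie
correction and continuity correction is used. Zero differences are
dropped; a probe set with no usable pairs is Absent with p = 1. The
discrimination score is scale-free, so detection p-values are invariant to
joint rescaling of PM and MM — property-tested.

**Noise filter.** The bottom fifth of intensities on a genome-wide array
is treated as noise: a probe set is retained iff it exceeds the 20th
percentile (linear-interpolation definition) of the per-sample
distribution in at least one sample (`percentile_filter()`).

## The cross-hybridization mask

Five mouse RNA populations (universal RNA, two tumors, two host skins),
each hybridized in triplicate to the *human* array, define the mask. A
probe set is "detected" in one biological sample when at least 2 of its 3
replicate calls are Present. This is the order-free reading of the
replicate-call patterns PPP/PPM/PPA: the three listed patterns share
exactly the ≥2-Present property, and replicate order on a chip is
arbitrary. Patterns such as PMM or PAA are *not* detected; the predicate
is configurable (`min_present`). The mask stores, per probe set, the
count (0–5) of biological samples with detection; `mask_at_stringency(s)`
keeps probe sets with count ≥ s, so views are nested downward in s.

For transition reporting the default exclusion stringency is **1**,
because the worked example this package reproduces removes entries
flagged in as few as one mouse sample; the conservative 4-of-5
alternative is a parameter away.

## Passage stability and the transition analysis

Differential expression between two passages uses one-way fixed-effects
ANOVA on log2 values — identical to the pooled-variance t-test for two
groups (Welch is available). P-values are unadjusted, matching the
p < 0.05 convention of the workflow modeled here; a BH option exists for
the enrichment stage. Fold change is the ratio of geometric means,
`2^(difference of log2 group means)`, and the >3-fold stability cutoff is
strict (FC > 3).

The **stability metric** of a model is the pair of counts of probe sets
changed >3-fold (p < 0.05) from P1→P4 and P1→P10; models are ranked
ascending by the P1→P10 count (ties: P1→P4 count, then name). The
percentile filter is applied per model before counting — the workflow
default; it can be disabled (`pct = 0`), which matters when comparing
against published counts because a down-drifting transcript whose
baseline sits below the 20th percentile is removed by the filter before
it can be counted.

The **transition analysis** pairs each model's P0 (in vitro) samples with
its own P1 xenografts: per probe set, `FC = 2^(mean log2 P1 − mean log2
P0)`. Class-level tables average the member models' *linear* per-model
fold changes (not pooled samples), because each line is paired with its
own xenografts first. The two-block report shows the top-N list before
masking (annotated with mouse-sample counts) and the top N of the masked
full table — entries ranked below N pre-mask can enter the post-mask
block, which is why the report must be computed from the full ranked
table, not by filtering the pre-mask block.

## Enrichment statistics

`enrich_list()` reproduces the column semantics of a DAVID-style report:
the default p-value is the EASE score, the jackknifed Fisher exact test
`ease_p(k) = fisher_p(k − 1)` (an overlap of one is never significant);
`fold_enrichment = (k/n)/(K/N)`; `benjamini` is Benjamini–Hochberg over
the tested terms; and the FDR column is emitted as `benjamini × 100`.
Historical reports computed their FDR column differently (an empirical
variant), and annotation databases drift between versions, so numeric
agreement with any particular published enrichment table is explicitly
out of scope: the statistics, not a database snapshot, are the
deliverable. The background defaults to the union of all term members
and should be set to the array's mapped universe when available.

## Efficacy arithmetic

Tumor weight is taken as `length × width² / 2` (mm → mg), so a 10 × 10 mm
tumor is ~500 mg. `%T/C` per measurement day is `100 × median(treated
weights)/median(control weights)`; the *optimal* %T/C is the minimum over
days with both groups measured, and ≤40% (boundary inclusive) calls the
agent active. The median was chosen as the group summary because the
protocol randomizes on median tumor weight; the mean is a flag. Raw
animal-level data behind the published %T/C triplet (19/41/64) are not
public, so those exact values are demonstrated on synthetic series only,
labelled as such.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: per model, 3 P0 (in
vitro) replicates and 5 tumors at each of P1/P4/P10; `simulate_mouse_panel()`
produces the 5 × 3 mouse panel. The signal model, per probe set *j*:

* human log2 abundance `a_j ~ Normal(8, 2)`; control (`AFFX-`) sets get a
  fixed graded series (7 → 13), mimicking spike-in controls so that every
  good chip shows the same structured control profile;
* drifting sets in model *m* add `e_{m,j}(t)`, by default growing
  linearly over the in vivo passage index (about half the P1→P10 change
  present at P4, matching the observed kinetics for unstable models); a
  step-at-P4 onset is available;
* optional transition sets add a P0→P1 effect; optional signature sets
  add a constant ≥100-fold model-identity offset at all passages
  (default off — the null-calibration and recovery suites are defined on
  the shared-baseline cohort; switched on for co-clustering analyses);
* a sample with mouse fraction *f* has true signal
  `s = (1−f)·2^(a+e) + f·affinity_j·2^(a)`, where `affinity ∈ [0.3, 1]`
  on a random 10% of probe sets and 0 elsewhere; mouse "abundance"
  reuses the human prior because only detectability, not biology, is
  modeled;
* probe pairs measure `PM = s·2^eps + bg`, `MM = mm_leak·s·2^eps' + bg`
  with `eps ~ Normal(0, noise_sd)` (multiplicative log-normal noise) and
  `bg ~ Exponential(mean = background_mean)` — the standard microarray
  error structure. A pair's PM and MM share one background draw: chip
  background is spatially smooth, so the mismatch cell sees the same
  background as its perfect-match neighbour (the ideal-mismatch
  assumption). A zero-signal probe set then has R = 0 exactly and can
  never be called Present by noise alone.

Defaults: `noise_sd = 0.25`, `mm_leak = 0.3`, `mouse_fraction = 0.05`
for ordinary in vivo samples (the source workflow gives no quantitative
admixture level; a few percent is the scale at which stromal RNA is
reported in subcutaneous models), and `background_mean = 5`. The
background value was fixed by requiring that a 4-fold change remain
detectable at the 10th-percentile abundance (2^5.44 ≈ 43 units): additive
background compresses observed fold changes — down-regulation twice as
hard, since the denominator passage hits the floor first — and at bg ≈ 5
(≈2% of the median true signal, a realistic optical background) the
compression stays below the 3-fold counting threshold across the
abundance range. "Mouse outgrowth" models set `mouse_fraction = 1` for
P4/P10, reproducing the scenario in which late passages contain no human
tumor at all.

The generator writes a truth channel (drifting sets and effects,
transition effects, affinities, per-sample species mix, per-mouse-sample
expressed sets) sufficient to score sensitivity and false positives
downstream without re-deriving anything.

**What passing tests do and do not show.** The generator has no
probe-sequence thermodynamics, no spatial chip artifacts, no RNA
degradation gradients, and independent noise across probe sets (real
arrays share batch structure). Recovery of injected effects therefore
demonstrates the estimators' correctness, not field performance on real
chips; conversely the worked example shipped as a fixture exercises the
masking arithmetic on genuinely published numbers.

## QC design choices

* Control-probe QC replaces visual inspection with a correlation
  criterion: a sample is flagged when its control profile's Pearson
  correlation with the cohort-median control profile drops below 0.9
  (tunable; the source workflow does not state the criterion by which
  its one control-probe outlier was excluded).
* PCA outliers: samples as observations on mean-centered expression;
  flag when the robust z-score (median/MAD) of the distance from the
  centroid in the first 3 components exceeds 4. Invariant to adding a
  constant to all values. Cohorts of fewer than 3 samples are
  not-evaluable, never silently clean.
* Co-clustering uses the distance `1 − |Pearson r|` — the common reading
  of the "Pearson absolute" metric name — with centroid linkage, after
  a filter of percentile-20, unadjusted one-way ANOVA p < 0.05 across
  model × passage conditions, and a 100-fold range across condition
  means. Per-model purity is the fraction of the model's samples whose
  smallest enclosing subtree with at least the model's sample count is
  exactly that size and model-pure; single-sample models have purity 1.
* The species-composition score is the in-silico stand-in for a
  species-specific PCR assay: per sample,
  `mean rank of masked probe sets / (mean rank of masked + mean rank of
  unmasked)`. It is rank-based (so normalization-invariant), lies in
  [0, 1], is monotone in the generator's mouse fraction (property
  tested), and flags above 0.6 by default. An empty mask, or one
  covering every probe set, makes the score not-evaluable.

## Numerical choices and degenerate inputs

* Exact signed-rank p-values use integer generating-function
  convolution after doubling midranks; the exact/approximate crossover
  is 12 pairs.
* Median polish converges on the residual L1 criterion; an exactly
  additive block converges in ≤2 sweeps; single-probe sets pass through
  unchanged.
* Ranking tie-breaks are always explicit: stability (P1→P10 count, then
  P1→P4, then model name), expression ranking (mean, then model name),
  top-N lists (fold change, then probe-set id). Re-ranking after
  masking is 1..n on the retained list.
* Readers reject malformed input with located errors (row numbers, the
  offending label); writers refuse non-finite values; round trips are
  bit-identical for the intensity format and precision-preserving for
  expression matrices.
* Missing data contracts: a model missing a passage yields an error
  listing available passages (stability) or an NA delta (trajectory) —
  never a silent 0.

## Problem sizes

The shipped analyses and tests run on cohorts of 500 probe sets × 11
probe pairs, 3–5 models, and 15-array mouse panels — sizes chosen so the
full chain (simulation → RMA → calls → mask → stability → transition)
completes in seconds per cohort while leaving every statistic's sampling
behaviour visible. The stochastic suites use 20 independent seeds. The
same code paths scale to full 54k-probe-set arrays; the accession-scale
driver (`analysis/09_accession_check.R`) documents the parameter choices
for reproducing published per-model counts where the public expression
data are available.

## Known limitations

* No CEL parsing: the probe-intensity TSV dialect is the canonical raw
  format here; conversion from binary chip files is external.
* Additive background is not removed by default, so fold changes of
  low-abundance transcripts are compressed (see above); enable
  `background_method = "minimum-shift"` or background-correct upstream
  when absolute fold-change fidelity at the low end matters.
* The percentile filter removes down-drifting transcripts whose
  baseline is already below the 20th percentile (~10% of injected
  drift in the default synthetic conditions) — a property of the
  modeled workflow itself, not of this implementation.
* The cross-hybridization mask is purely empirical; it cannot flag a
  probe set no panel sample expressed. Sequence-based prediction is a
  non-goal.
* Enrichment results depend on the user-supplied annotation collection;
  no database ships with the package.
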