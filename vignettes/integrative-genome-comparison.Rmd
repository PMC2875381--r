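---
title: "Integrative genome comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative genome comparison: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igcomp)
```

This vignette is the package's own account of the statistical machinery it
implements: what each stage assumes, which tunable parameters matter and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open and a choice had to
be made.

## The scientific problem

Array-CGH measures relative DNA copy number as a log2 tumor/reference ratio
per probe. Given two clinically defined cohorts — here primary cutaneous
melanomas versus melanoma metastases — the question is which genomic regions
are *differentially* altered between the cohorts, and which resident genes
also show copy-driven expression changes. Alterations enriched in metastases
are candidate drivers of progression. The pipeline answers this with a chain
of classical tools: change-point segmentation, recurrence heuristics,
unsupervised subclassing, per-region exact tests with FDR control, and a
moderated t-like expression statistic.

## Segmentation (CBS)

Each chromosome of each sample is segmented by circular binary segmentation
in its basic form: the chromosome is treated as a circle, every arc `(i, j]`
is compared with its complement by a pooled two-sample t statistic, and the
maximizing arc is accepted as a split when its permutation p-value is at most
`alpha`. Accepted cuts are recursed into. Segment values are the *median* of
the spanned probes, which is robust to outlier probes. The arc scan is the
hot loop and is compiled (Rcpp); the permutation loop early-stops as soon as
the split can no longer be accepted at `alpha`, which makes null chromosomes
cheap. Refinements found in mature segmenters (undo-splits pruning, hybrid
p-value approximations) are deliberately omitted: the basic form has an
exactly checkable oracle — an exhaustive max-|t| recursion in plain R — and
the test suite holds the implementation to it within ±2 probes.

Parameters: `alpha` (default 0.01, log2-unitless significance), `n_perm`
(default 1000, at least 100; tests and benchmarks use 100, which resolves
p = 1/101 < 0.01), `min_width` (2 probes — a single-probe spike is not
trusted as a segment). Chromosomes with fewer than two probes become one
segment untested. Missing probe values are imputed from the flanking
non-missing probes before segmentation.

Degenerate inputs: a zero-variance arc/complement split with differing means
is treated as infinitely significant in the scan but still has to survive the
permutation reference, which on piecewise-constant noiseless data is an
honest combinatorial test — with very few probes the permutation p cannot go
below `alpha` and no split is made. This is why the unit tests of noiseless
recovery feed exact segmentations to the downstream callers rather than
asking CBS to resolve two-probe runs.

## Mode centering and thresholds

Tumor profiles have no absolute zero: the modal copy-number state is assumed
diploid and shifted to log2 = 0. The mode is found on a probe-weighted
histogram of segment values with 0.01-log2 bins *centered on multiples of
0.01*; ties break toward the bin nearest zero. Because every shift is then a
grid multiple, re-centering shifts by exactly zero — centering is idempotent
by construction, not approximately. Centering is per sample by default
(`per_sample = FALSE` gives a single global shift; the choice is exposed
because either reading of "centered by the tallest mode" is defensible, and
per-sample is the one that makes profiles comparable when labs or batches
shift baselines differently).

Calling thresholds default to the platform-calibrated fixed values: gain/loss
at ±0.15, amplification/deletion at ±0.4, extreme events at ±1.0, MCRs
capped below 2 Mb. `derive_thresholds()` re-derives the gain/loss cutoff as
six standard deviations of the middle 75% of the centered data (values
between the 12.5th and 87.5th percentiles — "middle 75%" is read as the
central 75% of the distribution, the interpretation under which 6 SD of
array noise lands near 0.15). The ±0.4 amplification cutoff is *not*
derived: the quantile prescription for it is ambiguous as printed
(asymmetric 4%/94% quantiles), so the fixed value is kept. Degenerate
zero-variance input falls back to the fixed defaults with a warning. All
boundaries are inclusive, and the extreme states imply the milder ones
(an amplification is also a gain) — `state_direction()` collapses to the
three-level gain/loss/neutral calls used by the Fisher stage.

## MCR calling

A sample's CNA intervals are maximal runs of adjacent same-direction altered
segments. Per direction, per-probe recurrence is the number of samples whose
intervals cover the probe; candidate regions are maximal probe runs with
recurrence ≥ 2, and the MCR is the *maximal-recurrence plateau* within a
candidate. The plateau rule is one of several defensible readings of
"minimal common region"; it was chosen because it is deterministic and
oracle-checkable, and on noiseless planted data it provably returns the
intersection of the planted intervals. When a plateau is discontiguous, each
contiguous piece becomes its own MCR (both sub-peaks are reported rather
than arbitrarily picking one); `mode = "envelope"` widens to the whole
recurrence ≥ 2 run for users who prefer inclusive regions. High-confidence
filtering then requires an extreme event (|log2| ≥ 1 in at least one sample,
in direction) and width < 2 Mb. `n_tumors` is the plateau recurrence — the
count of samples at the shared core, not any-overlap — which matches the
"minimal" reading; this is flagged because a table built under the
any-overlap count would differ.

All intervals in the package are half-open `[start, end)` with
`width = end − start`; an MCR's end bound is the position of the first probe
beyond the plateau (chromosome end: last probe + 1). Under this convention
the packaged table transcriptions satisfy `width = end − start` exactly,
row by row.

## gNMF subclassing

The segmented cohort is collapsed to non-redundant columns (consecutive
probes identical across all samples), split into non-negative gain
(`max(x, 0)`) and loss (`max(−x, 0)`) channels — preserving sign information
without shifting, which a global offset would distort — and factorized by
KL-divergence multiplicative updates from seeded uniform starts. Samples are
clustered by their largest factor weight; restarts are aggregated into a
consensus matrix whose entries are co-clustering frequencies (exact
multiples of 1/`n_runs`); final assignments come from average-linkage
hierarchical clustering of 1 − consensus, and the cophenetic correlation
between consensus distances and the dendrogram measures rank stability. The
orientation (samples × features, cluster from W) and the
cluster-from-consensus rule are stated choices where the lineage of
consensus-NMF implementations varies. The stopping rule is connectivity
stability: iteration ends when sample assignments have not changed for 40
consecutive checks (checked every 10 iterations) or at `max_iter`.

Significance of a chosen rank is assessed by permuting, independently for
each chromosome, which sample owns each chromosome-profile — destroying
cross-chromosome co-segregation while preserving every chromosome's marginal
profile set — and recomputing the cophenetic correlation per permutation;
the empirical p is `(1 + #{null ≥ observed}) / (n_perm + 1)`. A
single-chromosome input degenerates to a whole-profile shuffle and warns.

## Cohort comparison (the core statistic)

All samples' breakpoints are pooled per chromosome; the intervals between
consecutive union breakpoints are R-segments, on which every sample is
constant by construction (the count identity #R-segments = #distinct
breakpoints + #chromosomes is asserted in tests). Per R-segment and
direction, samples are cross-tabulated cohort × altered/normal, excluding
samples altered in the *opposite* direction (a lost sample is neither gained
nor informatively normal for the gain test). A direction is tested only if
at least one sample in either cohort carries it — "above noise threshold" is
read as this minimal-information condition, which also defines the
multiple-testing family. The two-sided p is Fisher's exact
(minimum-likelihood convention, `stats::fisher.test`), cross-checked in the
suite against full hypergeometric enumeration.

q-values follow Storey: pi0 estimated on the lambda grid 0–0.90 (step 0.05)
with a cubic smoothing spline extrapolated to lambda = 1; with fewer than
100 p-values pi0 is pinned at 1, reducing the estimator to
Benjamini–Hochberg (small families cannot support a pi0 fit). Gains and
losses are corrected as one family by default — one FDR is reported for the
analysis — with a per-direction switch. Significant same-direction
R-segments that are consecutive in the partition merge into ROIs; merging
never crosses chromosomes.

## Expression integration (SAM)

Probes are "deemed expressed" when above `floor` (default `log2(100)`, a
MAS5-scale convention — the criterion is unspecified upstream and exposed as
an assumption) in at least `min_fraction = 0.25` of samples, and must lie
inside a significant ROI. The SAM statistic is d = (mean₂ − mean₁)/(s + s₀)
with s the pooled-scatter standard error and s₀ chosen by Tusher's
percentile search (minimizing the coefficient of variation of windowed
MAD(d) across the range of s); `s0_mode = "median"` is the fallback for
matrices too small to window, and an explicit `s0` can be forced. q-values
come from group-label permutations of |d| with a pi0 estimated from the
central half of the permuted distribution, monotonized so a larger |d| never
gets a larger q. Relative expression is the ratio of *unlogged* group means
(the reading under which a printed "Rel Exp ≥ 2" is a linear fold; a ratio
of medians is the plausible alternative and would differ for skewed genes).
Candidate selection keeps overexpressed records (d > 0) at q ≤ 0.05 and
fold ≥ 2, deduplicates per gene by the max-fold probe, and ranks by fold.

## The synthetic-data generator

`simulate_cohorts()` emulates the study design: two cohorts (default 25
primary, 61 metastatic), ~16,097 probes over autosomes 1–22 with exponential
inter-probe gaps of median 54.8 kb, planted events carried independently per
sample (Bernoulli at the cohort's frequency) whose amplitudes sum in log2
space, Gaussian probe noise (default SD 0.12 log2), and dosage-driven
expression `baseline + slope × copy + noise` on the log2 scale. It does
**not** emulate dye-swap or wave artifacts, whole-genome-amplification bias,
probe-specific variance, correlated noise, or subclonal (fractional)
amplitudes — so passing benchmarks demonstrate that the statistical
machinery recovers clean planted structure at realistic noise, not that it
is robust to every artifact of real arrays. Independent Bernoulli carriage
is the simplest exchangeable model; overlap-additivity keeps the truth
table linearly reconstructible, and the noiseless simulation is bit-exactly
the sum of its truth rows (asserted in tests). Identical seeds give
bit-identical cohorts; every randomized stage takes an explicit seed.

## Benchmarks and problem sizes

Two seeded benchmarks back the acceptance script. The *enrichment recovery*
experiment plants three metastasis-enriched gains (carriage 0.50 vs 0.04) of
1.2–1.5 Mb and amplitudes 0.6–1.1 log2 on chromosomes 1, 7 and 17 — the
chromosomes where melanoma progression gains concentrate — in 25 vs 61
samples on 2,000 probes at noise 0.12, and scores over 20 independent seeds
how often at least two of the three planted regions are recovered as gain
ROIs at q ≤ 0.1 and what fraction of significant R-segments are false. The
*subclass rank* benchmark builds 30 metastatic profiles in three planted
subclasses (broad-gain, mixed gain/loss, hypoploidy-like patterns; carriage
0.9, segment jitter 0.1) and checks that the consensus cophenetic
correlation prefers rank 3 over rank 4 at 50 restarts and that assignments
match the planted labels. These sizes — 2,000 probes rather than 16,097,
100 CBS permutations, 50 restarts — are the package's chosen desk-scale
conditions; they keep a full benchmark run in the low minutes on one CPU
while leaving every statistical property intact.

The original cohort's headline counts (thousands of R-segments, the exact
numbers of significant segments, ROIs and candidate genes, the cohort
instability p-value) depend on the deposited raw profiles and the original
platform annotation and are not desk-reproducible; the packaged table
fixtures carry the published summary arithmetic, and the property suites
(calibration, reconstruction, symmetry) cover the machinery those counts
came from.

## Known limitations

- CBS here is the basic Olshen form; very long chromosomes with many weak
  change-points will segment differently from refined implementations.
- The pi0 spline can be unstable for families of a few hundred p-values with
  strong signal; the BH fallback below 100 tests is deliberately
  conservative.
- SAM q-values use the symmetric |d| convention; a one-sided variant would
  be slightly more powerful for a purely overexpression-focused question.
- Cytoband naming is pass-through only; no liftover is attempted, and the
  packaged fixture coordinates are used verbatim on their original build.
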