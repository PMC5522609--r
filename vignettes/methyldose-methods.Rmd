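---
title: "methyldose: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methyldose: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methyldose)
```

## Scope and data model

methyldose analyses dose-structured whole-genome bisulfite experiments:
a control group and two treated groups (doses expressed as percent of a
field application rate, 0/5/10 by convention), each with four biological
replicates. The unit of data is the per-cytosine count record
(chromosome, 1-based position, strand, CG/CHG/CHH context, methylated and
unmethylated call counts), read from either Bismark dialect. Genomic
*intervals* (DMRs, features) are 0-based half-open internally, matching
BED; *sites* stay 1-based, matching the Bismark reports. GFF input is
shifted accordingly on read.

Symmetric CpG sites on opposite strands are **not** merged: destranding is
lossy and no single convention dominates, so both strand records are kept
and treated as separate sites throughout. Context is taken from the report
when present; coverage (.cov) files carry neither strand nor context, so
both are derived from the reference FASTA (`classify_contexts()`), refusing
to guess when the reference base is not C/G and dropping sites whose
context window runs off the contig end.

Bisulfite conversion efficiency is estimated as one pooled ratio of
methylated calls on a contig known to be unmethylated (the chloroplast in
the motivating experiments; the `ctrl` contig in simulations). This pooled
estimator is the maximum-likelihood binomial estimate and is unbiased; it
is reported, not subtracted from the counts, because downstream testing is
between-group and a shared non-conversion offset cancels to first order.

## Per-site differential testing

Replicates are pooled within each group after median normalisation: each
sample's counts are scaled by (median of all samples' median coverages) /
(its own median coverage), rounded half away from zero. Rounding half-up
keeps each site's methylation ratio unchanged to within one count.
Pooling replicates for a Fisher's exact test is the classic two-group
treatment; a per-replicate regression mode is deliberately out of scope.

Each site with pooled coverage of at least 4 in both groups is tested with
the two-sided Fisher's exact test (sum of hypergeometric point
probabilities not exceeding the observed one, with the standard
`1 + 1e-7` tolerance factor against floating-point ties). Multiple testing
uses Benjamini–Hochberg; the original toolchain's q-value procedure is
unspecified, and BH is monotone, assumption-light and reproducible.
Retained DmCs satisfy |Δ| ≥ `min_diff` (25 percentage points) and
*q* < 0.01, and are then ranked by *q* ascending — ties broken by |Δ|
descending, then position — and truncated to the top
`top_confidence_fraction` (default 0.25). "Highest confidence" has no
published definition; lowest-q-quartile-of-passing-sites is the reading
implemented, and both the fraction and the ranking are parameters.

Under a global null this pipeline is strongly conservative: with ~20,000
sites and BH at 0.01, the expected fraction of sites with *q* < 0.01 is
well under 1% (empirically ~0 in the test suite's ten-seed check).

## DMR construction

Two callers are provided and intersected.

**Merging caller.** Consecutive same-direction DmCs at most `max_gap` bp
apart merge into a region; regions need `min_dmcs` ≥ 3 sites and |mean Δ| ≥
10 points. `max_gap = "auto"` fits a two-component Gaussian mixture
(mclust, unequal variances) to log10 inter-DmC distances — within-region
and between-region spacings form the two modes — and uses the density
antimode between the component means; with fewer than two distances or a
degenerate fit it falls back to 100 bp with a warning. This caller is a
transparent distance-merging reimplementation, not a clone of any
published weighted-optimisation algorithm.

**Smoothing caller.** Per sample, context and contig, each site's level is
a tricube-kernel weighted binomial mean over sites within
`bandwidth_bp`, kernel weights multiplied by coverage; windows with fewer
than `min_sites_in_window` (5) sites widen symmetrically by nearest
neighbours. Per shared site, a pooled-variance two-sample *t* statistic
compares the replicate smoothed values of the two groups (zero pooled
variance gives *t* = 0 with no region contribution). Cutoffs are the
empirical `q` and `1 − q` quantiles of all *t* values
(`t_cutoff_quantile`, default 0.015); candidate regions are maximal
same-sign beyond-cutoff runs, kept when they have ≥ `min_sites_per_dmr`
(3) sites and |areaStat| = |Σ*t*| ≥ `area_stat_min` (10).

The smoothing defaults are calibrated to the synthetic genome the package
ships: cytosine density there (~0.5 sites/bp across contexts) is far
higher than in a real plant genome and planted regions are 200–1000 bp, so
`bandwidth_bp = 100` keeps a region's own sites dominant in its window;
500 bp smoothing would average a short region into its flanks and roughly
halve recall. On real data with sparser CG tracks, users should widen the
bandwidth toward the few-hundred-bp scale and revisit
`t_cutoff_quantile`; all five knobs are exposed in `smooth_params()`. With
the defaults, planted-region recovery in the test suite attains mean
recall ≈ 0.97 and mean interval-level false discovery ≈ 0.07 over five
simulation seeds.

**Reconciliation and intersection.** Overlap semantics everywhere are ≥ 1
bp on half-open intervals. Regions from the two doses that overlap with
opposite directions are direction conflicts and both are removed
outright — mirroring the exclusion of direction-conflicting regions in
dose-paired designs; same-direction overlaps become one shared region over
the interval *union* (so per-dose statistics are computable on a common
span); the rest are dose-unique. High-confidence regions are
smoothing-caller regions overlapped by a same-direction merging-caller
region.

**Replicate stability.** `replicate_stability()` reruns a caller on every
pair of k-replicate subsets (36 combinations at k = 2, 16 at k = 3, 1 at
k = 4) to expose parameter stringency: lenient cutoffs inflate
two-replicate call counts, stringent cutoffs flatten the curve. For the
smoothing caller each replicate is smoothed once and reused.

## Dose-response classification

For each shared region, per-replicate coverage-weighted mean methylation
(percent, over the region's member sites of its context) is computed at
each dose, and the control-group grand mean subtracted, giving replicate
vectors Δ₅ and Δ₁₀. A pooled-variance Student's *t*-test at α = 0.05
compares them (Welch is available via `var_equal = FALSE`; Student's is
the default because equal-variance replicate groups are the design
assumption). Non-rejection → dose-independent; rejection with
|mean Δ₁₀| > |mean Δ₅| → positive dose-dependent; the reverse → inverse.
Absolute values unify the hyper- and hypomethylated cases. Degenerate
zero-variance inputs are classified by direct magnitude comparison; fewer
than two usable replicates per dose → unclassified. Regions unique to one
dose need no test: 10%-only regions are tentatively positive, 5%-only
regions tentatively inverse.

As a descriptive layer, for each significant side of the Δ₁₀-vs-Δ₅
scatter both a line through the origin and a quadratic through the origin
are fitted by least squares and compared by AIC and BIC; the quadratic is
retained as the boundary only when both criteria prefer it. The curve
family is a package choice (no published functional form exists); the
*t*-test, not the curve, assigns classes. Sides with fewer than 5 points
are skipped.

Exchanging the dose-5 and dose-10 sample sets maps positive ↔ inverse and
fixes independent — this symmetry is exact and tested.

## Annotation, enrichment, overlap statistics

A DMR associates with a feature when the gap between closest interval
edges is ≤ 2000 bp, boundary inclusive, overlap counting as gap 0; strand
is ignored and all many-to-many pairs are kept. Term enrichment is the
hypergeometric upper tail P(X ≥ k) with the normalized frequency
(k/n)/(K/N) required to exceed 1.5; no multiple-testing correction is
applied across terms, deliberately matching the practice the pipeline
mirrors — treat the term lists as exploratory.

Cross-stress overlap statistics operate on gene-id sets: expected pairwise
overlap under random placement is `round(nA/N × nB)` (half away from
zero — base R's round-half-even would disagree with conventionally rounded
integers); the three-way expectation scales the rounded pairwise
expectation by nC/N. Independence is tested on the 2×2 presence/absence
table with Pearson's χ², *no* Yates correction — the uncorrected statistic
is what published two-digit values reproduce. Degenerate tables (an empty
set, or a set spanning the whole universe) yield NA in the pipeline
report rather than an error. A permutation oracle
(`permutation_overlap_null()`) backs both the expectation and the test in
the suite.

## The synthetic methylome

The generator emulates the motivating study design: 3 doses × 4
replicates; mean coverage 60× (negative binomial, size 10), inside the
48–76× range reported for the real libraries; CG/CHG/CHH beta baselines
(α, β) = (0.6, 1.4), (0.3, 2.7), (0.2, 3.8) reproducing the plant ordering
CG > CHG > CHH with means 0.30/0.10/0.05; a 0.5% non-conversion rate
applied as level + (1 − level)·rate genome-wide; and an unmethylated
control contig. Planted DMRs (default 4 per dose class, 200–1000 bp, ≥ 5
sites of one context) shift the latent level by ±0.5 at the reference
dose, with the dose-5/dose-10 ratio encoding the class: equal shifts =
independent, half at 5% = positive, half at 10% = inverse; shifts clamp to
[0, 1], so regions planted near saturation realise smaller effects — a
deliberate, realistic censoring.

The count model draws one latent level per site (beta across sites) and
binomial counts given coverage; replicate variation enters through
coverage and binomial noise. A beta-binomial per-replicate dispersion knob
(`replicate_dispersion`) exists but defaults to off: the simpler model
suffices for planted-effect recovery and keeps the null cleanly calibrated.
What the generator does **not** model: read-level errors, mapping bias,
PCR duplicates, chromatin-correlated methylation autocorrelation beyond
the planted regions, TE/gene sequence structure (the synthetic annotation
places features uniformly), or inter-replicate biological heterogeneity.
Passing recovery tests therefore demonstrates algorithmic correctness at
realistic depth and effect sizes, not performance on real tissue data.

All randomness derives from one integer seed through fixed per-operation
sub-streams, so every module and the full pipeline are byte-reproducible.

## Problem sizes and numerical choices

The test suite runs the generator at 2 × 20 kb nuclear contigs plus a 4 kb
control (~22,000 cytosine sites, 12 samples) for calling checks, and
1 × 6–10 kb for unit fixtures — sizes chosen so the whole suite exercises
every stage end to end in a few minutes on one core while keeping ≥ 5
sites in every planted region. Exact-arithmetic oracles (hypergeometric
enumeration up to table total 40, BH by hand, closed-form χ²) are frozen
in the tests; Monte-Carlo comparisons use 3–4 standard errors.

Ties and degenerate inputs: equal smoothed variance gives t = 0; equal
|Δ₅| and |Δ₁₀| with a significant test falls back to independent; empty
inputs return typed empty tables rather than errors wherever the empty
result is meaningful, and errors name the offending site or stage
otherwise.

## Known limitations

* The merging caller is a distance heuristic; its auto-gap mixture needs
  clearly bimodal spacings to be better than the 100 bp fallback.
* The smoothing caller's quantile cutoffs adapt to the data at hand; on a
  genome where a large fraction of sites is truly differential, the
  cutoffs shift and recall degrades — cutoffs by fixed |t| would be the
  escape hatch.
* Dose classes for dose-unique regions are tentative by construction
  (no second dose to test against).
* The enrichment layer does not traverse an ontology graph; terms are
  independent labels.
* Three-way set independence is summarised pairwise by default; a 2×2×2
  mutual-independence test (df = 4) is available behind the `three_way`
  flag of `overlap_report()`, but there is no canonical construction for
  such a table and other formulations give different statistics.
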