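---
title: "Co-expressed pathway prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expressed pathway prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexPath)
```

# The problem

Co-expression — similarity of expression profiles across many conditions — is
a long-standing proxy for functional relatedness. Most co-expression
resources only report the pathways enriched among a gene's *strongly*
co-expressed neighbours (an over-representation analysis at one arbitrary
cutoff). coexPath implements a ranking scheme that also uses the rest of the
ranked list (via unweighted GSEA with exact p-values) and corrects the
systematic bias both tests inherit from *internal correlation* within
pathways, via a per-pathway percentile score. This vignette documents the
statistical model, every tunable parameter, and the design decisions that
were genuinely open.

# Preprocessing

Starting from a gene × sample matrix of non-negative expression units (TPM in
the intended use), the `CoexMatrix` container tracks a `stage` tag so that
each step sees the input it assumes:

* **Depth filter** (`filterSamplesByDepth`, default cutoff 10⁶ total
  estimated counts): shallow libraries produce noisy TPM profiles that
  corrupt correlations. Totals come from quantification, not from the TPM
  matrix, so they are passed explicitly.
* **Quantile normalization** (`quantileNormalize`): forces all samples onto
  the common distribution given by the across-sample mean of order
  statistics. Ties within a sample receive the mean of the reference values
  over their rank span, so tied inputs stay tied — the conventional tie
  policy of the widely used implementations. Caveat: because it removes
  per-sample distributional shifts, quantile normalization attenuates the
  correlation of a co-expressed block in proportion to the fraction of the
  panel the block occupies; at realistic scale (pathways ≤ 3% of measured
  genes) the effect is minor, but on tiny panels it is visible.
* **Log transform** (`logTransform`, pseudo-count 4): log2(x + 4) damps the
  log-scale variance of weakly expressed genes while preserving order. The
  pseudo-count is a convention of the pipeline this package reimplements; it
  only matters relative to the scale of the expression unit.
* **Correlation** (`correlationMatrix`): Pearson correlation of logged
  profiles, requiring ≥ 3 samples. Zero-variance genes have no defined
  correlation; they raise an error naming the offending genes rather than
  propagating NaN into ranked lists — the caller decides whether to drop
  them. `upgmaDendrogram` (average linkage on 1 − Pearson between sample
  profiles; the distance is our choice, consistent with the package's
  correlation machinery) gives the usual visual check that samples group by
  biology.

# Ranked lists and ORA

`rankedGeneList` orders all genes except the target by decreasing correlation
with it; ties are broken lexicographically by gene id (C locale) so results
are identical across platforms. `oraProfile` tests the top-N genes for each
N ∈ {100, 500, 1000, 1500, 2000, 2500, 3000} against each pathway with the
one-sided (enrichment) Fisher's exact test. Two contract decisions:

* **Background universe** = the n genes of the ranked list itself. The
  sampling frame from which the top-N are drawn is exactly those n genes, so
  any other background would break the 2 × 2 margins.
* **The target gene is excluded from pathway membership counts**: it can
  never appear among its own selected genes, so counting it would inflate K.

Pathways with fewer than 15 or more than 500 measurable members are dropped
(`filterPathways`); sizes are counted *after* intersecting with the measured
universe, because the downstream statistics only ever see measurable genes.
No multiple-testing correction is applied: the method ranks pathways by raw
p-values within a gene, it does not make accept/reject calls.

# Unweighted GSEA with exact permutation p-values

For pathway S with m members among the n ranked genes, the running sum steps
by +1/m at members and −1/(n−m) at non-members; the enrichment score is the
signed maximum deviation, with the smallest maximizing position reported.
All running-sum arithmetic is performed on integers: rescaling by m(n−m)
turns the steps into +(n−m) and −m, so prefix sums, the maximum and the
p-value threshold are exact — there are no floating-point comparisons
anywhere in the test. The final prefix is asserted to be zero on every
evaluation.

Two conventions resolve genuine ambiguities in the score definition:

* **Sign ties.** If the maximal |prefix| is attained with both signs, the
  positive sign wins. The argmax in the textbook definition is ambiguous
  under ties, and top-enrichment is the object of interest.
* **Negative scores.** p = 1 whenever ES ≤ 0. Enrichment at the bottom of a
  co-expression ranking (strong *negative* co-expression) is not evidence of
  shared pathway membership for this application.

## The null and the dynamic programme

The null places the m members uniformly at random among the n positions (a
gene-permutation null; sample permutation is meaningless here because the
"phenotype" is the target gene, not a sample covariate). The p-value is

p = Pr(max_k prefix_k ≥ T),  T = ES⁺ · m(n−m) (an integer).

`exactPositivePvalue` counts the arrangements whose every prefix stays ≤ T−1
with the lattice-path recurrence f[j][h] = [h·n − j·m ≤ T−1]·(f[j−1][h−1] +
f[j−1][h]), and returns 1 − count/C(n,m). Counts reach C(n,m), far beyond
2⁵³, so the DP rows hold little-endian base-2³² big integers (addition is the
only operation needed); the final ratio uses the top 96 bits of each operand,
giving ≤ 10⁻¹⁵ relative error. C(n,m) is obtained from the same DP with the
constraint disabled and cached per (n, m). Complexity is O(n·m) additions
with two rolling rows. One subtlety: the null statistic is the
*unconditional* maximum prefix over all arrangements, not a maximum
conditioned on arrangements whose two-sided score is positive. Every
arrangement's maximum prefix is ≥ 0 (the total sum is zero), so the two
readings coincide except exactly at T = 0, where we return p = 1 — consistent
with the non-positive-score convention.

# The percentile (p-)score

Internal correlation — the mean pairwise correlation among a pathway's
members (`internalCorrelation`) — inflates both ORA and GSEA significance for
genes *outside* the pathway: a cohesive block travels together through every
ranked list, so it is always either jointly near the top or jointly near the
bottom. `inflationDiagnostic` quantifies this as the correlation, across
pathways, between internal correlation and the mean −log10 p over non-member
genes.

The correction re-expresses a gene's ES as a percentile of the pathway's own
*observed* ES distribution across all target genes of the corpus:
`fitKde` models that distribution as a Gaussian mixture with one component
per observed value and a single Silverman rule-of-thumb bandwidth
h = 0.9·min(sd, IQR/1.34)·N^(−1/5) (type-7 quartiles — the default of R's
`density()`, the environment in which the approach was developed; identical
values are an error since the bandwidth would be zero, in which case an
empirical-CDF percentile is the documented fallback). `pScore` is the exact
closed-form survival of the mixture, (1/N) Σ Φ̄((ES_e − c_i)/h) — no grid
integration, so it is both exact and fast, and strictly decreasing in ES_e.

Member genes' ES values are deliberately *included* in the observed
distribution: the corpus pools all ranked lists, and excluding members would
require the annotation being predicted. Users can subset the GSEA table
before `collectEsDistribution` if they want the alternative.

One structural fact worth knowing: the signed max-deviation statistic is
bounded away from zero (a random walk's largest excursion is never tiny), so
every observed ES distribution has an empty gap straddling 0. Consequently
the distribution of p-scores over genes, while close to uniform and — the
property that matters — nearly identical across pathways of very different
cohesion, is systematically thin in the decile where the survival function
crosses that gap, and kernel smoothing slightly thins the extreme deciles.
The tests assert exactly this shape rather than strict uniformity.

# Combined ranking and ROC evaluation

`combinedPathwayRanking` orders pathways by (ORA top-500 p ascending, p-score
ascending, set id) — the ORA threshold that performs best, with the p-score
breaking the wide ties created when the top-500 contains no member of a
pathway at all (those pathways share p = 1, and the p-score is defined for
every pair). The ranking is total, deterministic and invariant to input
order.

`rocAuc` labels gene–pathway pairs condition positive iff the gene is an
annotated member, sweeps thresholds over distinct scores, and returns the
trapezoidal AUC (ties count one half, so constant scores give 0.5 —
numerically identical to the Mann–Whitney pairwise formulation, which the
tests verify exactly). Two modes mirror the two natural evaluations: pooled
p-values across all pairs, and pooled per-gene pathway *ranks* (rank 1 =
strongest), which evaluates the ranking a user actually sees. Pooling (vs
averaging per-gene curves) is our choice for the p-value mode.

# The synthetic corpus generator

`simulateDataset` draws gene profiles from a multivariate normal with
block-exchangeable correlation: genes in planted block p share pairwise
correlation ρ_p, everything else shares ρ₀ (default 0), via the one-factor
construction z_i = √ρ₀·G + √(ρ_p−ρ₀)·B_p + √(1−ρ_p)·ε_i. This is the
simplest structure whose single knob is exactly the diagnostic quantity
(internal correlation). Values are mapped to expression units as
max(0, 10 + 2·z) — baseline 10 and noise sd 2 keep essentially all values
positive while leaving quantile normalization and log2(x + 4) meaningful.
The generator emulates: a compendium-scale correlation structure, planted
pathways of controlled size and cohesion, and a matching truth GMT. It does
*not* emulate count-level RNA-seq realism (negative-binomial noise, library
size, zero inflation), tissue structure among samples, overlapping pathways,
or correlated-but-unannotated modules — so passing tests demonstrate the
statistical machinery and its calibration, not robustness to all properties
of real data. Positive semi-definiteness requires ρ₀ ≤ min ρ_p < 1, which is
validated before sampling; the seed is mandatory and the global RNG state is
restored afterwards.

# Problem sizes and numerical tolerances used in the tests

* Exact-DP and Fisher oracles: exhaustive enumeration for all n ≤ 12 (every
  m, every achievable threshold), compared at 10⁻¹⁵/10⁻¹² relative error —
  i.e. exactly, at double precision.
* KDE survival vs adaptive numerical integration: 100 random mixtures,
  agreement within 10⁻⁸.
* Calibration and recovery experiments: corpora of 1,000 genes × 50 samples
  with 30-gene planted blocks, 20 seeds each — one cohesive block (ρ = 0.7)
  among nine decoys for rank-1 recovery of the planted pathway, and a
  ρ = 0.8 vs ρ = 0.1 pair for the inflation diagnostic (GSEA −log10 p
  inflated for the cohesive block in every seed, while non-member p-score
  means stay in [0.4, 0.6]). The generator's Monte-Carlo checks (empirical
  within-block correlation within ±0.05 of ρ) are asserted on its raw
  output, since that is the generative parameter.
* Correlation matrices are checked against a two-pass Pearson oracle at
  10⁻¹⁰ on random 20 × 10 matrices.

# Known limitations

* Exact p-values get coarse, not wrong, for very small m; for very large
  ranked lists the O(n·m) DP per pathway is the dominant cost (it is linear
  in both, with big-integer words ∝ n/32).
* The p-score calibrates each pathway against its own observed distribution;
  it cannot create signal where GSEA sees none, and for pathways whose
  observed distribution is dominated by their own members (tiny corpora) the
  percentile is conservative.
* Quantile normalization assumes most genes are not co-regulated; on panels
  where planted/true modules are a large fraction of all genes it shrinks
  their internal correlation noticeably (see Preprocessing).
* The intended expression unit is within-sample-normalized abundance (TPM);
  raw counts should be converted first, and the depth filter needs the
  quantification totals.
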