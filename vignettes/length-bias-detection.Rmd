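---
title: "Detecting gene-length-dependent expression trends against a baseline null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-length-dependent expression trends against a baseline null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longtrend)
```

## The problem

Running-average plots — windowed means of per-gene log2 fold change
plotted against gene length — have repeatedly been read as evidence that
genes longer than 100 kb are preferentially misregulated, notably in
MeCP2 loss- and gain-of-function models. The difficulty is that such a
curve has no intrinsic scale: amplification-based expression platforms
carry technical variation that is itself length-dependent, so the
comparison of two sets of *control* samples also produces a bending
curve. A trend is only evidence of biology if it exceeds what the
controls do to each other. `longtrend` packages that decision procedure
together with a simulator rich enough to exercise every part of it.

## The statistical procedure

**Windowing.** Genes are restricted to lengths in
[`min_length`, `max_length`] (defaults 1 kb, 1000 kb — very short genes
are poorly measured and the sparse extreme tail would dominate otherwise),
sorted by (length, gene id), and covered by windows of `bin_size = 200`
consecutive genes stepping by `shift = 40`, so adjacent windows share 160
genes. Trailing genes that do not fill a complete window are dropped by
default (`keep_partial = FALSE`): complete windows keep the per-bin n
constant at 200, which the per-bin test assumes; the option exists because
the convention is not forced by anything deeper. Ties in length are broken
by gene id in byte order, making the binning deterministic across sessions
and locales.

**Curves.** Each window contributes the arithmetic mean and sample SD
(n − 1) of its members' log2 fold changes and its mean gene length. For
display, ribbons of mean ± 0.5 SD are drawn (half of one standard
deviation on each side keeps overlapping ribbons legible; mean ± 1.96 SD
gives the conventional 95% band and is available through the same
function).

**Fold changes.** On counts,
`log2((mean(group1) + 1)/(mean(group2) + 1))` — the pseudocount of 1
keeps zeros finite and is configurable. On log2-scale (array-style) data,
the difference of group means of log2 values; the two conventions agree
in the limit of vanishing pseudocount on strictly positive data, which is
tested. Arrays are probe-collapsed by averaging log2 values per gene;
collapsing raw counts is refused because averaging counts across features
has no coherent unit.

**The overlap test.** The signal comparison (case vs control) and the
baseline comparison (two disjoint random subsets of controls, built by
`split_controls()`) are windowed on their shared gene universe so bins
match gene-for-gene. In each window a two-sided pooled-variance Student
t test (df = 398) compares the 200 signal values with the 200 baseline
values; a Welch variant is available but the pooled test is the default
since the two samples are the same genes under two contrasts and have
similar spread. P-values are Benjamini–Hochberg adjusted across the
windows of one analysis (not across analyses), and windows with q < 0.05
are flagged. The reported "threshold line" is the largest raw p among
flagged windows, `NA` when nothing is flagged.

Two properties make this the right test for the question:

* *Shared distortion cancels.* A length-dependent multiplicative bias
  present in both comparisons shifts both window distributions equally;
  the t statistic is invariant to a common shift, so the curves bend but
  nothing is flagged. This is verified by simulation (shared ramp of 0.3
  log2 units bends both curves by ~0.1 in long-gene windows while the
  flagged fraction stays at the null level).
* *Genuine signal is detected.* An effect confined to long genes of the
  case group moves only the signal windows; with a −0.58 log2 effect
  (~50% down) every long-gene window is flagged even at 5 replicates per
  group.

**Calibration caveat.** Windows overlap, so within one dataset the 119
window p-values are strongly correlated; type-I calibration holds on
average across experiments, not per experiment. The averaged fraction of
windows with raw p < 0.05 under the null simulation is 0.05 (checked over
200 replicates at n = 10/group, 5000 genes, depth 2×10⁶ — sizes chosen so
the suite completes in about a minute while leaving Monte-Carlo error
well inside the asserted band).

**A property worth knowing.** With 200 genes per window the t test
resolves shifts of a few hundredths of a log2 unit. When a large fraction
of the transcriptome is genuinely repressed, global normalization
re-inflates the remainder, and that compositional counter-shift in short
genes is itself statistically significant. This is correct behavior — the
short-gene windows really do differ from baseline — but it means "which
windows are flagged" should be read jointly with the curve levels.

## Titration β ratio

For reference mixtures C = 0.75A + 0.25B and D = 0.25A + 0.75B,
β = (B − A)/(C − A) equals 4 for every gene with B ≠ A, independent of
expression level; log2 β = 2. Genes with |C − A| ≤ ε·max(A, B, 1)
(ε = 10⁻⁶) or β ≤ 0 are flagged rather than silently dropped — sampling
noise near B ≈ A makes the ratio unstable and published analyses
never specify a convention, so exclusions are counted and reported. β is
computed on replicate means of normalized expression (median-of-ratios by
default, configurable), and the length-binned β curve uses the same
windowing machinery as the fold-change curves.

One algebraic fact shaped the simulator: a distortion b(L) applied
*identically* to all four sample types cancels exactly in β
((bB − bA)/(bC − bA) = β), so a shared amplification bias can never move
the β curve. The observed long-gene overestimation of β in real titration
data therefore implies type- or batch-specific distortion. The generator
models this by placing the length ramp on the brain reference B (the
profile richest in long transcripts), which reproduces the
direction seen in real titration data: β overestimated at long genes, surviving all
three normalizations. Normalization absorbs the global component of the
distortion, so the robust statistic is the long-minus-short contrast of
the β curve, which is what the tests assert.

## Normalization

Three between-sample methods, each a per-sample division:

* *Total count*: factor = library size / mean library size, so all
  normalized columns sum to the mean of the original library sizes
  (any common target is admissible; the mean keeps values on the
  original scale).
* *Median of ratios*: factor = median over all-positive genes of
  count / per-gene geometric mean. The estimator's fixed point is exact:
  the median ratio of normalized counts to the raw-count pseudo-reference
  is 1 per sample. No geometric-mean rescaling is applied, so the factors
  coincide with the DESeq2 estimator, against which they are tested.
* *TMM*: M and A values against a reference column (the one whose upper
  quartile of scaled counts is closest to the mean upper quartile), genes
  with zeros excluded, 30%/5% two-sided trims on M and A, and a
  precision-weighted mean of retained M values. The matrix is divided by
  effective-library size factors (TMM factor × library size, geometric
  mean 1), so a sample that is an exact multiple of another normalizes to
  identical values. Factors are checked against edgeR's
  `calcNormFactors` to 10⁻⁶.

## The synthetic-data generator

`simulate_lengths()` draws gene lengths from a two-component log-normal
mixture (bodies near 15 kb and 400 kb, σ_log of 0.9 and 0.7) with the
mixture weight solved so P(L > 100 kb) equals the target fraction,
default 0.13 — the approximate share of >100 kb genes in mammalian
transcriptomes (~3200 of ~24000). Draws are truncated to [200 bp,
2.5 Mb].

`simulate_counts()` draws NB counts with variance m + φm² (common
dispersion, default φ = 0.05 — technical-replicate-like noise), baseline
expression log-normal (σ_log 1.5) and independent of length, expected
column sums equal to `depth`. Two kinds of structure can be injected,
and both are serialized as ground truth:

* a log2 *genotype effect* per group applied to genes above a length
  threshold (default 100 kb);
* a log2 *batch bias amplitude* per library batch, multiplied by the
  length ramp r(L): 0 below 100 kb, 1 above 1 Mb, linear in log10 L
  between. The true functional form of amplification bias is unknown
  (real data only brackets its magnitude, roughly 3–40%); any monotone
  ramp is admissible and this one is simple, configurable and documented.
  The bias-visibility experiments use amplitude 0.3 (~23% at full ramp,
  inside that bracket); the specificity experiment uses 0.15, matching
  the magnitude of the reported MeCP2-range trends.

`simulate_titration()` mixes relative abundances before multinomial
sampling (mixing RNA mass before library prep), giving exact expected
mixture proportions at any depth.

What the generator does *not* emulate: biological replicate-to-replicate
covariance (gene-gene correlation), GC-content and RNA-priming biases,
isoform structure, and length-correlated expression levels. Passing tests
therefore demonstrate the statistical machinery's operating
characteristics under a faithful null and faithful injected signal — not
that any particular real dataset is free of artifacts.

## Numerical and design choices

* Degenerate windows (zero variance in both groups, equal means) give
  t = 0, p = 1 rather than an error.
* The Wilcoxon long-vs-short test enumerates the exact null when both
  groups have ≤ 8 observations and no ties; otherwise the normal
  approximation with tie and continuity corrections. Values whose total
  spread is below 10⁻⁹ (relative) are treated as fully tied (p = 1) so
  that analytically constant inputs are not ranked on rounding noise.
* "Long" means strictly greater than 100,000 bp everywhere; the boundary
  gene is short.
* The concordance chi-square dichotomizes |Δlog2FC| at the overall
  median by default (the published construction is under-specified); the
  threshold is exposed, Pearson's statistic is computed without
  continuity correction, and expected cell counts below 1 raise an error
  recommending an exact test.
* The reciprocal-artifact construction uses the middle (unbiased) batch
  as the pivot: batches with amplitudes (+a, 0, −a) compared 1-vs-2 and
  3-vs-2 give long-gene trends of +a-like and −a-like sign — a purely
  technical reciprocal pattern.
* `split_controls()` supports both seeded random splits and explicit
  lists, since published control pairings rarely document how they were
  chosen.
* All simulation entry points take an integer seed and restore the
  caller's RNG state, so analyses are reproducible end to end
  (`run_overlap_workflow()` reruns byte-identically).

## Limitations

The per-window t test treats the 200 genes in a bin as independent
observations; real expression data violate this (co-regulation,
chromosomal domains), which makes per-dataset significance counts
anti-conservative in ways the baseline comparison only partially absorbs.
The framework quantifies whether a trend exceeds the control-derived
noise floor under the stated assumptions; it does not identify the
mechanism of a bias, and a biological effect that happens to mimic the
baseline's length profile exactly is undetectable by construction.
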