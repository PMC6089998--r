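# longtrend

Are "long genes" really misregulated, or are you looking at technical
noise? Several influential transcriptomic studies reported that genes
longer than 100 kb are preferentially up- or down-regulated (most
prominently in MeCP2/Rett-syndrome models), based on running-average plots
of fold change against gene length. Those plots, however, were drawn
without a noise floor: comparing two groups of *control* samples to each
other produces length-dependent curves of similar magnitude, because
amplification-based platforms (RNA-seq, microarray) carry a
length-dependent technical bias of their own.

`longtrend` implements the statistical framework for making this call
properly, for analysts of bulk or single-cell expression data:

* **Running-average curves.** Genes with length L in [1, 1000] kb are
  sorted by length and binned with a sliding window of 200 genes stepping
  by 40; each window contributes its mean and SD of per-gene log2 fold
  change, plotted against mean gene length.
* **Overlap test** (the decision procedure). A *signal* comparison
  (case vs control) and a *baseline* comparison (two randomized subsets of
  controls) are windowed on the same bins. In each window a two-sided
  two-sample Student t test compares the 200 signal fold changes with the
  200 baseline fold changes; Benjamini–Hochberg FDR is applied across
  windows and bins with q < 0.05 are flagged. A curve that bends *as much
  as the baseline bends* is not significant — the test asks whether signal
  exceeds the noise floor, not whether the curve is flat.
* **Titration β-ratio QC.** For SEQC-style reference mixtures
  (A = UHRR, B = HBRR, C = 3:1, D = 1:3), β = (B − A)/(C − A) is
  analytically 4 (log2 β = 2) for every gene. Length-binned β curves expose
  length-dependent distortion independently of any biological contrast.
* **Normalization** by total-count, median-of-ratios, and TMM, to show
  that length bias is not a normalization artifact.
* **Gene-level summaries**: long-vs-short Wilcoxon tests (exact for small
  samples), DE quadrant counts at the 100 kb boundary, and cross-platform
  fold-change concordance chi-square tests.
* **A synthetic-data generator** (negative-binomial counts with ~13% long
  genes, batch-specific length-bias ramps, configurable genotype effects,
  multinomial titration mixtures) so every claim above is testable without
  external downloads.

## Worked example

The central question in one sitting: simulate an experiment whose
library preparation inflates long genes by up to 0.3 log2 units in *both*
the case and the control batches (no real biology), and ask the overlap
test about it:

```r
library(longtrend)

ann <- simulate_lengths(5000, frac_long = 0.13, seed = 42)
ex  <- simulate_overlap_experiment(ann, n_per_group = 10, depth = 2e6,
                                   shared_bias = 0.3, seed = 42)
res <- ex$result
long <- res$mean_length_bp > 1e5
sum(res$significant)                       # 0
mean(res$mean_fc_signal[long])             # +0.108
mean(res$mean_fc_baseline[long])           # +0.098
min_significant_p(res)                     # NA (no window flagged)
```

Both running-average curves bend upward by ~0.1 log2 in the long-gene
windows — exactly the kind of curve that has been read as "long gene
misregulation" — yet none of the 119 windows is significant, because the
baseline control-vs-control curve bends identically. Replacing the shared
bias with a genuine effect (`effect = -0.58` on long genes of the case
group only) flags every long-gene window: the signal curve drops to −0.46
while the baseline stays at −0.003, and the test separates them decisively.

`analysis/` contains the full study as numbered drivers:
`01_simulate.R` (datasets), `02_overlap_workflow.R` (end-to-end report
bundles with figures), `03_calibration_power.R` (type-I calibration,
power/specificity, power surface), `04_titration_beta.R` (β curves under
three normalizations), `05_reciprocal_batches.R` (opposite-signed
batch-bias artifact). Each writes its tables under `results/`.

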