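#!/usr/bin/env Rscript
# Run the full overlap-plot workflow on the three simulated experiments from
# 01_simulate.R. The expectation: the genuine -0.58 effect yields significant
# long-gene windows; the shared-bias and null experiments yield (almost) none,
# even though the shared-bias running-average curves visibly bend.

suppressPackageStartupMessages(library(longtrend))

samples <- function(group) paste0(group, "_", 1:10)

for (name in c("effect", "shared_bias", "null")) {
  counts <- sprintf("results/data/counts_%s.tsv", name)
  if (!file.exists(counts)) stop("run analysis/01_simulate.R first")
  config <- analysis_config(
    counts = counts, annotation = "results/data/genes.tsv",
    signal = comparison_spec("case_vs_control",
                             samples("case"), samples("control")),
    baseline = comparison_spec("ctrl_vs_ctrl",
                               samples("ctrlA"), samples("ctrlB"),
                               role = "baseline"),
    normalization = "median_of_ratios",
    out_dir = sprintf("results/overlap_%s", name), seed = 1)
  run <- run_overlap_workflow(config)
  s <- run$summary
  message(sprintf(
    "%-12s %3d windows | %2d significant (%d long, %d short) | max curve |dev| %.3f",
    name, s$n_windows, s$n_significant, s$n_significant_long,
    s$n_significant_short, max(abs(run$result$mean_fc_signal))))
}
message("full bundles (tables, summary.json, figures) under results/overlap_*/")
message(paste("note: in the effect scenario short-gene windows can also reach",
              "significance - repressing 13% of the transcriptome inflates the",
              "relative abundance of the rest, and with 200 genes per window",
              "the t test resolves that small compositional counter-shift"))
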