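#!/usr/bin/env Rscript
# Generate the synthetic study datasets every later step analyses:
# a 5000-gene annotation with ~13% long genes, plus three count experiments
# (a genuine -0.58 log2 long-gene effect; a 0.3 log2 shared library bias
# with no real effect; a plain null) and a titration experiment.

suppressPackageStartupMessages(library(longtrend))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260921L

ann <- simulate_lengths(5000, frac_long = 0.13, seed = seed)
write_annotation(ann, "results/data/genes.tsv")
message(sprintf("annotation: %d genes, %.1f%% longer than 100 kb",
                nrow(ann), 100 * mean(ann$gene_length > 1e5)))

scenarios <- list(
  effect = list(effect_spec = c(case = -0.58), bias_spec = NULL),
  shared_bias = list(effect_spec = NULL, bias_spec = c(p1 = 0.3)),
  null = list(effect_spec = NULL, bias_spec = NULL))

for (name in names(scenarios)) {
  sc <- scenarios[[name]]
  config <- sim_config(
    n_replicates = c(case = 10, control = 10, ctrlA = 10, ctrlB = 10),
    depth = 2e6, dispersion = 0.05,
    effect_spec = sc$effect_spec, bias_spec = sc$bias_spec,
    batch_of = c(case = "p1", ctrlA = "p1", control = "p2", ctrlB = "p2"),
    seed = seed + match(name, names(scenarios)))
  sim <- simulate_counts(config, ann)
  write_expression(sim$matrix, sprintf("results/data/counts_%s.tsv", name))
  message(sprintf("counts_%s.tsv: %d x %d, depth %.0f", name,
                  nrow(sim$matrix), ncol(sim$matrix), mean(colSums(sim$matrix))))
}

tit <- simulate_titration(ann, depth = 1e7, n_reps = 6, bias = "on",
                          seed = seed + 9L)
write_expression(tit$counts, "results/data/titration_counts.tsv")
write.table(data.frame(sample_id = names(tit$sample_type),
                       sample_type = tit$sample_type),
            "results/data/titration_samples.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("titration: 4 types x 6 replicates at depth 1e7, bias on (B +0.6 log2)")
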