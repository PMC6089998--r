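#' Simulate one overlap-plot experiment
#'
#' Generates four independent replicate groups (case, control, and two
#' extra control groups for the baseline split) from one negative-binomial
#' process, computes the signal (case vs control) and baseline
#' (control vs control) fold changes on normalized counts, and runs the
#' windowed overlap test. Two knobs reproduce the study conditions of
#' interest:
#'
#' * `effect`: a true log2 genotype effect applied to long genes
#'   (> 100 kb) of the case group only — genuine signal.
#' * `shared_bias`: a log2 length-ramp amplitude applied to one library
#'   batch that contains the first group of *both* comparisons — a
#'   technical artifact that bends both running-average curves equally
#'   while leaving no real group difference.
#'
#' @param annotation annotation data frame.
#' @param n_per_group replicates per group.
#' @param depth expected reads per sample.
#' @param dispersion NB dispersion.
#' @param effect log2 effect on long genes of the case group.
#' @param shared_bias log2 length-bias amplitude shared by the numerator
#'   groups of both comparisons.
#' @param seed integer seed.
#' @param params a [binning_params()].
#' @param normalize normalization method (`"none"` to skip).
#' @param alpha FDR threshold.
#' @return list with `result` (an `overlap_result`), `fc_signal`,
#'   `fc_baseline`, and `truth`.
#' @export
simulate_overlap_experiment <- function(annotation, n_per_group = 10,
                                        depth = 2e6, dispersion = 0.05,
                                        effect = 0, shared_bias = 0,
                                        seed = 1, params = binning_params(),
                                        normalize = "median_of_ratios",
                                        alpha = 0.05) {
  n <- n_per_group
  config <- sim_config(
    n_replicates = c(case = n, control = n, ctrlA = n, ctrlB = n),
    depth = depth, dispersion = dispersion,
    effect_spec = c(case = effect),
    bias_spec = if (shared_bias != 0) c(p1 = shared_bias) else NULL,
    batch_of = c(case = "p1", ctrlA = "p1", control = "p2", ctrlB = "p2"),
    seed = seed)
  sim <- simulate_counts(config, annotation)
  m <- if (identical(normalize, "none")) sim$matrix
       else normalize_counts(sim$matrix, normalize)$matrix
  sample_ids <- colnames(m)
  grp <- function(g) sample_ids[sim$truth$group_of == g]
  fc_signal <- compute_log2fc(m, comparison_spec("case_vs_control",
                                                 grp("case"), grp("control")))
  fc_baseline <- compute_log2fc(m, comparison_spec("control_vs_control",
                                                   grp("ctrlA"), grp("ctrlB"),
                                                   role = "baseline"))
  res <- overlap_test(fc_signal, fc_baseline, annotation, params, alpha = alpha)
  list(result = res, fc_signal = fc_signal, fc_baseline = fc_baseline,
       truth = sim$truth)
}

#' Replicate overlap experiments and summarize window behaviour
#'
#' Repeats [simulate_overlap_experiment()] with seeds `seed + 1 ... seed +
#' reps` on a fixed annotation and collects per-replicate window metrics:
#' the fraction of windows with raw p below 0.05, the fractions flagged at
#' the FDR threshold (all windows and long-gene windows, i.e. windows with
#' mean length above 100 kb), and the mean curve level in long windows
#' for both comparisons.
#'
#' @inheritParams simulate_overlap_experiment
#' @param reps number of simulation replicates.
#' @param long_threshold_bp windows with mean length above this count as
#'   long-gene windows.
#' @return data frame, one row per replicate: `rep`, `frac_raw_p05`,
#'   `frac_flagged`, `frac_long_flagged`, `mean_fc_long_signal`,
#'   `mean_fc_long_baseline`, `n_windows`, `n_long_windows`.
#' @export
replicate_overlap_metrics <- function(annotation, reps, seed = 1,
                                      n_per_group = 10, depth = 2e6,
                                      dispersion = 0.05, effect = 0,
                                      shared_bias = 0,
                                      params = binning_params(),
                                      normalize = "median_of_ratios",
                                      alpha = 0.05,
                                      long_threshold_bp = 1e5) {
  rows <- lapply(seq_len(reps), function(i) {
    ex <- simulate_overlap_experiment(annotation, n_per_group, depth,
                                      dispersion, effect, shared_bias,
                                      seed = seed + i, params = params,
                                      normalize = normalize, alpha = alpha)
    r <- ex$result
    long <- r$mean_length_bp > long_threshold_bp
    data.frame(rep = i,
               frac_raw_p05 = mean(r$p_value < 0.05),
               frac_flagged = mean(r$significant),
               frac_long_flagged = if (any(long)) mean(r$significant[long]) else NA_real_,
               mean_fc_long_signal = mean(r$mean_fc_signal[long]),
               mean_fc_long_baseline = mean(r$mean_fc_baseline[long]),
               n_windows = nrow(r), n_long_windows = sum(long))
  })
  do.call(rbind, rows)
}

#' Detection/false-flag rates over a grid of study conditions
#'
#' For each grid row (log2 `effect`, group size `n`, sequencing `depth`)
#' runs `reps` overlap simulations with the effect present and `reps`
#' matched null simulations (same conditions, zero effect), and reports
#' the mean fraction of long-gene windows flagged in each, with
#' Monte-Carlo standard errors (NA when `reps = 1`).
#'
#' @param grid data frame with columns `effect`, `n`, `depth`.
#' @param reps simulation replicates per cell.
#' @param annotation annotation data frame.
#' @param seed integer seed.
#' @param dispersion NB dispersion.
#' @param params a [binning_params()].
#' @param normalize normalization method.
#' @return `grid` augmented with `detection_rate`, `detection_se`,
#'   `null_rate`, `null_se`.
#' @export
power_surface <- function(grid, reps, annotation, seed = 1,
                          dispersion = 0.05, params = binning_params(),
                          normalize = "median_of_ratios") {
  stopifnot(nrow(grid) > 0, all(c("effect", "n", "depth") %in% names(grid)))
  mc <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cell_seed <- seed + 10000L * i
    eff <- replicate_overlap_metrics(annotation, reps, seed = cell_seed,
                                     n_per_group = grid$n[i],
                                     depth = grid$depth[i],
                                     dispersion = dispersion,
                                     effect = grid$effect[i],
                                     params = params, normalize = normalize)
    nul <- replicate_overlap_metrics(annotation, reps, seed = cell_seed + 5000L,
                                     n_per_group = grid$n[i],
                                     depth = grid$depth[i],
                                     dispersion = dispersion, effect = 0,
                                     params = params, normalize = normalize)
    data.frame(detection_rate = mean(eff$frac_long_flagged),
               detection_se = mc(eff$frac_long_flagged),
               null_rate = mean(nul$frac_long_flagged),
               null_se = mc(nul$frac_long_flagged))
  })
  cbind(grid, do.call(rbind, out))
}

#' Reciprocal batch-artifact experiment
#'
#' Simulates three batches of technical replicates of one biological
#' condition whose library preparations carry length-bias amplitudes
#' `(+amplitude, 0, -amplitude)`. Comparing the first and the third batch
#' against the middle (unbiased) batch produces running-average curves
#' whose long-gene window means have opposite signs — a purely technical
#' reciprocal pattern mimicking opposite-direction long-gene trends
#' between studies.
#'
#' @param annotation annotation data frame.
#' @param n_per_batch technical replicates per batch.
#' @param depth reads per sample.
#' @param amplitude log2 length-bias amplitude.
#' @param dispersion NB dispersion.
#' @param seed integer seed.
#' @param params a [binning_params()].
#' @param normalize normalization method.
#' @return list with `series_1v2`, `series_3v2` (`bin_series`) and
#'   `long_mean_1v2`, `long_mean_3v2` (mean of window means above 100 kb).
#' @export
reciprocal_artifact <- function(annotation, n_per_batch = 8, depth = 2e6,
                                amplitude = 0.4, dispersion = 0.05, seed = 1,
                                params = binning_params(),
                                normalize = "median_of_ratios") {
  config <- sim_config(
    n_replicates = c(batch1 = n_per_batch, batch2 = n_per_batch,
                     batch3 = n_per_batch),
    depth = depth, dispersion = dispersion,
    bias_spec = c(lp1 = amplitude, lp3 = -amplitude),
    batch_of = c(batch1 = "lp1", batch2 = "lp2", batch3 = "lp3"),
    seed = seed)
  sim <- simulate_counts(config, annotation)
  m <- if (identical(normalize, "none")) sim$matrix
       else normalize_counts(sim$matrix, normalize)$matrix
  ids <- colnames(m)
  grp <- function(g) ids[sim$truth$group_of == g]
  fc12 <- compute_log2fc(m, comparison_spec("batch1_vs_batch2",
                                            grp("batch1"), grp("batch2")))
  fc32 <- compute_log2fc(m, comparison_spec("batch3_vs_batch2",
                                            grp("batch3"), grp("batch2")))
  s12 <- running_average(fc12, annotation, params)
  s32 <- running_average(fc32, annotation, params)
  long12 <- s12$mean_length_bp > 1e5
  long32 <- s32$mean_length_bp > 1e5
  list(series_1v2 = s12, series_3v2 = s32,
       long_mean_1v2 = mean(s12$mean_log2fc[long12]),
       long_mean_3v2 = mean(s32$mean_log2fc[long32]))
}
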