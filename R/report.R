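#' Analysis configuration for the overlap workflow
#'
#' @param counts path to a counts TSV/CSV or an `expr_matrix`.
#' @param annotation path to an annotation TSV or a data frame.
#' @param signal,baseline [comparison_spec()] objects, or lists with
#'   `label`, `group1`, `group2`.
#' @param normalization `"median_of_ratios"`, `"total_count"`, `"tmm"`
#'   or `"none"`.
#' @param params a [binning_params()].
#' @param alpha FDR threshold.
#' @param seed integer seed (recorded in the summary; used only when a
#'   random control split is requested).
#' @param out_dir output directory, created if missing.
#' @param make_plots write the overlap figure (PDF) with its data
#'   sidecar TSV.
#' @return validated `analysis_config` list.
#' @export
analysis_config <- function(counts, annotation, signal, baseline,
                            normalization = "median_of_ratios",
                            params = binning_params(), alpha = 0.05,
                            seed = 1, out_dir = "longtrend_out",
                            make_plots = TRUE) {
  as_spec <- function(x, role) {
    if (inherits(x, "comparison_spec")) x
    else comparison_spec(x$label %||% role, x$group1, x$group2, role)
  }
  if (is.character(counts) && !file.exists(counts))
    stop("counts file not found: ", counts)
  if (is.character(annotation) && !file.exists(annotation))
    stop("annotation file not found: ", annotation)
  structure(list(counts = counts, annotation = annotation,
                 signal = as_spec(signal, "signal"),
                 baseline = as_spec(baseline, "baseline"),
                 normalization = normalization, params = params,
                 alpha = alpha, seed = seed, out_dir = out_dir,
                 make_plots = make_plots),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Expected keys: `counts`, `annotation`, `out_dir`, `normalization`,
#' `alpha`, `seed`, `signal: {label, group1, group2}`,
#' `baseline: {label, group1, group2}`, optional
#' `binning: {bin_size, shift, min_length, max_length}`.
#'
#' @param path YAML file.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  b <- y$binning %||% list()
  lp <- length_params(min_length = b$min_length %||% 1000,
                      max_length = b$max_length %||% 1000000)
  params <- binning_params(bin_size = b$bin_size %||% 200L,
                           shift = b$shift %||% 40L, length_params = lp)
  analysis_config(counts = y$counts, annotation = y$annotation,
                  signal = y$signal, baseline = y$baseline,
                  normalization = y$normalization %||% "median_of_ratios",
                  params = params, alpha = y$alpha %||% 0.05,
                  seed = y$seed %||% 1,
                  out_dir = y$out_dir %||% "longtrend_out",
                  make_plots = isTRUE(y$make_plots %||% TRUE))
}

#' Run the full overlap-plot workflow
#'
#' Orchestrates normalize -> fold changes (signal and baseline) ->
#' running averages -> overlap test -> report. Writes the normalized
#' matrix, size factors, both fold-change tables, both window series, the
#' overlap test table, a machine-readable JSON summary (counts of
#' significant windows above and below 100 kb, the p-value threshold
#' line, parameters), and optionally the overlap figure with a data
#' sidecar. Any stage error aborts with the stage name and removes
#' partial outputs. The exit state reflects validation only, never the
#' scientific outcome.
#'
#' @param config an [analysis_config()].
#' @return list with `result`, `series`, `summary`, `files` (invisible
#'   paths written).
#' @export
run_overlap_workflow <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(writer, obj, name) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  tryCatch({
    stage <- "read inputs"
    counts <- if (is.character(config$counts))
      read_expression(config$counts, scale = "counts") else config$counts
    annotation <- if (is.character(config$annotation))
      read_annotation(config$annotation) else config$annotation
    check_comparison(config$signal, counts)
    check_comparison(config$baseline, counts)

    stage <- "normalize"
    if (identical(config$normalization, "none")) {
      norm <- list(matrix = counts,
                   factors = size_factors(colnames(counts),
                                          rep(1, ncol(counts)), "none"))
    } else norm <- normalize_counts(counts, config$normalization)
    emit(write_expression, norm$matrix, "normalized.tsv")
    emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         norm$factors, "size_factors.tsv")

    stage <- "fold changes"
    fc_signal <- compute_log2fc(norm$matrix, config$signal)
    fc_baseline <- compute_log2fc(norm$matrix, config$baseline)
    emit(write_fc_table, fc_signal, "fc_signal.tsv")
    emit(write_fc_table, fc_baseline, "fc_baseline.tsv")

    stage <- "overlap test"
    result <- overlap_test(fc_signal, fc_baseline, annotation,
                           config$params, alpha = config$alpha)
    series <- overlap_series(result)
    emit(write_bin_series, series$signal, "windows_signal.tsv")
    emit(write_bin_series, series$baseline, "windows_baseline.tsv")
    emit(function(x, p) utils::write.table(as.data.frame(x), p, sep = "\t",
                                           quote = FALSE, row.names = FALSE),
         result, "overlap.tsv")

    stage <- "report"
    long <- result$mean_length_bp > 1e5
    summary <- list(
      n_windows = nrow(result),
      n_significant = sum(result$significant),
      n_significant_long = sum(result$significant & long),
      n_significant_short = sum(result$significant & !long),
      min_significant_p = min_significant_p(result),
      alpha = config$alpha, normalization = config$normalization,
      bin_size = config$params$bin_size, shift = config$params$shift,
      seed = config$seed,
      signal = config$signal$label, baseline = config$baseline$label)
    emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                             digits = NA, null = "null",
                                             na = "null", pretty = TRUE),
         summary, "summary.json")

    if (isTRUE(config$make_plots)) {
      stage <- "figures"
      emit(function(x, p) save_overlap_plot(x$result, x$series, p),
           list(result = result, series = series), "overlap_plot.pdf")
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           overlap_plot_data(result), "overlap_plot_data.tsv")
    }
    invisible(list(result = result, series = series, summary = summary,
                   files = written))
  }, error = function(e) {
    unlink(written)
    stop(sprintf("overlap workflow failed at stage '%s': %s",
                 stage, conditionMessage(e)), call. = FALSE)
  })
}

# flat per-window table of everything the figure draws
overlap_plot_data <- function(result) {
  rib_s <- ribbon(overlap_series(result)$signal)
  rib_b <- ribbon(overlap_series(result)$baseline)
  data.frame(mean_length_kb = result$mean_length_bp / 1000,
             mean_fc_signal = result$mean_fc_signal,
             signal_lower = rib_s$lower, signal_upper = rib_s$upper,
             mean_fc_baseline = result$mean_fc_baseline,
             baseline_lower = rib_b$lower, baseline_upper = rib_b$upper,
             neg_log10_p = -log10(pmax(result$p_value, 1e-300)),
             significant = result$significant)
}

#' Overlap plot
#'
#' Upper panel: the two running-average curves with mean +/- 0.5 SD
#' ribbons (signal red, baseline blue) on a log10 gene-length axis.
#' Lower panel: the per-window -log10 p track with significant windows as
#' red dots and, when any window is flagged, a dashed line at the minimum
#' -log10 p corresponding to FDR below alpha.
#'
#' @param result an `overlap_result`.
#' @param series optional [overlap_series()] output (recomputed if NULL).
#' @return list of two ggplot objects (`curves`, `pvalues`).
#' @export
plot_overlap <- function(result, series = NULL) {
  if (is.null(series)) series <- overlap_series(result)
  if (!identical(series$signal$offset, result$offset))
    stop("series windows do not match the overlap result")
  d <- overlap_plot_data(result)
  curves <- ggplot2::ggplot(d, ggplot2::aes(x = mean_length_kb)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = baseline_lower,
                                      ymax = baseline_upper),
                         fill = "blue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = signal_lower,
                                      ymax = signal_upper),
                         fill = "red", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = mean_fc_baseline), color = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = mean_fc_signal), color = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Gene length (kb)", y = "Mean log2 fold change") +
    ggplot2::theme_minimal()
  thr <- min_significant_p(result)
  pv <- ggplot2::ggplot(d, ggplot2::aes(x = mean_length_kb,
                                        y = neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(color = significant), size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Gene length (kb)", y = "-log10 p") +
    ggplot2::theme_minimal()
  if (!is.na(thr))
    pv <- pv + ggplot2::geom_hline(yintercept = -log10(thr),
                                   linetype = "dashed", color = "red")
  list(curves = curves, pvalues = pv)
}

save_overlap_plot <- function(result, series, path) {
  plots <- plot_overlap(result, series)
  if (requireNamespace("cowplot", quietly = TRUE)) {
    fig <- cowplot::plot_grid(plots$curves, plots$pvalues, ncol = 1,
                              rel_heights = c(2, 1), align = "v")
    ggplot2::ggsave(path, fig, width = 6, height = 6, device = grDevices::pdf)
  } else {
    grDevices::pdf(path, width = 6, height = 6)
    print(plots$curves); print(plots$pvalues)
    grDevices::dev.off()
  }
  invisible(path)
}
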