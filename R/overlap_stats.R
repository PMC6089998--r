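#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values across the windows of one overlap analysis,
#' order-preserving with respect to input positions.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# pooled-variance two-sample Student t from summary statistics;
# zero pooled variance with equal means -> t = 0 (p = 1), with unequal
# means -> +/-Inf (p = 0)
student_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf), (m1 - m2) / se)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

# Welch variant (unequal variances, Satterthwaite df)
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  t <- ifelse(se == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf), (m1 - m2) / se)
  df[!is.finite(df)] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

#' Overlap-plot test: per-window signal vs baseline comparison
#'
#' The decision procedure behind the overlap plot. Both fold-change
#' vectors are restricted to their common annotated gene universe, windows
#' are built once on that universe (so bins match gene-for-gene), and in
#' every window a two-sided two-sample t test compares the signal
#' fold-change values against the baseline fold-change values. P-values
#' are Benjamini-Hochberg adjusted across all windows of the analysis and
#' windows with `q < alpha` are flagged. A length-dependent trend that is
#' present in the baseline (control-vs-control) curve as strongly as in
#' the signal curve is therefore not flagged: the test asks whether the
#' signal exceeds the noise floor, not whether the curve bends.
#'
#' @param fc_signal,fc_baseline `fc_vector`s for the signal (case vs
#'   control) and baseline (control vs control) comparisons. They must
#'   cover the same annotated gene universe.
#' @param annotation annotation data frame.
#' @param params a [binning_params()].
#' @param alpha FDR threshold for flagging windows.
#' @param variant `"student"` (pooled variance, the default) or `"welch"`.
#' @return data frame (class `overlap_result`), one row per window:
#'   `offset`, `n`, `mean_length_bp`, `mean_fc_signal`, `mean_fc_baseline`,
#'   `sd_fc_signal`, `sd_fc_baseline`, `t_stat`, `p_value`, `q_value`,
#'   `significant`. Attributes: `alpha`, `variant`, `windows`.
#' @export
overlap_test <- function(fc_signal, fc_baseline, annotation,
                         params = binning_params(), alpha = 0.05,
                         variant = c("student", "welch")) {
  variant <- match.arg(variant)
  only_s <- setdiff(fc_signal$gene_id, fc_baseline$gene_id)
  only_b <- setdiff(fc_baseline$gene_id, fc_signal$gene_id)
  if (length(only_s) || length(only_b))
    stop(sprintf(paste0("fold-change vectors cover different gene universes ",
                        "(%d only in signal, e.g. %s; %d only in baseline, e.g. %s)"),
                 length(only_s), paste(utils::head(only_s, 3), collapse = ","),
                 length(only_b), paste(utils::head(only_b, 3), collapse = ",")))
  shared <- annotation[annotation$gene_id %in% fc_signal$gene_id, , drop = FALSE]
  w <- make_windows(shared, params)
  xs <- fc_signal$log2fc[match(w$gene_ids, fc_signal$gene_id)]
  xb <- fc_baseline$log2fc[match(w$gene_ids, fc_baseline$gene_id)]
  st_s <- window_stats(w, xs)
  st_b <- window_stats(w, xb)
  lenst <- window_stats(w, w$lengths)
  tt <- if (variant == "student")
    student_t_summary(st_s$mean, st_s$sd, st_s$n, st_b$mean, st_b$sd, st_b$n)
  else
    welch_t_summary(st_s$mean, st_s$sd, st_s$n, st_b$mean, st_b$sd, st_b$n)
  q <- bh_adjust(tt$p)
  out <- data.frame(offset = w$starts - 1L, n = st_s$n,
                    mean_length_bp = lenst$mean,
                    mean_fc_signal = st_s$mean, mean_fc_baseline = st_b$mean,
                    sd_fc_signal = st_s$sd, sd_fc_baseline = st_b$sd,
                    t_stat = tt$t, p_value = tt$p, q_value = q,
                    significant = q < alpha)
  structure(out, alpha = alpha, variant = variant, windows = w,
            class = c("overlap_result", "data.frame"))
}

#' P-value threshold line of an overlap plot
#'
#' The largest raw p-value among windows flagged at `q < alpha` — the
#' height of the dashed minimum `-log10(p)` line that separates flagged
#' from unflagged windows in the plot. `NA` when no window is flagged.
#'
#' @param result an `overlap_result`.
#' @return numeric p-value, or `NA_real_` when nothing is significant.
#' @export
min_significant_p <- function(result) {
  if (!any(result$significant)) return(NA_real_)
  max(result$p_value[result$significant])
}

#' Extract the two running-average curves of an overlap analysis
#'
#' @param result an `overlap_result`.
#' @return list of two `bin_series` (`signal`, `baseline`) on the shared
#'   windows.
#' @export
overlap_series <- function(result) {
  w <- attr(result, "windows")
  mk <- function(mean, sd, label) {
    structure(data.frame(offset = result$offset, n = result$n,
                         mean_length_bp = result$mean_length_bp,
                         mean_log2fc = mean, sd_log2fc = sd),
              windows = w, comparison_label = label,
              class = c("bin_series", "data.frame"))
  }
  list(signal = mk(result$mean_fc_signal, result$sd_fc_signal, "signal"),
       baseline = mk(result$mean_fc_baseline, result$sd_fc_baseline, "baseline"))
}
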