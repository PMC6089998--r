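#' Long-vs-short gene distribution test
#'
#' Two-sided Wilcoxon-Mann-Whitney comparison of a per-gene statistic
#' (typically a log2 fold change or log2 beta ratio) between long genes
#' (length strictly greater than `threshold_bp`) and short genes. The
#' exact null distribution is enumerated when both groups have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param values named numeric vector (names = gene ids) or an `fc_vector`.
#' @param annotation annotation data frame.
#' @param threshold_bp long/short boundary, default 100 kb; the boundary
#'   gene itself counts as short.
#' @return list with `statistic` (Mann-Whitney U for the long group),
#'   `p_value`, `n_long`, `n_short`, `exact`.
#' @export
long_short_test <- function(values, annotation, threshold_bp = 100000) {
  v <- as_gene_values(values)
  len <- annotation$gene_length[match(names(v), annotation$gene_id)]
  keep <- !is.na(len)
  v <- v[keep]; len <- len[keep]
  is_long <- len > threshold_bp
  x <- v[is_long]; y <- v[!is_long]
  if (!length(x) || !length(y))
    stop("both long and short gene groups must be nonempty")
  spread <- diff(range(c(x, y)))
  if (spread <= 1e-9 * max(1, abs(mean(c(x, y)))))  # degenerate: all tied

    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                n_long = length(x), n_short = length(y), exact = FALSE))
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_long = length(x), n_short = length(y), exact = exact)
}

as_gene_values <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("gene_id", "log2fc") %in% names(values)))
    stats::setNames(values$log2fc, values$gene_id)
  } else {
    if (is.null(names(values))) stop("`values` must be named by gene id")
    values
  }
}

#' Quadrant counts of differentially expressed genes
#'
#' Cross-classifies flagged DE genes by length (> `threshold_bp` = long,
#' strictly) and fold-change direction (up/down). Flagged genes with a
#' fold change of exactly zero are excluded from the quadrants and counted
#' separately, as are flagged genes missing from the annotation.
#'
#' @param fc_table data frame with `gene_id`, `log2fc` and a logical (or
#'   0/1) `de_flag` column.
#' @param annotation annotation data frame.
#' @param threshold_bp long/short boundary, default 100 kb.
#' @return list with `counts` (named integers `long_up`, `long_down`,
#'   `short_up`, `short_down`), `n_zero_fc`, `n_unannotated`,
#'   `threshold_bp`.
#' @export
de_quadrants <- function(fc_table, annotation, threshold_bp = 100000) {
  stopifnot(all(c("gene_id", "log2fc", "de_flag") %in% names(fc_table)))
  de <- fc_table[as.logical(fc_table$de_flag), , drop = FALSE]
  len <- annotation$gene_length[match(de$gene_id, annotation$gene_id)]
  n_unannotated <- sum(is.na(len))
  de <- de[!is.na(len), , drop = FALSE]; len <- len[!is.na(len)]
  zero <- de$log2fc == 0
  n_zero <- sum(zero)
  de <- de[!zero, , drop = FALSE]; len <- len[!zero]
  is_long <- len > threshold_bp
  up <- de$log2fc > 0
  counts <- c(long_up = sum(is_long & up), long_down = sum(is_long & !up),
              short_up = sum(!is_long & up), short_down = sum(!is_long & !up))
  list(counts = counts, n_zero_fc = n_zero, n_unannotated = n_unannotated,
       threshold_bp = threshold_bp)
}

#' Cross-platform fold-change concordance test
#'
#' Builds the per-gene absolute log2 fold-change difference between two
#' platforms and asks whether large discrepancies are enriched among long
#' genes: genes are dichotomized at `diff_threshold` (default the overall
#' median absolute difference) and a 2x2 Pearson chi-square test (no
#' continuity correction) of long/short against above/below threshold is
#' computed.
#'
#' @param rows data frame with `gene_id`, `log2fc_platform1`,
#'   `log2fc_platform2` and `is_long` (logical), or with `abs_diff`
#'   precomputed.
#' @param diff_threshold `"median"` or a numeric cut on `abs_diff`.
#' @return list with `table` (2x2 counts), `statistic`, `p_value`,
#'   `threshold` and the augmented `rows` (with `abs_diff`).
#' @export
concordance_test <- function(rows, diff_threshold = "median") {
  rows <- as.data.frame(rows)
  if (is.null(rows$abs_diff))
    rows$abs_diff <- abs(rows$log2fc_platform1 - rows$log2fc_platform2)
  if (nrow(rows) < 20) stop("need at least 20 genes for the concordance test")
  if (!any(rows$is_long) || !any(!rows$is_long))
    stop("both long and short genes must be present")
  thr <- if (identical(diff_threshold, "median")) stats::median(rows$abs_diff)
         else as.numeric(diff_threshold)
  tab <- table(factor(rows$is_long, levels = c(FALSE, TRUE),
                      labels = c("short", "long")),
               factor(rows$abs_diff > thr, levels = c(FALSE, TRUE),
                      labels = c("concordant", "discordant")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table (an all-zero row or column)")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    stop("expected cell count below 1; use an exact test instead")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, statistic = unname(ct$statistic),
       p_value = ct$p.value, threshold = thr, rows = rows)
}
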