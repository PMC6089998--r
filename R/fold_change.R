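#' Per-gene log2 fold changes for a comparison
#'
#' On count matrices uses the classic formula
#' `log2((mean(group1) + pseudocount) / (mean(group2) + pseudocount))`;
#' on log2-scale matrices the difference of group means of log2 values
#' (the standard convention downstream of RMA-style preprocessing).
#'
#' @param x an `expr_matrix`.
#' @param comparison a [comparison_spec()].
#' @param pseudocount added to both group means in counts mode; default 1.
#' @return data frame with columns `gene_id`, `log2fc` and attributes
#'   `comparison_label`, `role`, `pseudocount` (class `fc_vector`).
#' @export
compute_log2fc <- function(x, comparison, pseudocount = 1) {
  check_comparison(comparison, x)
  m <- unclass(x)
  mu1 <- rowMeans(m[, comparison$group1, drop = FALSE])
  mu2 <- rowMeans(m[, comparison$group2, drop = FALSE])
  if (expr_scale(x) == "counts") {
    if (pseudocount <= 0 && (any(mu1 == 0) || any(mu2 == 0)))
      stop("pseudocount must be > 0 when zero group means are present")
    fc <- log2((mu1 + pseudocount) / (mu2 + pseudocount))
  } else {
    fc <- mu1 - mu2
  }
  if (any(!is.finite(fc))) stop("non-finite fold change produced")
  fc_vector(rownames(m), fc, label = comparison$label, role = comparison$role,
            pseudocount = if (expr_scale(x) == "counts") pseudocount else NA_real_)
}

fc_vector <- function(gene_ids, log2fc, label = "fc", role = "signal",
                      pseudocount = NA_real_) {
  stopifnot(length(gene_ids) == length(log2fc), !anyDuplicated(gene_ids))
  structure(data.frame(gene_id = as.character(gene_ids),
                       log2fc = as.numeric(log2fc), stringsAsFactors = FALSE),
            comparison_label = label, role = role, pseudocount = pseudocount,
            class = c("fc_vector", "data.frame"))
}

#' Read a fold-change / differential-expression table
#'
#' TSV with columns `gene_id`, `log2fc` and optionally `pvalue`, `qvalue`,
#' `de_flag` (externally produced DE results, e.g. shrunken fold changes,
#' are accepted as input only). Genes absent from `annotation` are flagged
#' in the `unannotated` attribute.
#'
#' @param path file path.
#' @param annotation optional annotation data frame for flagging.
#' @return an `fc_vector` data frame, extra columns preserved.
#' @export
load_fc_table <- function(path, annotation = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df)))
    stop("fold-change table needs columns gene_id and log2fc")
  if (!is.numeric(df$log2fc)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$log2fc))))[1L]
    stop(sprintf("non-numeric log2fc in row %d (gene '%s')", bad, df$gene_id[bad]))
  }
  out <- fc_vector(df$gene_id, df$log2fc, label = basename(path))
  for (col in setdiff(names(df), c("gene_id", "log2fc"))) out[[col]] <- df[[col]]
  if (!is.null(annotation))
    attr(out, "unannotated") <- setdiff(out$gene_id, annotation$gene_id)
  out
}

#' Write a fold-change table
#' @param fc an `fc_vector`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fc_table <- function(fc, path) {
  df <- as.data.frame(fc)
  df$log2fc <- format(df$log2fc, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
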