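#' Construct a validated expression matrix
#'
#' Wraps a numeric genes-by-samples matrix together with the scale of its
#' values (raw sequencing counts vs log2 intensities) and the platform it
#' came from. The scale tag governs fold-change semantics downstream:
#' counts are compared as `log2((mean1 + pc)/(mean2 + pc))`, log2 values as
#' a difference of group means.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param scale `"counts"` or `"log2"`.
#' @param platform `"rnaseq"`, `"array"`, `"ncounter"` or `"other"`.
#' @return the matrix with class `"expr_matrix"` and attributes `scale`
#'   and `platform`.
#' @export
expression_matrix <- function(values, scale = c("counts", "log2"),
                              platform = c("rnaseq", "array", "ncounter", "other")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyNA(values))
    stop("missing values are not supported in expression matrices")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (scale == "counts" && any(values < 0))
    stop("negative values are not allowed when scale = \"counts\"")
  structure(values, scale = scale, platform = platform,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale=%s, platform=%s\n",
              nrow(x), ncol(x), attr(x, "scale"), attr(x, "platform")))
  utils::str(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Scale tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"counts"` or `"log2"`.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "counts"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' The delimiter is taken from the file extension (`.csv` = comma,
#' anything else = tab). Row and column order are preserved.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("counts", "log2"),
                            platform = c("rnaseq", "array", "ncounter", "other")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expected a gene id column plus at least one sample column")
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[-1L])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("non-numeric value %s at gene '%s', sample '%s'",
                 dQuote(vals[bad[1L], bad[2L]]), gene_ids[bad[1L]],
                 colnames(vals)[bad[2L]]))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  expression_matrix(num, scale = scale, platform = platform)
}

#' Write an expression matrix to TSV/CSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, then one column
#' per sample. Values are written with full double precision so that a
#' read/write round trip is exact for integer counts and good to at least
#' 12 significant digits for reals.
#'
#' @param x an `expr_matrix` (or plain named matrix).
#' @param path output path; `.csv` switches the delimiter to comma.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene_id = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a two-group comparison
#'
#' A named contrast between two disjoint sample groups. `role = "signal"`
#' marks a biological contrast (case vs control); `role = "baseline"` marks
#' a control-vs-control split used to estimate the technical/biological
#' noise floor.
#'
#' @param label comparison name.
#' @param group1,group2 character vectors of sample ids (numerator first:
#'   fold changes are group1 over group2).
#' @param role `"signal"` or `"baseline"`.
#' @return a `comparison_spec` list.
#' @export
comparison_spec <- function(label, group1, group2, role = c("signal", "baseline")) {
  role <- match.arg(role)
  group1 <- as.character(group1); group2 <- as.character(group2)
  if (!length(group1) || !length(group2))
    stop("both groups of comparison '", label, "' must be nonempty")
  ov <- intersect(group1, group2)
  if (length(ov))
    stop("groups of comparison '", label, "' overlap: ", paste(ov, collapse = ", "))
  structure(list(label = label, group1 = group1, group2 = group2, role = role),
            class = "comparison_spec")
}

check_comparison <- function(comparison, x) {
  missing <- setdiff(c(comparison$group1, comparison$group2), colnames(x))
  if (length(missing))
    stop("sample id(s) not in matrix: ", paste(missing, collapse = ", "))
  invisible(comparison)
}

#' Gene-length window parameters
#'
#' @param long_threshold genes strictly longer than this (bp) are "long";
#'   default 100 kb.
#' @param min_length,max_length length range (bp) retained before windowing;
#'   defaults 1 kb and 1 Mb.
#' @return a `length_params` list.
#' @export
length_params <- function(long_threshold = 100000L, min_length = 1000L,
                          max_length = 1000000L) {
  if (!(min_length < long_threshold && long_threshold < max_length))
    stop("need min_length < long_threshold < max_length")
  structure(list(long_threshold = as.numeric(long_threshold),
                 min_length = as.numeric(min_length),
                 max_length = as.numeric(max_length)),
            class = "length_params")
}

default_length_params <- function() length_params()

#' Collapse feature-level (probe) values to genes
#'
#' Microarray probes or transcript clusters mapping to the same gene are
#' summarized by the arithmetic mean of their log2 values. Collapsing raw
#' counts is refused: averaging counts across features has no clean
#' interpretation, and count platforms are quantified per gene upstream.
#'
#' @param x an `expr_matrix` with `scale = "log2"`; rownames are feature ids.
#' @param feature_to_gene named character vector (names = feature ids,
#'   values = gene ids) or a two-column data frame `(feature_id, gene_id)`.
#' @return an `expr_matrix` with one row per mapped gene, plus attribute
#'   `collapse_report`: a list with `n_features_in`, `n_unmapped_dropped`,
#'   `n_genes_out`.
#' @export
collapse_features <- function(x, feature_to_gene) {
  if (expr_scale(x) != "log2")
    stop("refusing to collapse a counts-scale matrix; collapse applies to log2 features only")
  if (is.data.frame(feature_to_gene)) {
    map <- stats::setNames(as.character(feature_to_gene[[2L]]),
                           as.character(feature_to_gene[[1L]]))
  } else map <- feature_to_gene
  genes <- unname(map[rownames(x)])
  unmapped <- is.na(genes)
  keep <- which(!unmapped)
  if (!length(keep)) stop("no feature maps to a gene")
  g <- factor(genes[keep], levels = unique(genes[keep]))
  collapsed <- rowsum(unclass(x)[keep, , drop = FALSE], g, reorder = FALSE) /
    as.vector(table(g)[levels(g)])
  out <- expression_matrix(collapsed, scale = "log2", platform = attr(x, "platform"))
  attr(out, "collapse_report") <- list(n_features_in = nrow(x),
                                       n_unmapped_dropped = sum(unmapped),
                                       n_genes_out = nrow(out))
  out
}

#' Resolve duplicate gene-length records
#'
#' Genes (or transcripts) annotated at several genomic locations keep the
#' longest length.
#'
#' @param records data frame with columns `gene_id`, `gene_length` and
#'   optionally `transcript_length`; one row per location.
#' @return annotation data frame with one row per `gene_id`, lengths equal
#'   to the per-id maximum; input order of first appearance preserved.
#' @export
resolve_lengths <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("gene_id", "gene_length") %in% names(records)))
    stop("`records` needs columns gene_id and gene_length")
  if (any(records$gene_length <= 0) ||
      (!is.null(records$transcript_length) &&
       any(records$transcript_length <= 0, na.rm = TRUE)))
    stop("lengths must be positive")
  ids <- factor(records$gene_id, levels = unique(records$gene_id))
  out <- data.frame(gene_id = levels(ids),
                    gene_length = as.vector(tapply(records$gene_length, ids, max)),
                    stringsAsFactors = FALSE)
  if (!is.null(records$transcript_length))
    out$transcript_length <-
      as.vector(tapply(records$transcript_length, ids, max, na.rm = TRUE))
  rownames(out) <- NULL
  out
}

#' Read a gene annotation table
#'
#' Two- or three-column TSV: `gene_id`, `gene_length` and optionally
#' `transcript_length`, lengths in bp. Duplicate ids are resolved to the
#' longest length via [resolve_lengths()].
#'
#' @param path file path.
#' @return annotation data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  resolve_lengths(df)
}

#' Write a gene annotation table
#' @param annotation annotation data frame.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split control samples into a random baseline comparison
#'
#' Draws two disjoint random subsets of the control samples, giving the
#' control-vs-control contrast whose fold changes estimate baseline
#' (within-genotype) variation. Deterministic for a fixed seed; controls
#' beyond `2 * n_per_side` are left out.
#'
#' @param control_ids character vector of control sample ids.
#' @param n_per_side samples per side.
#' @param seed integer seed.
#' @param label comparison label.
#' @return a [comparison_spec()] with `role = "baseline"`.
#' @export
split_controls <- function(control_ids, n_per_side, seed, label = "control_vs_control") {
  control_ids <- as.character(control_ids)
  if (length(control_ids) < 2L * n_per_side)
    stop(sprintf("need at least %d controls, got %d", 2L * n_per_side,
                 length(control_ids)))
  # local RNG scope without touching the session seed
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  picked <- sample(control_ids, 2L * n_per_side)
  comparison_spec(label,
                  group1 = picked[seq_len(n_per_side)],
                  group2 = picked[n_per_side + seq_len(n_per_side)],
                  role = "baseline")
}

#' Canonical gene order for windowing
#'
#' Length ascending, gene id lexicographic as a deterministic tie-break
#' (byte order, independent of locale).
#' @param annotation annotation data frame.
#' @param length_kind `"gene"` or `"transcript"`.
#' @return integer permutation of rows.
#' @keywords internal
length_order <- function(annotation, length_kind = c("gene", "transcript")) {
  length_kind <- match.arg(length_kind)
  len <- annotation_lengths(annotation, length_kind)
  order(len, annotation$gene_id, method = "radix")
}

annotation_lengths <- function(annotation, length_kind = c("gene", "transcript")) {
  length_kind <- match.arg(length_kind)
  if (length_kind == "transcript") {
    if (is.null(annotation$transcript_length))
      stop("annotation has no transcript_length column")
    annotation$transcript_length
  } else annotation$gene_length
}
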