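#' Sliding-window binning parameters
#'
#' Genes are sorted by length and binned with a sliding window of
#' `bin_size` consecutive genes moved in steps of `shift` genes; defaults
#' 200 and 40 (so consecutive windows share 160 genes). Genes outside
#' `[min_length, max_length]` (defaults 1 kb to 1000 kb) are dropped
#' before windowing. A trailing set of genes that does not fill a complete
#' window is dropped unless `keep_partial` is set, keeping the per-bin n
#' constant for the per-bin t test.
#'
#' @param bin_size genes per window.
#' @param shift step between window starts; `0 < shift <= bin_size`.
#' @param length_params a [length_params()].
#' @param length_kind covariate: `"gene"` or `"transcript"` length.
#' @param keep_partial keep a final incomplete window (default drop).
#' @return a `binning_params` list.
#' @export
binning_params <- function(bin_size = 200L, shift = 40L,
                           length_params = default_length_params(),
                           length_kind = c("gene", "transcript"),
                           keep_partial = FALSE) {
  length_kind <- match.arg(length_kind)
  bin_size <- as.integer(bin_size); shift <- as.integer(shift)
  if (!(shift > 0L && shift <= bin_size))
    stop("need 0 < shift <= bin_size")
  structure(list(bin_size = bin_size, shift = shift,
                 length_params = length_params, length_kind = length_kind,
                 keep_partial = keep_partial),
            class = "binning_params")
}

#' Build length-sorted sliding windows
#'
#' Filters the annotation to the configured length range, sorts genes by
#' (length, gene id) and lays complete windows at offsets
#' `0, shift, 2*shift, ...`; window count is
#' `floor((G - bin_size)/shift) + 1`.
#'
#' @param annotation annotation data frame (`gene_id`, `gene_length`,
#'   optionally `transcript_length`).
#' @param params a [binning_params()].
#' @return list with `gene_ids` (sorted, in-range), `lengths`, `starts`
#'   (1-based window start indices), `bin_size`, and `params`
#'   (class `length_windows`).
#' @export
make_windows <- function(annotation, params = binning_params()) {
  lp <- params$length_params
  len <- annotation_lengths(annotation, params$length_kind)
  keep <- len >= lp$min_length & len <= lp$max_length
  ann <- annotation[keep, , drop = FALSE]
  if (nrow(ann) < params$bin_size)
    stop(sprintf("only %d genes in [%g, %g] bp; need at least %d",
                 nrow(ann), lp$min_length, lp$max_length, params$bin_size))
  ord <- length_order(ann, params$length_kind)
  ann <- ann[ord, , drop = FALSE]
  G <- nrow(ann)
  n_win <- (G - params$bin_size) %/% params$shift + 1L
  starts <- 1L + params$shift * (seq_len(n_win) - 1L)
  sizes <- rep(params$bin_size, n_win)
  if (params$keep_partial && starts[n_win] + params$bin_size - 1L < G) {
    starts <- c(starts, starts[n_win] + params$shift)
    sizes <- c(sizes, G - starts[n_win + 1L] + 1L)
  }
  structure(list(gene_ids = ann$gene_id,
                 lengths = annotation_lengths(ann, params$length_kind),
                 starts = starts, sizes = sizes,
                 bin_size = params$bin_size, params = params),
            class = "length_windows")
}

# windowed mean/sd of a vector aligned to windows$gene_ids
# (sample SD, n-1 denominator)
window_stats <- function(w, x) {
  e <- w$starts + w$sizes - 1L
  k <- length(w$starts)
  mean <- numeric(k); sd <- numeric(k)
  for (i in seq_len(k)) {
    xi <- x[w$starts[i]:e[i]]
    mean[i] <- base::mean(xi)
    sd[i] <- stats::sd(xi)
  }
  list(mean = mean, sd = sd, n = w$sizes)
}

# per-window member values as a list (used for tests/oracles)
window_members <- function(w) {
  e <- w$starts + w$sizes - 1L
  lapply(seq_along(w$starts), function(i) w$gene_ids[w$starts[i]:e[i]])
}

#' Running-average curve of fold change vs gene length
#'
#' The per-window arithmetic mean and sample standard deviation of the
#' member genes' log2 fold changes, against the per-window mean gene
#' length: one row per window. Genes lacking a fold-change value are
#' dropped before windowing (reported via the `n_dropped` attribute).
#'
#' @param fc an `fc_vector` (or data frame with `gene_id`, `log2fc`).
#' @param annotation annotation data frame.
#' @param params a [binning_params()].
#' @param windows optional precomputed [make_windows()] result (used by
#'   [overlap_test()] so both curves share bins gene-for-gene).
#' @return data frame (class `bin_series`): `offset`, `n`,
#'   `mean_length_bp`, `mean_log2fc`, `sd_log2fc`; attribute `windows`.
#' @export
running_average <- function(fc, annotation, params = binning_params(),
                            windows = NULL) {
  if (is.null(windows)) {
    have <- annotation$gene_id %in% fc$gene_id
    windows <- make_windows(annotation[have, , drop = FALSE], params)
    attr(windows, "n_dropped") <- sum(!have)
  }
  x <- fc$log2fc[match(windows$gene_ids, fc$gene_id)]
  if (anyNA(x))
    stop("fold-change vector does not cover the windowed gene universe")
  st <- window_stats(windows, x)
  lenst <- window_stats(windows, windows$lengths)
  out <- data.frame(offset = windows$starts - 1L, n = st$n,
                    mean_length_bp = lenst$mean,
                    mean_log2fc = st$mean, sd_log2fc = st$sd)
  structure(out, windows = windows, n_dropped = attr(windows, "n_dropped"),
            comparison_label = attr(fc, "comparison_label"),
            class = c("bin_series", "data.frame"))
}

#' Ribbon bounds around a running-average curve
#'
#' `mean - half_sd * SD` to `mean + half_sd * SD` per window. The display
#' default 0.5 draws half of one standard deviation on each side; setting
#' `half_sd = 1.96` gives the conventional 95 percent band
#' (mean plus or minus 1.96 standard deviations).
#'
#' @param series a `bin_series` from [running_average()].
#' @param half_sd nonnegative multiplier of the per-window SD.
#' @return data frame with `mean_length_bp`, `lower`, `upper`.
#' @export
ribbon <- function(series, half_sd = 0.5) {
  if (half_sd < 0) stop("half_sd must be nonnegative")
  data.frame(mean_length_bp = series$mean_length_bp,
             lower = series$mean_log2fc - half_sd * series$sd_log2fc,
             upper = series$mean_log2fc + half_sd * series$sd_log2fc)
}

#' Write a running-average series to TSV
#' @param series a `bin_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
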