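#' Count normalization
#'
#' Three between-sample normalizations for raw count matrices: total-count
#' scaling, the median-of-ratios size factors of the DESeq family, and the
#' trimmed mean of M-values (TMM). Each returns the normalized matrix
#' together with the per-sample factors, so analyses are reproducible from
#' either. All three divide column j by a positive size factor; they differ
#' only in how that factor is estimated.
#'
#' @name normalization
NULL

size_factors <- function(sample_ids, factors, method) {
  stopifnot(length(sample_ids) == length(factors), all(factors > 0))
  data.frame(sample_id = sample_ids, factor = as.numeric(factors),
             method = method, stringsAsFactors = FALSE)
}

apply_factors <- function(counts, factors) {
  out <- sweep(unclass(counts), 2L, factors, "/")
  expression_matrix(out, scale = "counts", platform = attr(counts, "platform") %||% "rnaseq")
}

#' Total-count normalization
#'
#' Scaling factors are computed such that the normalized read counts across
#' all samples are equal: column j is divided by its library size over the
#' mean library size, so every normalized column sums to the mean of the
#' original library sizes (keeping values on the original count scale).
#'
#' @param counts an `expr_matrix` with `scale = "counts"`.
#' @return list with `matrix` (normalized `expr_matrix`) and `factors`
#'   (data frame `sample_id`, `factor`, `method`).
#' @export
normalize_total_count <- function(counts) {
  stopifnot(expr_scale(counts) == "counts")
  libsize <- colSums(counts)
  if (any(libsize <= 0))
    stop("zero column sum for sample(s): ",
         paste(colnames(counts)[libsize <= 0], collapse = ", "))
  f <- libsize / mean(libsize)
  list(matrix = apply_factors(counts, f),
       factors = size_factors(colnames(counts), f, "total_count"))
}

#' Median-of-ratios normalization
#'
#' Per-sample size factor = median over genes of the ratio of the sample's
#' count to the gene's geometric mean across samples, taken over genes with
#' all-positive counts (the estimator behind DESeq size factors). The
#' factors satisfy the estimator's fixed point exactly: the per-sample
#' median ratio of normalized counts to the reference profile (per-gene
#' geometric mean of the raw counts) is 1.
#'
#' @inheritParams normalize_total_count
#' @return list with `matrix` and `factors`.
#' @export
normalize_median_of_ratios <- function(counts) {
  stopifnot(expr_scale(counts) == "counts")
  m <- unclass(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has positive counts in every sample; median-of-ratios undefined")
  logm <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  f <- apply(exp(logm - loggeo), 2L, stats::median)
  list(matrix = apply_factors(counts, f),
       factors = size_factors(colnames(counts), f, "median_of_ratios"))
}

# TMM scaling factor of one sample against the reference column, the
# doubly trimmed precision-weighted mean of per-gene log2 ratios.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  # delta-method variance of M for binomial sampling of reads
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1;      hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- 2^(sum(M[keep2] / w[keep2], na.rm = TRUE) /
            sum(1 / w[keep2], na.rm = TRUE))
  if (!is.finite(f)) 1 else f
}

#' TMM normalization
#'
#' Trimmed mean of M-values. For each sample against a reference column,
#' per-gene log2 expression ratios (M) and average log abundances (A) are
#' formed after library-size adjustment, genes with a zero in either sample
#' are excluded, the most extreme 30 percent of M values and 5 percent of A
#' values on each side are trimmed, and the scaling factor is 2 to the
#' precision-weighted mean of the retained M values. Factors are rescaled
#' to geometric mean 1. The size factor applied to the matrix is the
#' effective library size (TMM factor times library size), rescaled to
#' geometric mean 1, so that a sample that is an exact multiple of another
#' normalizes to the same values.
#'
#' @inheritParams normalize_total_count
#' @param ref_sample reference sample id; default picks the column whose
#'   upper quartile of scaled counts is closest to the mean upper quartile.
#' @param logratio_trim,abs_trim trim fractions per tail on M and A.
#' @return list with `matrix`, `factors` (effective-library size factors)
#'   and `tmm_factors` (the pure TMM scaling factors, geometric mean 1).
#' @export
normalize_tmm <- function(counts, ref_sample = NULL,
                          logratio_trim = 0.3, abs_trim = 0.05) {
  stopifnot(expr_scale(counts) == "counts")
  m <- unclass(counts)
  lib <- colSums(m)
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(m)[lib <= 0], collapse = ", "))
  m <- m[rowSums(m) > 0, , drop = FALSE]   # all-zero genes carry no information
  if (is.null(ref_sample)) {
    uq <- apply(sweep(m, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
    ref_sample <- colnames(m)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref_sample %in% colnames(m)) stop("unknown reference sample: ", ref_sample)
  r <- match(ref_sample, colnames(m))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == r) 1 else tmm_pair_factor(m[, j], m[, r], lib[j], lib[r],
                                       logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  eff <- f * lib
  s <- eff / exp(mean(log(eff)))
  list(matrix = apply_factors(counts, s),
       factors = size_factors(colnames(m), s, "tmm"),
       tmm_factors = size_factors(colnames(m), f, "tmm"))
}

#' Normalize counts by a named method
#'
#' @inheritParams normalize_total_count
#' @param method `"total_count"`, `"median_of_ratios"` or `"tmm"`.
#' @param ... passed to the method.
#' @return list with `matrix` and `factors`.
#' @export
normalize_counts <- function(counts,
                             method = c("median_of_ratios", "total_count", "tmm"),
                             ...) {
  method <- match.arg(method)
  switch(method,
         total_count = normalize_total_count(counts),
         median_of_ratios = normalize_median_of_ratios(counts),
         tmm = normalize_tmm(counts, ...))
}
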