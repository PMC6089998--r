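#' Titration sample set
#'
#' Replicate-averaged, normalized expression profiles of the four
#' reference sample types used in SEQC-style titration designs:
#' A (Universal Human Reference RNA), B (Human Brain Reference RNA),
#' C (3:1 mixture of A and B) and D (1:3 mixture of A and B). If the
#' titration is faithful and measurement is unbiased,
#' `(B - A)/(C - A) = 4` for every gene with `B != A`, independent of the
#' gene and its expression level.
#'
#' @param A,B,C per-gene numeric vectors named by gene id (aligned).
#' @param D optional fourth profile (1:3 mixture).
#' @return a `titration_set` list with the profiles and the design
#'   weights (`C`: 3/4 A + 1/4 B, `D`: 1/4 A + 3/4 B).
#' @export
titration_set <- function(A, B, C, D = NULL) {
  ids <- names(A)
  if (is.null(ids)) stop("profiles must be named by gene id")
  for (p in list(B = B, C = C, D = D)) {
    if (is.null(p)) next
    if (!identical(names(p), ids))
      stop("all profiles must share one gene universe in the same order")
  }
  if (any(A < 0 | B < 0 | C < 0) || (!is.null(D) && any(D < 0)))
    stop("profiles must be nonnegative")
  structure(list(A = A, B = B, C = C, D = D,
                 design = list(C = c(A = 0.75, B = 0.25),
                               D = c(A = 0.25, B = 0.75))),
            class = "titration_set")
}

#' Per-gene beta ratio
#'
#' `beta_g = (B_g - A_g) / (C_g - A_g)`. For an exact 3:1 mixture
#' `C = 0.75 A + 0.25 B` this is 4 (log2 = 2) for every gene with
#' `B != A`. Genes whose denominator is within `epsilon` (relative to the
#' gene's magnitude) of zero, or whose beta is not positive (log2
#' undefined), are flagged invalid with a reason rather than dropped
#' silently.
#'
#' @param tset a [titration_set()].
#' @param epsilon relative near-zero-denominator tolerance.
#' @return data frame (class `beta_table`): `gene_id`, `beta`,
#'   `log2_beta`, `valid`, `exclusion_reason` in
#'   `{"none", "near_zero_denominator", "sign_mismatch"}`.
#' @export
beta_ratio <- function(tset, epsilon = 1e-6) {
  A <- tset$A; B <- tset$B; C <- tset$C
  denom <- C - A
  scale <- pmax(A, B, 1)
  near_zero <- abs(denom) <= epsilon * scale
  beta <- ifelse(near_zero, NA_real_, (B - A) / denom)
  nonpos <- !near_zero & beta <= 0
  valid <- !near_zero & !nonpos
  reason <- rep("none", length(A))
  reason[near_zero] <- "near_zero_denominator"
  reason[nonpos] <- "sign_mismatch"
  log2_beta <- rep(NA_real_, length(A))
  log2_beta[valid] <- log2(beta[valid])
  structure(data.frame(gene_id = names(A), beta = beta,
                       log2_beta = log2_beta,
                       valid = valid, exclusion_reason = reason,
                       stringsAsFactors = FALSE),
            n_excluded = sum(!valid),
            class = c("beta_table", "data.frame"))
}

#' Running-average curve of log2 beta vs gene length
#'
#' Windowed mean and SD of per-gene log2 beta over length-sorted valid
#' genes. For a faithful titration measured without length-dependent
#' distortion the expected curve is the horizontal line at
#' log2(beta) = 2; deviations localized to long genes indicate
#' length-dependent technical bias.
#'
#' @param table a [beta_ratio()] result.
#' @param annotation annotation data frame.
#' @param params a [binning_params()].
#' @return a `bin_series` of log2 beta (column `mean_log2fc` holds the
#'   windowed mean log2 beta).
#' @export
beta_length_curve <- function(table, annotation, params = binning_params()) {
  valid <- table[table$valid, c("gene_id", "log2_beta")]
  names(valid) <- c("gene_id", "log2fc")
  fc <- fc_vector(valid$gene_id, valid$log2fc, label = "log2_beta")
  running_average(fc, annotation, params)
}

#' Long-vs-short summary of log2 beta
#'
#' Per-group (long vs short genes) median and quartiles of log2 beta with
#' the two-sided Wilcoxon comparison of the two distributions.
#'
#' @inheritParams beta_length_curve
#' @param threshold_bp long/short boundary (bp).
#' @return list with `summary` (data frame: group, n, q25, median, q75)
#'   and `test` (the [long_short_test()] result).
#' @export
beta_long_short_summary <- function(table, annotation, threshold_bp = 100000) {
  valid <- table[table$valid, , drop = FALSE]
  v <- stats::setNames(valid$log2_beta, valid$gene_id)
  len <- annotation$gene_length[match(names(v), annotation$gene_id)]
  v <- v[!is.na(len)]; len <- len[!is.na(len)]
  is_long <- len > threshold_bp
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sm <- rbind(long = qs(v[is_long]), short = qs(v[!is_long]))
  summary <- data.frame(group = rownames(sm),
                        n = c(sum(is_long), sum(!is_long)),
                        q25 = sm[, 1], median = sm[, 2], q75 = sm[, 3],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary,
       test = long_short_test(v, annotation, threshold_bp))
}
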