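#' Evaluate code with a local RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulations are reproducible without clobbering the
#' session stream.
#' @param seed integer seed.
#' @param code expression.
#' @return value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Length-bias ramp
#'
#' Smooth monotone weight standing in for length-dependent amplification
#' bias: 0 for genes up to `lo` bp, 1 above `hi` bp, linear in log10
#' length in between. A batch with bias amplitude `a` (log2 units)
#' multiplies gene g's expected expression by `2^(a * length_ramp(L_g))`.
#'
#' @param length_bp gene lengths in bp.
#' @param lo,hi ramp bounds in bp (defaults 100 kb and 1 Mb).
#' @return numeric weights in `[0, 1]`.
#' @export
length_ramp <- function(length_bp, lo = 1e5, hi = 1e6) {
  pmin(1, pmax(0, (log10(length_bp) - log10(lo)) / (log10(hi) - log10(lo))))
}

#' Simulate a gene-length annotation
#'
#' Lengths are drawn from a two-component log-normal mixture (a body of
#' typical genes and a long-gene component) with the mixture weight
#' solved so that the probability of exceeding 100 kb equals `frac_long`
#' — by default 0.13, the approximate share of long genes in mammalian
#' transcriptomes (~3200 of ~24000 genes). Draws are truncated to
#' [200 bp, 2.5 Mb] by resampling.
#'
#' @param n number of genes (>= 100).
#' @param frac_long target P(length > 100 kb).
#' @param seed integer seed.
#' @return annotation data frame (`gene_id`, `gene_length`), gene ids
#'   `g00001`, `g00002`, ... in draw order.
#' @export
simulate_lengths <- function(n, frac_long = 0.13, seed = 1) {
  if (n < 100) stop("need n >= 100")
  ml1 <- log(1.5e4); sl1 <- 0.9   # typical genes, mostly < 100 kb
  ml2 <- log(4e5);   sl2 <- 0.7   # long-gene component, mostly > 100 kb
  p1 <- stats::pnorm((log(1e5) - ml1) / sl1, lower.tail = FALSE)
  p2 <- stats::pnorm((log(1e5) - ml2) / sl2, lower.tail = FALSE)
  w <- (frac_long - p1) / (p2 - p1)
  if (!is.finite(w) || w < 0 || w > 1)
    stop(sprintf("frac_long = %g is infeasible for the length mixture", frac_long))
  with_local_seed(seed, {
    comp <- stats::rbinom(n, 1L, w)
    len <- exp(stats::rnorm(n, ifelse(comp == 1L, ml2, ml1),
                            ifelse(comp == 1L, sl2, sl1)))
    bad <- which(len < 200 | len > 2.5e6)
    while (length(bad)) {
      len[bad] <- exp(stats::rnorm(length(bad),
                                   ifelse(comp[bad] == 1L, ml2, ml1),
                                   ifelse(comp[bad] == 1L, sl2, sl1)))
      bad <- which(len < 200 | len > 2.5e6)
    }
    data.frame(gene_id = sprintf("g%05d", seq_len(n)),
               gene_length = round(len), stringsAsFactors = FALSE)
  })
}

#' Simulation configuration
#'
#' Conditions for one simulated expression experiment: group sizes,
#' sequencing depth, negative-binomial dispersion, genotype effects and
#' batch-specific length bias.
#'
#' @param n_replicates named integer vector of group sizes, e.g.
#'   `c(case = 10, control = 10)`. Samples are named `<group>_<i>`.
#' @param depth expected reads per sample.
#' @param dispersion common NB dispersion (variance = m + dispersion*m^2).
#' @param effect_spec named numeric: log2 genotype effect per group
#'   (groups omitted get 0), applied to genes selected by
#'   `effect_threshold_bp`.
#' @param effect_threshold_bp genes strictly longer than this carry the
#'   effect; default 100 kb.
#' @param bias_spec named numeric: log2 length-bias amplitude per batch
#'   (batches omitted get 0); gene g in batch b is multiplied by
#'   `2^(bias_spec[b] * length_ramp(L_g))`.
#' @param batch_of named character: batch of each group (defaults to one
#'   common batch `"b1"`).
#' @param base_sdlog log-normal spread of baseline expression.
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_replicates = c(case = 10L, control = 10L),
                       depth = 2e6, dispersion = 0.05,
                       effect_spec = NULL, effect_threshold_bp = 1e5,
                       bias_spec = NULL, batch_of = NULL,
                       base_sdlog = 1.5, seed = 1) {
  if (is.null(names(n_replicates)) || any(n_replicates < 1))
    stop("n_replicates must be a named vector of positive group sizes")
  if (depth <= 0) stop("depth must be positive")
  if (dispersion < 0) stop("dispersion must be nonnegative")
  groups <- names(n_replicates)
  if (is.null(batch_of)) batch_of <- stats::setNames(rep("b1", length(groups)), groups)
  if (!all(groups %in% names(batch_of)))
    stop("batch_of must cover every group")
  effect <- stats::setNames(rep(0, length(groups)), groups)
  if (!is.null(effect_spec)) effect[names(effect_spec)] <- effect_spec
  structure(list(n_replicates = n_replicates, depth = depth,
                 dispersion = dispersion, effect_spec = effect,
                 effect_threshold_bp = effect_threshold_bp,
                 bias_spec = bias_spec, batch_of = batch_of[groups],
                 base_sdlog = base_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a count matrix with known ground truth
#'
#' Counts are negative binomial with mean
#' `m_g * 2^(effect_g[group(j)]) * 2^(bias[batch(j)] * ramp(L_g))`,
#' rescaled per sample so expected column sums equal `depth`; `m_g` is
#' log-normal baseline expression (independent of gene length). The
#' ground truth (baseline means, per-gene effects, per-gene per-batch
#' bias multipliers, sample metadata, expected matrix) is returned with
#' the data so recovery can be checked exactly.
#'
#' @param config a [sim_config()].
#' @param annotation annotation data frame (defines the gene universe).
#' @return list with `matrix` (`expr_matrix`, counts) and `truth` (list:
#'   `base_mean`, `effect_log2` gene x group matrix, `bias_log2` gene x
#'   batch matrix, `group_of`, `batch_of` per sample, `mu` expected
#'   counts).
#' @export
simulate_counts <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  G <- nrow(annotation)
  groups <- names(config$n_replicates)
  sample_group <- rep(groups, config$n_replicates)
  sample_ids <- unlist(lapply(groups, function(g)
    paste0(g, "_", seq_len(config$n_replicates[[g]]))))
  sample_batch <- unname(config$batch_of[sample_group])
  batches <- unique(sample_batch)
  ramp <- length_ramp(annotation$gene_length)
  long_sel <- annotation$gene_length > config$effect_threshold_bp
  effect_log2 <- outer(as.numeric(long_sel), config$effect_spec[groups])
  rownames(effect_log2) <- annotation$gene_id
  bias_amp <- stats::setNames(rep(0, length(batches)), batches)
  if (!is.null(config$bias_spec)) {
    known <- intersect(names(config$bias_spec), batches)
    bias_amp[known] <- config$bias_spec[known]
  }
  bias_log2 <- outer(ramp, bias_amp)
  rownames(bias_log2) <- annotation$gene_id
  with_local_seed(config$seed, {
    m <- stats::rlnorm(G, meanlog = 0, sdlog = config$base_sdlog)
    rel <- m * 2^(effect_log2[, sample_group, drop = FALSE] +
                    bias_log2[, sample_batch, drop = FALSE])
    mu <- sweep(rel, 2L, colSums(rel) / config$depth, "/")
    counts <- if (config$dispersion == 0)
      matrix(stats::rpois(G * length(sample_ids), mu), nrow = G)
    else
      matrix(stats::rnbinom(G * length(sample_ids), mu = mu,
                            size = 1 / config$dispersion), nrow = G)
    dimnames(counts) <- list(annotation$gene_id, sample_ids)
    dimnames(mu) <- dimnames(counts)
    list(matrix = expression_matrix(counts, scale = "counts"),
         truth = list(base_mean = stats::setNames(m, annotation$gene_id),
                      effect_log2 = effect_log2, bias_log2 = bias_log2,
                      group_of = stats::setNames(sample_group, sample_ids),
                      batch_of = stats::setNames(sample_batch, sample_ids),
                      mu = mu))
  })
}

#' Simulate a titration experiment
#'
#' Draws two distinct log-normal reference transcriptomes A and B
#' (relative abundances), forms the in-silico mixtures
#' `C = 0.75 A + 0.25 B` and `D = 0.25 A + 0.75 B` at the
#' relative-abundance level (mixing mass before library prep), and
#' samples replicate counts multinomially at the given depth. A per-type
#' length-ramp bias (log2 amplitude) can distort the sampling
#' probabilities of chosen sample types; a distortion shared exactly by
#' all four types cancels in the beta ratio, so only type- or
#' batch-specific distortion is modelled.
#'
#' @param annotation annotation data frame.
#' @param depth reads per replicate.
#' @param n_reps replicates per sample type.
#' @param bias named numeric, log2 ramp amplitude per sample type
#'   (e.g. `c(B = 0.6)`); `NULL` for unbiased. The shorthand `bias = "on"`
#'   applies amplitude 0.6 to the brain reference B, modelling
#'   composition-dependent amplification distortion concentrated in the
#'   long-transcript-rich reference (a distortion shared exactly by all
#'   types cancels in beta and is therefore not a usable bias model).
#' @param base_sdlog log-normal spread of the reference profiles.
#' @param seed integer seed.
#' @return list with `counts` (`expr_matrix`, columns `A_1 ... D_n`),
#'   `sample_type` (named character per column), and `truth`
#'   (`p_A`, `p_B`, `p_C`, `p_D` true relative abundances before bias,
#'   `bias` amplitudes used).
#' @export
simulate_titration <- function(annotation, depth = 1e7, n_reps = 6,
                               bias = NULL, base_sdlog = 1.2, seed = 1) {
  if (identical(bias, "on")) bias <- c(B = 0.6)
  G <- nrow(annotation)
  with_local_seed(seed, {
    p_A <- stats::rlnorm(G, 0, base_sdlog); p_A <- p_A / sum(p_A)
    p_B <- stats::rlnorm(G, 0, base_sdlog); p_B <- p_B / sum(p_B)
    if (stats::cor(p_A, p_B) >= 0.99)
      stop("reference profiles A and B are not distinct enough")
    p <- list(A = p_A, B = p_B,
              C = 0.75 * p_A + 0.25 * p_B, D = 0.25 * p_A + 0.75 * p_B)
    ramp <- length_ramp(annotation$gene_length)
    amp <- stats::setNames(rep(0, 4), names(p))
    if (!is.null(bias)) amp[names(bias)] <- bias
    counts <- do.call(cbind, lapply(names(p), function(ty) {
      q <- p[[ty]] * 2^(amp[[ty]] * ramp)
      stats::rmultinom(n_reps, size = depth, prob = q / sum(q))
    }))
    sample_ids <- paste0(rep(names(p), each = n_reps), "_", seq_len(n_reps))
    dimnames(counts) <- list(annotation$gene_id, sample_ids)
    list(counts = expression_matrix(counts, scale = "counts"),
         sample_type = stats::setNames(rep(names(p), each = n_reps), sample_ids),
         truth = c(stats::setNames(p, paste0("p_", names(p))),
                   list(bias = amp)))
  })
}

#' Build a titration_set from replicate counts
#'
#' Normalizes the combined count matrix (median-of-ratios by default),
#' averages replicates within each sample type and returns the
#' [titration_set()] on which [beta_ratio()] operates.
#'
#' @param counts `expr_matrix` of replicate counts.
#' @param sample_type named character vector, sample id to type (A/B/C/D).
#' @param method normalization method, or `"none"`.
#' @return a [titration_set()].
#' @export
make_titration_set <- function(counts, sample_type,
                               method = c("median_of_ratios", "total_count",
                                          "tmm", "none")) {
  method <- match.arg(method)
  m <- if (method == "none") unclass(counts)
       else unclass(normalize_counts(counts, method)$matrix)
  avg <- function(ty) rowMeans(m[, names(sample_type)[sample_type == ty],
                                 drop = FALSE])
  types <- unique(sample_type)
  D <- if ("D" %in% types) avg("D") else NULL
  titration_set(A = avg("A"), B = avg("B"), C = avg("C"), D = D)
}

#' Exact in-silico titration profiles
#'
#' Noiseless titration set with mixtures formed exactly from A and B;
#' the analytic fixed point of the beta ratio (log2 beta = 2 everywhere).
#'
#' @param A,B named per-gene nonnegative vectors.
#' @return a [titration_set()] with `C = 0.75 A + 0.25 B`,
#'   `D = 0.25 A + 0.75 B`.
#' @export
exact_titration_set <- function(A, B) {
  titration_set(A = A, B = B, C = 0.75 * A + 0.25 * B, D = 0.25 * A + 0.75 * B)
}
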