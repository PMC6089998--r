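make_nb_counts <- function(genes = 200, samples = 4, seed = 21, depth_spread = TRUE) {
  set.seed(seed)
  mu <- rlnorm(genes, 3, 1.3)
  lib <- if (depth_spread) runif(samples, 0.5, 2) else rep(1, samples)
  m <- sapply(seq_len(samples), function(j)
    rnbinom(genes, mu = mu * lib[j], size = 20))
  dimnames(m) <- list(sprintf("g%04d", seq_len(genes)),
                      paste0("s", seq_len(samples)))
  expression_matrix(m, scale = "counts")
}

test_that("total-count normalization equalizes library sizes", {
  m <- expression_matrix(
    matrix(c(30, 70, 120, 80), 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
    scale = "counts")
  out <- normalize_total_count(m)
  expect_equal(out$factors$factor, c(100 / 150, 200 / 150))
  expect_equal(unname(colSums(out$matrix)), c(150, 150))

  # equal totals: identity; single sample: factor 1
  eq <- expression_matrix(matrix(c(1, 9, 4, 6), 2,
                                 dimnames = list(c("a", "b"), c("s1", "s2"))),
                          scale = "counts")
  expect_equal(unclass(normalize_total_count(eq)$matrix)[, ], unclass(eq)[, ])
  single <- expression_matrix(matrix(c(3, 4), 2,
                                     dimnames = list(c("a", "b"), "s1")),
                              scale = "counts")
  expect_equal(normalize_total_count(single)$factors$factor, 1)

  zero <- expression_matrix(matrix(c(1, 2, 0, 0), 2,
                                   dimnames = list(c("a", "b"), c("s1", "s2"))),
                            scale = "counts")
  expect_error(normalize_total_count(zero), "s2")

  big <- make_nb_counts(500, 6)
  cs <- colSums(normalize_total_count(big)$matrix)
  expect_lt(max(cs) - min(cs), 1e-9 * mean(cs))
})

test_that("median-of-ratios matches its definition and the DESeq2 estimator", {
  # sample2 = 2 x sample1: factors proportional to (1/sqrt(2), sqrt(2))
  base <- c(g1 = 10, g2 = 55, g3 = 200, g4 = 31, g5 = 8)
  m <- expression_matrix(cbind(s1 = base, s2 = 2 * base) + 0,
                         scale = "counts")
  out <- normalize_median_of_ratios(m)
  expect_equal(out$factors$factor, c(1 / sqrt(2), sqrt(2)))
  expect_equal(unclass(out$matrix)[, "s1"], unclass(out$matrix)[, "s2"])

  ident <- expression_matrix(cbind(s1 = base, s2 = base) + 0, scale = "counts")
  rownames(ident) <- paste0("g", 1:5)
  expect_equal(normalize_median_of_ratios(ident)$factors$factor, c(1, 1))

  # brute-force oracle on a random matrix
  set.seed(3)
  r <- matrix(rpois(30, 40) + 1, 10, 3,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  rm_ <- expression_matrix(r + 0, scale = "counts")
  fact <- normalize_median_of_ratios(rm_)$factors$factor
  geo <- apply(r, 1, function(x) prod(x)^(1 / length(x)))
  brute <- apply(r / geo, 2, median)
  expect_equal(fact, unname(brute))

  skip_if_not_installed("DESeq2")
  big <- make_nb_counts(300, 5)
  ours <- normalize_median_of_ratios(big)$factors$factor
  deseq <- DESeq2::estimateSizeFactorsForMatrix(unclass(big))
  expect_equal(ours, unname(deseq), tolerance = 1e-10)
})

test_that("median-of-ratios leaves unit median ratios to the reference profile", {
  big <- make_nb_counts(400, 5, seed = 77)
  raw <- unclass(big)
  norm <- unclass(normalize_median_of_ratios(big)$matrix)
  pos <- rowSums(raw > 0) == ncol(raw)
  geo <- exp(rowMeans(log(raw[pos, ])))   # the estimator's pseudo-reference
  med <- apply(norm[pos, ] / geo, 2, median)
  expect_equal(unname(med), rep(1, ncol(norm)), tolerance = 1e-9)
})

test_that("TMM factors agree with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  for (seed in c(1, 2, 3)) {
    big <- make_nb_counts(800, 6, seed = seed)
    ours <- normalize_tmm(big)$tmm_factors$factor
    theirs <- edgeR::calcNormFactors(unclass(big), method = "TMM")
    expect_equal(ours, unname(theirs), tolerance = 1e-6)
  }
})

test_that("TMM handles scaled and identical samples analytically", {
  base <- rpois(300, 60) + 1
  names(base) <- sprintf("g%03d", seq_along(base))
  m <- expression_matrix(cbind(s1 = base, s2 = 2 * base) + 0, scale = "counts")
  out <- normalize_tmm(m)
  expect_equal(unclass(out$matrix)[, "s1"], unclass(out$matrix)[, "s2"],
               tolerance = 1e-9)
  ident <- expression_matrix(cbind(s1 = base, s2 = base) + 0, scale = "counts")
  expect_equal(normalize_tmm(ident)$factors$factor, c(1, 1))
})

test_that("normalizations are row-permutation invariant and column-equivariant", {
  big <- make_nb_counts(300, 4, seed = 12)
  perm <- sample(nrow(big))
  permuted <- expression_matrix(unclass(big)[perm, ], scale = "counts")
  for (method in c("total_count", "median_of_ratios", "tmm")) {
    f1 <- normalize_counts(big, method)$factors$factor
    f2 <- normalize_counts(permuted, method)$factors$factor
    expect_equal(f1, f2, tolerance = 1e-12, label = method)
  }
  # scaling one column by c multiplies its factor, relative to the others, by c
  scaled <- unclass(big); scaled[, 2] <- scaled[, 2] * 3
  scaled <- expression_matrix(scaled, scale = "counts")
  for (method in c("total_count", "median_of_ratios")) {
    f1 <- normalize_counts(big, method)$factors$factor
    f2 <- normalize_counts(scaled, method)$factors$factor
    expect_equal((f2[2] / f2[1]) / (f1[2] / f1[1]), 3, tolerance = 1e-9,
                 label = method)
  }
})

test_that("long-gene beta deviation persists under all three normalizations", {
  ann <- fixture_annotation(3000, seed = 301)
  sim <- simulate_titration(ann, depth = 2e6, n_reps = 4, bias = "on",
                            seed = 55)
  params <- binning_params(bin_size = 200, shift = 100)
  # length-dependent part of the curve: long-window level minus short-window
  # level (normalization can shift the whole curve but not remove the trend)
  devs <- sapply(c("total_count", "median_of_ratios", "tmm"), function(meth) {
    tset <- make_titration_set(sim$counts, sim$sample_type, method = meth)
    curve <- beta_length_curve(beta_ratio(tset), ann, params)
    long <- curve$mean_length_bp > 1e5
    short <- curve$mean_length_bp < 5e4
    mean(curve$mean_log2fc[long]) - mean(curve$mean_log2fc[short])
  })
  expect_true(all(devs > 0))  # long genes overestimated under every method
  expect_true(all(devs > 0.05))
})
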