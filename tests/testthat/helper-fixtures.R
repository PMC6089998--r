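# Shared fixtures, generated in code. The annotation cache avoids
# re-drawing the same gene universe in every test file.

.fixture_cache <- new.env(parent = emptyenv())

fixture_annotation <- function(n = 5000, frac_long = 0.13, seed = 101) {
  key <- paste(n, frac_long, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_lengths(n, frac_long, seed = seed)
  .fixture_cache[[key]]
}

# tiny deterministic counts matrix
tiny_counts <- function(genes = 3, samples = 2, seed = 5, scale = "counts") {
  set.seed(seed)
  m <- matrix(rpois(genes * samples, 50), nrow = genes,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("s", seq_len(samples))))
  expression_matrix(m, scale = scale)
}

# annotation where gene ids g00001.. are already length-sorted
sorted_annotation <- function(n, min_bp = 2000, max_bp = 900000) {
  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             gene_length = round(seq(min_bp, max_bp, length.out = n)),
             stringsAsFactors = FALSE)
}

# independent brute-force BH step-up oracle: q_i = min_{j >= i} p_(j) * m / j
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(1, ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# enumeration oracle for the two-sided rank-sum test (no ties)
enumerate_wmw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  center <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  })
  mean(abs(us - center) >= abs(u_obs - center))
}
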