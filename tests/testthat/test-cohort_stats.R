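ann_for <- function(values_long, values_short) {
  n1 <- length(values_long); n2 <- length(values_short)
  data.frame(gene_id = c(paste0("L", seq_len(n1)), paste0("S", seq_len(n2))),
             gene_length = c(rep(2e5, n1), rep(2e4, n2)),
             stringsAsFactors = FALSE)
}

named_values <- function(values_long, values_short) {
  setNames(c(values_long, values_short),
           c(paste0("L", seq_along(values_long)),
             paste0("S", seq_along(values_short))))
}

test_that("small-sample Wilcoxon uses the exact enumeration distribution", {
  ann <- ann_for(c(1, 2), c(3, 4))
  out <- long_short_test(named_values(c(1, 2), c(3, 4)), ann)
  expect_true(out$exact)
  expect_equal(out$p_value, 1 / 3)   # 2/6 arrangements as extreme

  # identical multisets in the two groups: p = 1
  ann2 <- ann_for(c(1, 2), c(1, 2))
  out2 <- long_short_test(named_values(c(1, 2), c(1, 2)), ann2)
  expect_equal(out2$p_value, 1)
})

test_that("exact Wilcoxon p equals the enumeration oracle for all small cases", {
  set.seed(77)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample.int(1000, n1 + n2)   # no ties
    x <- vals[seq_len(n1)]; y <- vals[n1 + seq_len(n2)]
    ann <- ann_for(x, y)
    out <- long_short_test(named_values(x, y), ann)
    expect_true(out$exact)
    expect_equal(out$p_value, enumerate_wmw_p(x, y), tolerance = 1e-12,
                 info = sprintf("case %d (n1=%d, n2=%d)", i, n1, n2))
    expect_equal(out$statistic, sum(outer(x, y, ">")))
  }
})

test_that("a clear location shift in long genes is detected", {
  set.seed(12)
  x <- rnorm(50) + 1; y <- rnorm(50)
  out <- long_short_test(named_values(x, y), ann_for(x, y))
  expect_false(out$exact)   # n > 8 uses the corrected normal approximation
  expect_lt(out$p_value, 0.01)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(out$p_value, ref$p.value)
})

test_that("DE quadrants classify by strict 100 kb threshold and direction", {
  ann <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    gene_length = c(150000, 150000, 50000, 50000, 100000))
  fc <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   log2fc = c(0.5, -0.5, 0.5, -0.5, 0.7),
                   de_flag = TRUE)
  q <- de_quadrants(fc, ann)
  # gene e sits exactly on the boundary: counted short
  expect_equal(q$counts,
               c(long_up = 1, long_down = 1, short_up = 2, short_down = 1))

  empty <- de_quadrants(fc[fc$de_flag == FALSE, ], ann)
  expect_equal(sum(empty$counts), 0)

  # order invariance and flagged-count accounting
  perm <- fc[sample(nrow(fc)), ]
  expect_equal(de_quadrants(perm, ann)$counts, q$counts)
  fc2 <- rbind(fc, data.frame(gene_id = "zz", log2fc = 1, de_flag = TRUE),
               data.frame(gene_id = "a0", log2fc = 0, de_flag = TRUE))
  ann2 <- rbind(ann, data.frame(gene_id = "a0", gene_length = 1000))
  q2 <- de_quadrants(fc2, ann2)
  expect_equal(q2$n_unannotated, 1)  # zz missing from annotation
  expect_equal(q2$n_zero_fc, 1)      # a0 flagged but fc exactly 0
  expect_equal(sum(q2$counts), sum(fc2$de_flag) - 2)
})

test_that("concordance chi-square equals the brute-force Pearson statistic", {
  set.seed(9)
  n <- 60
  rows <- data.frame(gene_id = sprintf("g%02d", 1:n),
                     log2fc_platform1 = rnorm(n),
                     log2fc_platform2 = rnorm(n),
                     is_long = rep(c(TRUE, FALSE), c(20, 40)))
  out <- concordance_test(rows)
  tab <- out$table
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  brute <- sum((tab - expected)^2 / expected)
  expect_equal(out$statistic, brute, tolerance = 1e-10)
  expect_equal(out$threshold, median(out$rows$abs_diff))

  # perfect 2x2 association: chi-square equals n
  rows2 <- data.frame(gene_id = sprintf("h%02d", 1:40),
                      abs_diff = rep(c(2, 0.1), c(20, 20)),
                      is_long = rep(c(TRUE, FALSE), c(20, 20)))
  out2 <- concordance_test(rows2, diff_threshold = 1)
  expect_equal(out2$statistic, 40)

  # degenerate table: every gene above the threshold
  rows3 <- transform(rows2, abs_diff = 2 + seq_len(40))
  expect_error(concordance_test(rows3, diff_threshold = 1), "degenerate")
  expect_error(concordance_test(rows2[1:10, ], diff_threshold = 1), "20")
})

test_that("concordance p-values are roughly uniform when no association exists", {
  set.seed(123)
  ps <- replicate(200, {
    rows <- data.frame(gene_id = sprintf("g%02d", 1:60),
                       abs_diff = rexp(60),
                       is_long = sample(rep(c(TRUE, FALSE), c(20, 40))))
    concordance_test(rows)$p_value
  })
  # null p-values are not enriched at the small end (the median-split
  # table is discrete, so we check the rejection rate, not exact uniformity)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps > 0.5), 0.25)
})
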