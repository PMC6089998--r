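test_that("expression matrices round-trip through TSV and CSV", {
  m <- tiny_counts(genes = 6, samples = 4)
  for (ext in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_expression(m, path)
    back <- read_expression(path, scale = "counts")
    expect_equal(unclass(back)[, ], unclass(m)[, ] + 0)  # values bit-exact
  }
  # real-valued matrices survive to at least 12 significant digits
  r <- expression_matrix(unclass(m) * pi, scale = "log2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(r, path)
  back <- read_expression(path, scale = "log2")
  expect_equal(unclass(back)[, ], unclass(r)[, ], tolerance = 1e-12)
})

test_that("matrix validation rejects malformed input with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression(path, scale = "counts"), "gA")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t3\toops"), path)
  expect_error(read_expression(path, scale = "counts"), "gB.*s2|s2.*gB")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t-3\t4"), path)
  expect_error(read_expression(path, scale = "counts"), "egative")
  expect_silent(read_expression(path, scale = "log2"))

  vals <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s", "s")))
  expect_error(expression_matrix(vals), "duplicate sample")
  vals2 <- matrix(c(1, NA, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(vals2), "missing")
})

test_that("probe collapsing averages log2 values per gene and refuses counts", {
  m <- expression_matrix(
    matrix(c(4, 6, 7, 5, 3, 2), nrow = 3, byrow = FALSE,
           dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))),
    scale = "log2", platform = "array")
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- collapse_features(m, map)
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(unclass(out)["gA", "s1"], (4 + 6) / 2)  # two probes -> mean
  expect_equal(unclass(out)["gB", ], unclass(m)["p3", ])  # single probe identity

  cts <- tiny_counts()
  expect_error(collapse_features(cts, c(g1 = "x", g2 = "x", g3 = "y")),
               "counts")
})

test_that("collapsing matches a brute-force per-gene mean on random features", {
  set.seed(42)
  n_feat <- 100
  feats <- sprintf("f%03d", seq_len(n_feat))
  genes <- sample(sprintf("G%02d", 1:20), n_feat, replace = TRUE)
  vals <- matrix(rnorm(n_feat * 3, 8, 2), nrow = n_feat,
                 dimnames = list(feats, c("a", "b", "c")))
  # a few unmapped features must be dropped and reported
  map <- setNames(genes, feats)
  map_in <- map[seq_len(n_feat - 5)]
  m <- expression_matrix(vals, scale = "log2", platform = "array")
  out <- collapse_features(m, map_in)
  rep <- attr(out, "collapse_report")
  expect_equal(rep$n_unmapped_dropped, 5)
  expect_equal(rep$n_genes_out, length(unique(map_in)))
  for (g in sample(unique(map_in), 5)) {
    members <- names(map_in)[map_in == g]
    expect_equal(unclass(out)[g, ],
                 colMeans(vals[members, , drop = FALSE]))
  }
  # grand mean equals mean of per-gene probe means
  per_gene <- tapply(rowMeans(vals[names(map_in), ]), map_in, mean)
  expect_equal(mean(out), mean(per_gene))
})

test_that("duplicate length records resolve to the longest annotated length", {
  rec <- data.frame(gene_id = c("gX", "gX", "gY"),
                    gene_length = c(50000, 80000, 1200))
  out <- resolve_lengths(rec)
  expect_equal(out$gene_length[out$gene_id == "gX"], 80000)
  expect_equal(out$gene_length[out$gene_id == "gY"], 1200)

  set.seed(9)
  rec2 <- data.frame(gene_id = sample(c("a", "b", "c"), 25, replace = TRUE),
                     gene_length = sample.int(1e6, 25))
  out2 <- resolve_lengths(rec2)
  brute <- tapply(rec2$gene_length, rec2$gene_id, max)
  expect_equal(unname(setNames(out2$gene_length, out2$gene_id)[names(brute)]),
               as.vector(brute))

  expect_error(resolve_lengths(data.frame(gene_id = "a", gene_length = 0)),
               "positive")
})

test_that("control splits are disjoint, deterministic and seed-uniform", {
  ids <- paste0("wt", 1:6)
  cmp <- split_controls(ids, 2, seed = 11)
  expect_s3_class(cmp, "comparison_spec")
  expect_identical(cmp$role, "baseline")
  expect_length(intersect(cmp$group1, cmp$group2), 0)
  expect_length(cmp$group1, 2)
  expect_identical(split_controls(ids, 2, seed = 11), cmp)
  expect_error(split_controls(ids[1:3], 2, seed = 1), "at least 4")

  # with 2 controls the only partition (up to side swap) is forced
  cmp2 <- split_controls(c("u", "v"), 1, seed = 3)
  expect_setequal(c(cmp2$group1, cmp2$group2), c("u", "v"))

  # distribution of group1 over 2000 seeds is uniform over the 6 subsets
  ids4 <- letters[1:4]
  keys <- vapply(1:2000, function(s) {
    paste(sort(split_controls(ids4, 2, seed = s)$group1), collapse = "")
  }, character(1))
  tab <- table(keys)
  expect_length(tab, 6)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("annotation files round-trip and resolve duplicates on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tgene_length", "gA\t5000", "gA\t9000", "gB\t200000"),
             path)
  ann <- read_annotation(path)
  expect_equal(ann$gene_length, c(9000, 200000))
  write_annotation(ann, path)
  expect_equal(read_annotation(path), ann)
})
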