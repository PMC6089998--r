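workflow_fixture <- function(dir, effect = -0.58, seed = 7, n = 4,
                             n_genes = 1500) {
  ann <- fixture_annotation(n_genes, seed = 61)
  config <- sim_config(n_replicates = c(case = n, control = n,
                                        ctrlA = n, ctrlB = n),
                       depth = 5e5, effect_spec = c(case = effect),
                       seed = seed)
  sim <- simulate_counts(config, ann)
  counts_path <- file.path(dir, "counts.tsv")
  ann_path <- file.path(dir, "genes.tsv")
  write_expression(sim$matrix, counts_path)
  write_annotation(ann, ann_path)
  grp <- function(g) names(sim$truth$group_of)[sim$truth$group_of == g]
  analysis_config(
    counts = counts_path, annotation = ann_path,
    signal = comparison_spec("case_vs_control", grp("case"), grp("control")),
    baseline = comparison_spec("ctrl_vs_ctrl", grp("ctrlA"), grp("ctrlB"),
                               role = "baseline"),
    params = binning_params(bin_size = 200, shift = 100),
    out_dir = file.path(dir, "out"), seed = seed)
}

test_that("the overlap workflow writes a complete, correct report bundle", {
  dir <- withr::local_tempdir()
  config <- workflow_fixture(dir)
  run <- run_overlap_workflow(config)
  expected <- c("normalized.tsv", "size_factors.tsv", "fc_signal.tsv",
                "fc_baseline.tsv", "windows_signal.tsv", "windows_baseline.tsv",
                "overlap.tsv", "summary.json", "overlap_plot.pdf",
                "overlap_plot_data.tsv")
  expect_true(all(file.exists(file.path(config$out_dir, expected))))
  expect_gt(file.size(file.path(config$out_dir, "overlap_plot.pdf")), 0)

  # a strong long-gene effect yields significant long-gene windows
  summ <- jsonlite::read_json(file.path(config$out_dir, "summary.json"))
  expect_gt(summ$n_significant_long, 0)
  expect_equal(summ$n_windows, nrow(run$result))
  expect_equal(summ$n_significant_long + summ$n_significant_short,
               summ$n_significant)

  # figure sidecar carries exactly the ribbon values
  sidecar <- read.delim(file.path(config$out_dir, "overlap_plot_data.tsv"))
  rib <- ribbon(run$series$signal)
  expect_equal(sidecar$signal_lower, rib$lower, tolerance = 1e-6)
  expect_equal(sidecar$signal_upper, rib$upper, tolerance = 1e-6)
})

test_that("workflow reruns are byte-identical for a fixed seed and config", {
  dir <- withr::local_tempdir()
  config <- workflow_fixture(dir)
  run_overlap_workflow(config)
  tables <- c("normalized.tsv", "fc_signal.tsv", "overlap.tsv", "summary.json")
  first <- lapply(tables, function(f)
    readLines(file.path(config$out_dir, f)))
  run_overlap_workflow(config)
  second <- lapply(tables, function(f)
    readLines(file.path(config$out_dir, f)))
  expect_identical(first, second)
})

test_that("stage errors abort with the stage name and remove partial output", {
  dir <- withr::local_tempdir()
  config <- workflow_fixture(dir)
  config$signal$group1 <- c(config$signal$group1, "ghost_sample")
  expect_error(run_overlap_workflow(config), "read inputs.*ghost_sample")
  expect_length(list.files(config$out_dir), 0)
})

test_that("plot builders respect the significance sentinel", {
  dir <- withr::local_tempdir()
  config <- workflow_fixture(dir, effect = 0)
  run <- run_overlap_workflow(config)
  plots <- plot_overlap(run$result)
  expect_s3_class(plots$curves, "ggplot")
  expect_s3_class(plots$pvalues, "ggplot")
  if (is.na(min_significant_p(run$result))) {
    hline <- vapply(plots$pvalues$layers, function(l)
      inherits(l$geom, "GeomHline"), logical(1))
    expect_false(any(hline))   # no threshold line without significant windows
  }
  # mismatched windows are rejected
  series <- run$series
  series$signal <- series$signal[-1, ]
  expect_error(plot_overlap(run$result, series), "match")
})

test_that("YAML analysis configs round-trip into the workflow", {
  dir <- withr::local_tempdir()
  config <- workflow_fixture(dir)
  yaml_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    counts = config$counts, annotation = config$annotation,
    out_dir = file.path(dir, "out_yaml"),
    normalization = "median_of_ratios", alpha = 0.05, seed = 7,
    binning = list(bin_size = 200, shift = 100),
    signal = list(label = "case_vs_control",
                  group1 = config$signal$group1,
                  group2 = config$signal$group2),
    baseline = list(label = "ctrl_vs_ctrl",
                    group1 = config$baseline$group1,
                    group2 = config$baseline$group2)), yaml_path)
  cfg <- read_analysis_config(yaml_path)
  expect_s3_class(cfg, "analysis_config")
  run <- run_overlap_workflow(cfg)
  expect_true(file.exists(file.path(dir, "out_yaml", "summary.json")))
})
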