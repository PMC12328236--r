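# Benchmark orchestration and CLI.

small_double_world <- function(seed = 23) {
  simulate_dataset(
    synthetic_spec(n_genes = 150, n_singles = 16, n_doubles = 10,
                   cells_per_condition = 400, true_rank = 4,
                   interaction_fraction = 0.02, seed = seed),
    level = "pseudobulk")$dataset
}

test_that("double benchmark produces replicate reports and curves", {
  pb <- small_double_world()
  config <- benchmark_config(pb, "double-holdout", n_replicates = 2,
                             top_n_genes = 100, K = 4,
                             models = c("no-change", "mean", "additive"))
  bench <- run_double_benchmark(config)
  expect_length(bench$replicates, 2)
  for (rep in bench$replicates) {
    expect_identical(sort(unique(rep$report$metrics$model)),
                     c("additive", "mean", "no-change"))
    expect_identical(nrow(rep$report$metrics),
                     3L * length(rep$report$shared))
    # the additive model does not compete in interaction prediction
    expect_false("additive" %in% names(rep$curves))
    expect_setequal(names(rep$curves), c("no-change", "mean"))
  }
  expect_gt(sum(bench$interactions$is_interaction), 0)
  expect_gt(bench$truth_threshold, 0)

  # identical seeds -> bit-identical results
  bench2 <- run_double_benchmark(config)
  expect_identical(bench2$replicates[[1]]$report$metrics,
                   bench$replicates[[1]]$report$metrics)
  expect_identical(bench2$replicates[[2]]$curves[["mean"]]$points,
                   bench$replicates[[2]]$curves[["mean"]]$points)
})

test_that("double benchmark ranks additive < mean < no-change without plants", {
  # a whisper of synergistic signal keeps the interaction truth set
  # non-empty for the curves without disturbing the L2 ordering
  pb <- simulate_dataset(
    synthetic_spec(n_genes = 400, n_singles = 30, n_doubles = 16,
                   cells_per_condition = 100, true_rank = 4,
                   interaction_fraction = 0.01,
                   interaction_classes = c(buffering = 0, synergistic = 1,
                                           opposite = 0), seed = 29),
    level = "pseudobulk")$dataset
  config <- benchmark_config(pb, "double-holdout", n_replicates = 2,
                             top_n_genes = 400, K = 4,
                             models = c("no-change", "mean", "additive"))
  bench <- suppressMessages(run_double_benchmark(config))
  for (rep in bench$replicates) {
    s <- rep$report$summary
    l2 <- setNames(s$l2, s$model)
    expect_lt(l2[["additive"]], l2[["mean"]])
    expect_lt(l2[["mean"]], l2[["no-change"]])
  }
})

test_that("single benchmark: training-PCA linear model beats the mean", {
  pb <- simulate_dataset(
    synthetic_spec(n_genes = 400, n_singles = 40, n_doubles = 2,
                   cells_per_condition = 100, true_rank = 4,
                   effect_scale = 0.25, seed = 31),
    level = "pseudobulk")$dataset
  config <- benchmark_config(pb, "single-holdout", n_replicates = 2,
                             top_n_genes = 400, K = 4,
                             models = c("mean", "linear-pca",
                                        "linear-random"))
  bench <- run_single_benchmark(config)
  expect_length(bench$replicates, 2)
  for (rep in bench$replicates) {
    rel <- rep$report$relative
    lin <- rel[rel$model == "linear-pca", ]
    expect_lt(lin$statistic, 0)
    expect_lt(lin$high, 0)          # CI excludes 0
    # random embeddings still produce finite predictions for all singles
    expect_true(all(is.finite(
      rep$report$metrics$l2[rep$report$metrics$model == "linear-random"])))
  }
})

test_that("unpredictable test perturbations are excluded with a log", {
  pb <- small_double_world(seed = 37)
  # restrict the read-out set so some targets fall outside it
  config <- benchmark_config(pb, "single-holdout", n_replicates = 1,
                             test_fraction = 0.5, top_n_genes = 60, K = 3,
                             models = c("mean", "linear-pca"))
  msgs <- capture_messages(bench <- run_single_benchmark(config))
  rep <- bench$replicates[[1]]
  if (rep$report$n_dropped > 0) {
    expect_true(any(grepl("unpredictable|dropped", msgs)))
    expect_lt(length(rep$report$shared), length(rep$split$test_labels))
  } else {
    succeed("all targets happened to be read-out genes")
  }
})

test_that("benchmark configs round-trip through JSON", {
  dir <- withr::local_tempdir()
  config <- benchmark_config("data.tsv", "double-holdout", seeds = c(5L, 9L),
                             n_replicates = 2, lambda = 0.2, K = 7,
                             out_dir = "out")
  path <- file.path(dir, "config.json")
  write_benchmark_config(config, path)
  config2 <- read_benchmark_config(path)
  expect_identical(config2$seeds, config$seeds)
  expect_identical(config2$lambda, config$lambda)
  expect_identical(config2$K, config$K)
  expect_identical(config2$protocol, config$protocol)
  expect_identical(config_hash(config2), config_hash(config))
})

test_that("external prediction tables are scored as models", {
  pb <- small_double_world(seed = 41)
  doubles <- colnames(pb)[label_type(colnames(pb)) == "double"]
  dir <- withr::local_tempdir()
  ext_path <- file.path(dir, "ext.tsv")
  write_prediction_matrix(predict_additive(pb, doubles), ext_path)
  config <- benchmark_config(
    pb, "double-holdout", n_replicates = 1, top_n_genes = 100, K = 4,
    models = c("no-change", "additive"),
    external_predictions = c(oracle_external = ext_path))
  bench <- run_double_benchmark(config)
  rep <- bench$replicates[[1]]
  expect_true("oracle_external" %in% unique(rep$report$metrics$model))
  m <- rep$report$summary
  expect_equal(m$l2[m$model == "oracle_external"],
               m$l2[m$model == "additive"], tolerance = 1e-10)
})

test_that("the CLI pipeline runs file-to-file", {
  dir <- withr::local_tempdir()
  sim_path <- file.path(dir, "sim.tsv")
  expect_message(perturblm_cli(c(
    "simulate", "--out", sim_path, "--n-genes", "150", "--n-singles", "16",
    "--n-doubles", "10", "--cells", "400", "--rank", "4",
    "--interaction-fraction", "0.02", "--seed", "3")),
    "wrote")
  expect_true(file.exists(sim_path))

  split_path <- file.path(dir, "split.json")
  perturblm_cli(c("split", "--input", sim_path, "--out", split_path,
                  "--protocol", "double-holdout", "--seed", "2"))
  split <- jsonlite::read_json(split_path, simplifyVector = TRUE)
  expect_true(all(label_type(split$test_labels) == "double"))

  fit_prefix <- file.path(dir, "fit")
  perturblm_cli(c("fit", "--input", sim_path, "--split", split_path,
                  "--out", fit_prefix, "--top-n-genes", "150", "--K", "4"))
  expect_true(file.exists(paste0(fit_prefix, ".W.tsv")))

  pred_path <- file.path(dir, "pred.tsv")
  perturblm_cli(c("predict", "--fit", fit_prefix, "--labels",
                  paste(split$test_labels, collapse = ","),
                  "--out", pred_path))
  pred <- read_prediction_matrix(pred_path)
  expect_identical(ncol(pred), length(split$test_labels))

  calls_path <- file.path(dir, "calls.tsv")
  perturblm_cli(c("interactions", "--input", sim_path, "--out", calls_path,
                  "--top-n-genes", "150"))
  calls <- read.delim(calls_path)
  expect_true(all(c("gene", "pair", "delta", "fdr", "class") %in%
                    names(calls)))
  expect_true(all(calls$class[!calls$is_interaction] == "none"))

  eval_dir <- file.path(dir, "eval")
  perturblm_cli(c("evaluate", "--observed", sim_path, "--predictions",
                  paste0("fitpred=", pred_path), "--out", eval_dir,
                  "--top-n-genes", "150"))
  expect_true(file.exists(file.path(eval_dir, "summary.tsv")))

  cfg_path <- file.path(dir, "config.json")
  write_benchmark_config(
    benchmark_config(sim_path, "double-holdout", n_replicates = 1,
                     top_n_genes = 100, K = 4,
                     models = c("no-change", "mean", "additive")),
    cfg_path)
  out_dir <- file.path(dir, "bench")
  perturblm_cli(c("benchmark-double", "--config", cfg_path,
                  "--out", out_dir))
  expect_true(file.exists(file.path(out_dir, "interactions.tsv")))
  expect_true(file.exists(file.path(out_dir, "provenance.json")))
})
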