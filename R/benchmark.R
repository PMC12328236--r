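#' Benchmark configuration
#'
#' Collects every tunable of the two benchmark protocols with the
#' conventional defaults: five replicates for the double-perturbation
#' protocol and two for the single-perturbation protocol, 1000 read-out
#' genes, ridge penalty 0.1, embedding dimension K = 10 and an interaction
#' FDR level of 5%. Every replicate records its own seed (derived from
#' `seeds` or the base seed).
#'
#' @param dataset Path to a dataset readable by [read_dataset()], or a
#'   [pseudobulk_matrix()] / [perturb_dataset()] object.
#' @param protocol `"double-holdout"` or `"single-holdout"`.
#' @param n_replicates Number of split replicates (default 5 for doubles,
#'   2 for singles).
#' @param test_fraction Held-out fraction per split.
#' @param top_n_genes Read-out gene count (default 1000).
#' @param lambda Ridge penalty (default 0.1).
#' @param K Embedding dimension (default 10).
#' @param fdr_level Interaction-calling FDR level (default 0.05).
#' @param seeds Integer vector of per-replicate seeds (default
#'   `seq_len(n_replicates)`).
#' @param models Character vector of built-in models to run; subsets of
#'   `c("no-change", "mean", "additive", "linear-pca", "linear-random")`.
#' @param external_predictions Named character vector of paths to external
#'   genes x perturbations prediction tables, scored as additional models.
#' @param out_dir Output directory for report files.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(dataset,
                             protocol = c("double-holdout", "single-holdout"),
                             n_replicates = NULL, test_fraction = NULL,
                             top_n_genes = 1000L, lambda = 0.1, K = 10L,
                             fdr_level = 0.05, seeds = NULL,
                             models = NULL, external_predictions = character(),
                             out_dir = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(n_replicates)) {
    n_replicates <- if (protocol == "double-holdout") 5L else 2L
  }
  if (is.null(test_fraction)) {
    test_fraction <- if (protocol == "double-holdout") 0.5 else 0.2
  }
  if (is.null(seeds)) seeds <- seq_len(n_replicates)
  stopifnot(length(seeds) == n_replicates)
  if (is.null(models)) {
    models <- if (protocol == "double-holdout") {
      c("no-change", "mean", "additive", "linear-pca")
    } else {
      c("mean", "linear-pca", "linear-random")
    }
  }
  structure(
    list(dataset = dataset, protocol = protocol,
         n_replicates = as.integer(n_replicates),
         test_fraction = test_fraction, top_n_genes = as.integer(top_n_genes),
         lambda = lambda, K = as.integer(K), fdr_level = fdr_level,
         seeds = as.integer(seeds), models = models,
         external_predictions = external_predictions, out_dir = out_dir),
    class = "benchmark_config"
  )
}

#' Read / write a benchmark configuration
#'
#' Configurations round-trip through a JSON text file (nested key-value
#' structure); the dataset is referenced by path.
#'
#' @param config A [benchmark_config()] with a path-valued `dataset`.
#' @param path JSON file path.
#' @return `read_benchmark_config()` returns a [benchmark_config()].
#' @export
write_benchmark_config <- function(config, path) {
  stopifnot(inherits(config, "benchmark_config"), is.character(config$dataset))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_benchmark_config
#' @export
read_benchmark_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  benchmark_config(
    dataset = x$dataset, protocol = x$protocol,
    n_replicates = x$n_replicates, test_fraction = x$test_fraction,
    top_n_genes = x$top_n_genes, lambda = x$lambda, K = x$K,
    fdr_level = x$fdr_level, seeds = x$seeds, models = x$models,
    external_predictions = unlist(x$external_predictions) %||% character(),
    out_dir = x$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  # provenance fingerprint of the run plan (no cryptographic intent)
  s <- jsonlite::toJSON(unclass(config)[setdiff(names(config), "dataset")],
                        auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 100000000
}

resolve_dataset <- function(config) {
  ds <- config$dataset
  if (is.character(ds)) ds <- read_dataset(ds)
  if (inherits(ds, "perturb_dataset")) ds <- pseudobulk(ds)
  stopifnot(is_pseudobulk(ds))
  ds
}

log_msg <- function(...) message("[perturblm] ", ...)

# Fit/predict every configured model for one replicate. Returns a named list
# of prediction_matrix objects over `test` labels (genes restricted later).
replicate_predictions <- function(config, pb, split, readout) {
  train_pb <- subset_conditions(pb, split$train_labels)
  test <- split$test_labels
  preds <- list()
  for (m in config$models) {
    preds[[m]] <- switch(m,
      "no-change" = predict_no_change(pb, test),
      "mean" = predict_mean(train_pb, test),
      "additive" = predict_additive(pb, test),
      "linear-pca" = {
        G <- pca_gene_embedding(subset_genes(train_pb, readout), config$K)
        P <- tryCatch(perturbation_rows(G, split$train_labels),
                      perturblm_unpredictable = function(e) e)
        if (inherits(P, "condition")) {
          # restrict training to embeddable conditions
          keep <- setdiff(split$train_labels, P$labels)
          P <- perturbation_rows(G, keep)
          fit <- fit_linear_model(
            subset_genes(subset_conditions(pb, keep), readout),
            embedding_pair(G, P, "pca"), config$lambda)
        } else {
          fit <- fit_linear_model(subset_genes(train_pb, readout),
                                  embedding_pair(G, P, "pca"), config$lambda)
        }
        predictable <- test[vapply(label_targets(test), function(t)
          all(t %in% rownames(G)), logical(1))]
        if (length(predictable) < length(test)) {
          log_msg(length(test) - length(predictable),
                  " test perturbation(s) unpredictable for linear-pca")
        }
        if (length(predictable) == 0L) NULL else
          predict_linear_model(fit, predictable)
      },
      "linear-random" = {
        G <- random_embedding(readout, config$K, seed = config$seeds[1] + 7777L)
        P <- perturbation_rows(G, split$train_labels)
        fit <- fit_linear_model(subset_genes(train_pb, readout),
                                embedding_pair(G, P, "random"), config$lambda)
        predictable <- test[vapply(label_targets(test), function(t)
          all(t %in% rownames(G)), logical(1))]
        if (length(predictable) == 0L) NULL else
          predict_linear_model(fit, predictable)
      },
      stop("unknown model: ", m)
    )
  }
  for (nm in names(config$external_predictions)) {
    path <- config$external_predictions[[nm]]
    tab <- utils::read.delim(path, check.names = FALSE)
    M <- as.matrix(tab[, -1, drop = FALSE])
    rownames(M) <- tab[[1]]
    colnames(M) <- canonicalize_labels(colnames(M))
    have <- intersect(test, colnames(M))
    if (length(have) > 0L) {
      preds[[nm]] <- prediction_matrix(M[, have, drop = FALSE], model = nm)
    } else {
      log_msg("external model '", nm, "' covers no test perturbation")
    }
  }
  preds[!vapply(preds, is.null, logical(1))]
}

#' Run the double-perturbation benchmark
#'
#' For each replicate: draw a double-holdout split, fit and predict every
#' configured model (plus external prediction files), evaluate L2 and
#' Pearson-delta metrics on the read-out genes, derive the interaction truth
#' set from an empirical-null fit of the full-data deviations, and compute
#' one FDP-TPR curve per model (the additive model is excluded from the
#' curves: it cannot predict interactions by construction). A failing
#' replicate is logged and skipped, not fatal.
#'
#' @param config A [benchmark_config()] with `protocol = "double-holdout"`.
#' @return An object of class `double_benchmark`: list with `replicates`
#'   (per-replicate evaluation reports and curves), `interactions` (the
#'   full-data calls), `config_hash` and `seeds`. Written to
#'   `config$out_dir` as tab-separated tables when set.
#' @export
run_double_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"),
            config$protocol == "double-holdout")
  pb <- resolve_dataset(config)
  readout <- top_expressed_genes(pb, config$top_n_genes)
  type <- label_type(colnames(pb), pb_sep(pb), pb_control(pb))
  doubles <- colnames(pb)[type == "double"]

  # full-data interaction truth set (pooled over all pairs and genes)
  add_all <- predict_additive(pb, doubles)
  deltas <- delta_matrix(subset_genes(subset_conditions(pb, doubles),
                                      readout)[readout, doubles],
                         add_all[readout, doubles])
  null_fit <- fit_empirical_null(as.numeric(deltas))
  calls <- call_interactions(deltas, null_fit, config$fdr_level)
  u <- tryCatch(truth_threshold_from_calls(calls), error = function(e) {
    log_msg("no interactions at FDR ", config$fdr_level,
            "; FDP-TPR curves skipped")
    NA_real_
  })

  replicates <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    seed <- config$seeds[r]
    res <- tryCatch({
      split <- make_double_split(pb, config$test_fraction, seed)
      preds <- replicate_predictions(config, pb, split, readout)
      preds_ro <- lapply(preds, function(p) {
        prediction_matrix(unclass(p)[readout, , drop = FALSE],
                          model = prediction_model(p))
      })
      report <- evaluate_models(
        preds_ro, subset_genes(pb, readout), genes = readout,
        baseline = if ("additive" %in% names(preds_ro)) "additive" else NULL,
        seed = seed)
      obs_test <- subset_genes(pb, readout)[readout, report$shared,
                                            drop = FALSE]
      add_test <- add_all[readout, report$shared, drop = FALSE]
      curves <- if (is.na(u)) list() else lapply(
        preds_ro[setdiff(names(preds_ro), "additive")],
        function(p) {
          fdp_tpr_curve(p[, report$shared, drop = FALSE],
                        prediction_matrix(add_test, "additive"),
                        obs_test, u)
        })
      list(seed = seed, split = split, report = report, curves = curves)
    }, error = function(e) {
      log_msg("replicate ", r, " (seed ", seed, ") failed: ",
              conditionMessage(e))
      NULL
    })
    replicates[[r]] <- res
  }

  out <- structure(
    list(replicates = replicates[!vapply(replicates, is.null, logical(1))],
         interactions = calls, truth_threshold = u, null_fit = null_fit,
         readout = readout, config = config,
         config_hash = config_hash(config), seeds = config$seeds),
    class = "double_benchmark"
  )
  if (!is.null(config$out_dir)) write_double_benchmark(out, config$out_dir)
  out
}

write_double_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interaction_calls(bench$interactions,
                          file.path(dir, "interactions.tsv"))
  for (rep in bench$replicates) {
    rep_dir <- file.path(dir, sprintf("replicate_seed%d", rep$seed))
    write_evaluation_report(rep$report, rep_dir)
    for (m in names(rep$curves)) {
      write_fdp_tpr_curve(rep$curves[[m]],
                          file.path(rep_dir, paste0("curve_", m, ".tsv")))
    }
  }
  jsonlite::write_json(
    list(config_hash = bench$config_hash, seeds = bench$seeds,
         truth_threshold = bench$truth_threshold,
         protocol = "double-holdout",
         split = "seeded uniform random holdout"),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the single-perturbation benchmark
#'
#' For each replicate: draw a single-holdout split (a seeded uniform random
#' holdout of single perturbations), fit the configured models, restrict the
#' evaluation to perturbations predicted by every model, and report L2 /
#' Pearson-delta metrics with bootstrap relative-error confidence intervals
#' against the mean baseline.
#'
#' @param config A [benchmark_config()] with `protocol = "single-holdout"`.
#' @return An object of class `single_benchmark`: list with `replicates`,
#'   `config_hash` and `seeds`.
#' @export
run_single_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"),
            config$protocol == "single-holdout")
  pb <- resolve_dataset(config)
  readout <- top_expressed_genes(pb, config$top_n_genes)

  replicates <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    seed <- config$seeds[r]
    res <- tryCatch({
      split <- make_single_split(pb, config$test_fraction, seed)
      preds <- replicate_predictions(config, pb, split, readout)
      preds_ro <- lapply(preds, function(p) {
        prediction_matrix(unclass(p)[readout, , drop = FALSE],
                          model = prediction_model(p))
      })
      report <- evaluate_models(
        preds_ro, subset_genes(pb, readout), genes = readout,
        baseline = if ("mean" %in% names(preds_ro)) "mean" else NULL,
        seed = seed)
      list(seed = seed, split = split, report = report)
    }, error = function(e) {
      log_msg("replicate ", r, " (seed ", seed, ") failed: ",
              conditionMessage(e))
      NULL
    })
    replicates[[r]] <- res
  }
  out <- structure(
    list(replicates = replicates[!vapply(replicates, is.null, logical(1))],
         readout = readout, config = config,
         config_hash = config_hash(config), seeds = config$seeds),
    class = "single_benchmark"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (rep in out$replicates) {
      write_evaluation_report(
        rep$report,
        file.path(config$out_dir, sprintf("replicate_seed%d", rep$seed)))
    }
    jsonlite::write_json(
      list(config_hash = out$config_hash, seeds = out$seeds,
           protocol = "single-holdout",
           split = "seeded uniform random holdout"),
      file.path(config$out_dir, "provenance.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
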