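#' L2 prediction error
#'
#' Euclidean distance between predicted and observed expression vectors,
#' restricted to a read-out gene list (conventionally the 1000 most highly
#' expressed genes in the control condition; see [top_expressed_genes()]).
#'
#' @param predicted,observed Named numeric vectors of expression values.
#' @param genes Optional character vector of read-out gene identifiers; when
#'   given, both vectors are restricted to it (by name) before computing the
#'   distance.
#' @return The distance \eqn{\sqrt{\sum_g (\hat{y}_g - y_g)^2}}.
#' @export
l2_error <- function(predicted, observed, genes = NULL) {
  if (!is.null(genes)) {
    if (is.null(names(predicted)) || is.null(names(observed))) {
      stop("gene restriction requires named vectors", call. = FALSE)
    }
    if (!all(genes %in% names(predicted)) || !all(genes %in% names(observed))) {
      stop("read-out genes missing from prediction or observation",
           call. = FALSE)
    }
    predicted <- predicted[genes]
    observed <- observed[genes]
  }
  if (length(predicted) != length(observed)) {
    stop("misaligned vectors", call. = FALSE)
  }
  sqrt(sum((predicted - observed)^2))
}

#' Pearson delta correlation
#'
#' Pearson correlation between the predicted and observed deviations from
#' control. Unlike the L2 distance it does not penalize predictions that are
#' consistently too small or too large in amplitude: it rewards getting the
#' direction of the expression changes right. When either deviation vector
#' has zero variance (e.g. for the no-change model, whose predicted
#' deviation is identically zero) the correlation is undefined and `NA` is
#' returned with a message, never coerced to 0.
#'
#' @param predicted,observed,control Aligned numeric expression vectors.
#' @return Correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearson_delta <- function(predicted, observed, control) {
  if (length(predicted) != length(observed) ||
      length(observed) != length(control)) {
    stop("misaligned vectors", call. = FALSE)
  }
  dp <- predicted - control
  do <- observed - control
  if (stats::sd(dp) == 0 || stats::sd(do) == 0) {
    message("pearson_delta undefined (zero-variance deviation); returning NA")
    return(NA_real_)
  }
  stats::cor(dp, do)
}

#' FDP-TPR curve for interaction predictions
#'
#' Measures how well a model's predicted deviations from the additive
#' expectation recover the true interactions. All N = genes x pairs entries
#' are ranked by the absolute difference between prediction and additive
#' expectation (descending, ties by index). Truth is the indicator that the
#' observed value deviates from the additive expectation by at least `u`.
#' For every prefix length l, the false discovery proportion among the first
#' l ranked entries and the true-positive rate (recall) are computed; the
#' reported curve orders points by FDP and takes the running maximum of TPR,
#' so TPR is non-decreasing along the FDP axis.
#'
#' @param predicted A [prediction_matrix()] (genes x pairs).
#' @param additive The aligned additive-expectation [prediction_matrix()].
#' @param observed The aligned observed expression matrix.
#' @param u Positive truth threshold on `|observed - additive|`; must be
#'   attained by at least one entry.
#' @return An object of class `fdp_tpr_curve`: list with `u`, `N`, the
#'   ranking `order`, per-prefix `fdp` and `tpr`, and the final curve
#'   `points` (data.frame with columns `fdp`, `tpr`).
#' @export
fdp_tpr_curve <- function(predicted, additive, observed, u) {
  pred <- unclass(as.matrix(predicted))
  add <- unclass(as.matrix(additive))
  obs <- unclass(as.matrix(observed))
  if (!identical(dim(pred), dim(add)) || !identical(dim(pred), dim(obs))) {
    stop("dimension mismatch", call. = FALSE)
  }
  truth <- abs(as.numeric(obs) - as.numeric(add)) >= u
  if (!any(truth)) {
    stop("truth threshold u exceeds every observed deviation", call. = FALSE)
  }
  N <- length(truth)
  score <- abs(as.numeric(pred) - as.numeric(add))
  j <- order(-score, seq_len(N))
  hits <- cumsum(truth[j])
  l <- seq_len(N)
  fdp <- (l - hits) / l
  tpr <- hits / sum(truth)
  s <- order(fdp, l)
  points <- data.frame(fdp = fdp[s], tpr = cummax(tpr[s]))
  structure(
    list(u = u, N = N, order = j, fdp = fdp, tpr = tpr, points = points),
    class = "fdp_tpr_curve"
  )
}

#' @export
print.fdp_tpr_curve <- function(x, ...) {
  cat("fdp_tpr_curve: N = ", x$N, ", u = ", format(x$u), ", TPR at FDP<=0.2: ",
      sprintf("%.3f", max(c(0, x$points$tpr[x$points$fdp <= 0.2]))),
      "\n", sep = "")
  invisible(x)
}

#' Truth threshold from FDR-controlled interaction calls
#'
#' Bridges the empirical-null interaction calls to the FDP-TPR machinery:
#' the truth threshold `u` is the smallest absolute deviation among the
#' flagged interactions, so that the indicator `|delta| >= u` reproduces the
#' called set whenever the calls are monotone in `|delta|`.
#'
#' @param calls An `interaction_calls` data.frame from [call_interactions()].
#' @return The threshold `u` (positive scalar).
#' @export
truth_threshold_from_calls <- function(calls) {
  stopifnot(is.data.frame(calls), "is_interaction" %in% names(calls))
  flagged <- calls$delta[calls$is_interaction]
  if (length(flagged) == 0L) stop("no flagged interaction calls", call. = FALSE)
  min(abs(flagged))
}

#' Bootstrap relative-error confidence interval
#'
#' Compares a model's per-perturbation errors against a baseline's by the
#' mean relative error \eqn{\mathrm{mean}_p(e^{model}_p / e^{baseline}_p - 1)}
#' (zero when the model matches the baseline, negative when it is better),
#' with a percentile confidence interval from seeded paired bootstrap
#' resampling over perturbations. The `contains_zero` flag mirrors the
#' convention of de-emphasizing differences whose interval spans zero.
#'
#' @param errors_model,errors_baseline Paired numeric vectors of
#'   per-perturbation errors; baseline errors must be strictly positive.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A list with `statistic`, `low`, `high`, `contains_zero`,
#'   `n_boot`, `seed`, `n`.
#' @export
bootstrap_relative_error <- function(errors_model, errors_baseline,
                                     n_boot = 1000L, seed = 1L,
                                     level = 0.95) {
  stopifnot(length(errors_model) == length(errors_baseline),
            length(errors_model) >= 1L)
  if (any(errors_baseline <= 0)) {
    stop("baseline error must be > 0 for every perturbation", call. = FALSE)
  }
  ratios <- errors_model / errors_baseline - 1
  statistic <- mean(ratios)
  n <- length(ratios)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(ratios[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(statistic = statistic, low = ci[1], high = ci[2],
       contains_zero = ci[1] <= 0 && ci[2] >= 0,
       n_boot = as.integer(n_boot), seed = as.integer(seed), n = n)
}

#' Evaluate a set of prediction matrices against observed data
#'
#' Assembles the benchmark report for one split: restricts all models to the
#' perturbations for which every model has a prediction (dropped
#' perturbations are counted and reported), computes per-(model,
#' perturbation) L2 errors over the read-out genes and Pearson delta values,
#' per-model means, and bootstrap relative-error confidence intervals
#' against a designated baseline model.
#'
#' @param predictions Named list of [prediction_matrix()] objects.
#' @param observed A [pseudobulk_matrix()] holding the observed test columns
#'   (and the control column for Pearson delta).
#' @param genes Read-out gene identifiers used for the metrics (default: all
#'   genes of `observed`).
#' @param baseline Name of the baseline model for relative errors (default
#'   `"mean"` if present, else the first model).
#' @param n_boot,seed Bootstrap parameters, see [bootstrap_relative_error()].
#' @return An object of class `evaluation_report`: list with `metrics`
#'   (data.frame model/perturbation/l2/pearson_delta), `summary` (per-model
#'   means), `relative` (bootstrap CI rows vs the baseline), `shared`
#'   (evaluated perturbations) and `n_dropped`.
#' @export
evaluate_models <- function(predictions, observed, genes = NULL,
                            baseline = NULL, n_boot = 1000L, seed = 1L) {
  stopifnot(is.list(predictions), length(predictions) >= 1L,
            !is.null(names(predictions)), is_pseudobulk(observed))
  if (is.null(genes)) genes <- rownames(observed)
  shared <- Reduce(intersect, lapply(predictions, colnames))
  shared <- intersect(shared, colnames(observed))
  all_perts <- unique(unlist(lapply(predictions, colnames)))
  n_dropped <- length(setdiff(all_perts, shared))
  if (length(shared) == 0L) stop("empty shared perturbation set", call. = FALSE)
  if (n_dropped > 0L) {
    message(n_dropped,
            " perturbation(s) dropped: not predicted by every model")
  }
  y0 <- control_profile(observed)[genes]
  metrics <- do.call(rbind, lapply(names(predictions), function(m) {
    pred <- predictions[[m]]
    rows <- lapply(shared, function(p) {
      yhat <- pred[genes, p]
      y <- unclass(observed)[genes, p]
      pd <- suppressMessages(pearson_delta(yhat, y, y0))
      data.frame(model = m, perturbation = p,
                 l2 = l2_error(yhat, y),
                 pearson_delta = pd, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  summary <- stats::aggregate(cbind(l2, pearson_delta) ~ model, data = metrics,
                              FUN = function(x) mean(x, na.rm = TRUE),
                              na.action = stats::na.pass)
  if (is.null(baseline)) {
    baseline <- if ("mean" %in% names(predictions)) "mean"
                else names(predictions)[1]
  }
  base_err <- metrics$l2[metrics$model == baseline]
  relative <- do.call(rbind, lapply(names(predictions), function(m) {
    ci <- bootstrap_relative_error(metrics$l2[metrics$model == m], base_err,
                                   n_boot = n_boot, seed = seed)
    data.frame(model = m, baseline = baseline, statistic = ci$statistic,
               low = ci$low, high = ci$high,
               contains_zero = ci$contains_zero, n_boot = ci$n_boot,
               seed = ci$seed, stringsAsFactors = FALSE)
  }))
  structure(
    list(metrics = metrics, summary = summary, relative = relative,
         shared = shared, n_dropped = n_dropped, genes = genes,
         baseline = baseline),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report: ", length(unique(x$metrics$model)), " models x ",
      length(x$shared), " shared perturbations (", x$n_dropped,
      " dropped)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export an evaluation report to tab-separated files
#'
#' Writes `metrics.tsv`, `summary.tsv` and `relative.tsv` under `dir`, plus
#' a `report.json` with the report metadata (baseline, gene count, dropped
#' perturbations, relative-error statistic definition).
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$relative, file.path(dir, "relative.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(baseline = report$baseline,
               n_genes = length(report$genes),
               n_shared = length(report$shared),
               n_dropped = report$n_dropped,
               relative_statistic = "mean(e_model/e_baseline - 1)")
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Export an FDP-TPR curve as a two-column table
#'
#' @param curve An [fdp_tpr_curve()] result.
#' @param path Output path (TSV with columns `fdp`, `tpr`).
#' @return `path`, invisibly.
#' @export
write_fdp_tpr_curve <- function(curve, path) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
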