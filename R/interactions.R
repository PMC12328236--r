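#' Deviations from the additive expectation
#'
#' Element-wise difference between observed double-perturbation expression
#' and the additive expectation, the raw material for genetic-interaction
#' calling: a (gene, pair) entry deviating further than a Normal null
#' explains is an interaction.
#'
#' @param observed A [pseudobulk_matrix()] or plain matrix of observed
#'   expression (genes x pairs).
#' @param additive A [prediction_matrix()] of additive expectations with the
#'   same genes and pairs.
#' @return A numeric matrix of class `delta_matrix` (genes x pairs).
#' @export
delta_matrix <- function(observed, additive) {
  obs <- unclass(as.matrix(observed))
  add <- unclass(as.matrix(additive))
  if (!identical(dim(obs), dim(add))) stop("dimension mismatch", call. = FALSE)
  if (!is.null(rownames(obs)) && !is.null(rownames(add))) {
    if (!identical(rownames(obs), rownames(add)) ||
        !identical(colnames(obs), colnames(add))) {
      stop("gene/pair labels misaligned between observed and additive",
           call. = FALSE)
    }
  }
  structure(obs - add, class = c("delta_matrix", "matrix", "array"))
}

#' Empirical-null decomposition of deviation values
#'
#' Decomposes the marginal distribution of the pooled deviations into a
#' large central Normal null component and a minority tail component, in the
#' spirit of Efron's empirical-null / local-fdr methodology. The marginal
#' density f is estimated by Poisson regression of histogram counts on a
#' natural-spline basis; the null parameters (delta0, sigma0) come from a
#' maximum-likelihood fit of a truncated Normal to the central region; the
#' null proportion p0 matches the null mass to the observed count in that
#' region. Per-value local fdr and two-sided tail-area Fdr are returned, the
#' latter made monotone (non-increasing outward from the center).
#'
#' @param deltas Numeric vector of deviation values (>= 1000 values with
#'   non-zero spread).
#' @param bins Number of histogram bins for the density fit (default 120).
#' @param df Spline degrees of freedom for the density fit (default 7).
#' @param central Central quantile window used for the truncated-Normal null
#'   fit (default 0.5: the middle 50% of the data).
#' @return An object of class `empirical_null_fit`: list with `delta0`,
#'   `sigma0`, `p0`, density grid (`breaks`, `mids`, `f`), and per-input
#'   `lfdr` and `tail_fdr` (aligned with `deltas`).
#' @export
fit_empirical_null <- function(deltas, bins = 120L, df = 7L, central = 0.5) {
  deltas <- as.numeric(deltas)
  stopifnot(length(deltas) >= 1000L, all(is.finite(deltas)))
  if (stats::sd(deltas) == 0) stop("constant input: no spread", call. = FALSE)
  n <- length(deltas)

  ## marginal density: Poisson spline regression on histogram counts
  rng <- range(deltas)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- hist(deltas, breaks = breaks, plot = FALSE)
  mids <- h$mids
  width <- diff(breaks)[1]
  basis <- splines::ns(mids, df = df)
  # empty outer bins legitimately drive fitted rates to ~0; not a defect
  dens_fit <- withCallingHandlers(
    stats::glm(h$counts ~ basis, family = stats::poisson()),
    warning = function(w) {
      if (grepl("fitted rates numerically 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  f <- as.numeric(stats::fitted(dens_fit)) / (n * width)

  ## null parameters: truncated-Normal MLE on the central window
  qs <- stats::quantile(deltas, c((1 - central) / 2, 1 - (1 - central) / 2),
                        names = FALSE)
  core <- deltas[deltas >= qs[1] & deltas <= qs[2]]
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    mass <- stats::pnorm(qs[2], mu, sigma) - stats::pnorm(qs[1], mu, sigma)
    if (mass <= 0) return(Inf)
    -sum(stats::dnorm(core, mu, sigma, log = TRUE)) + length(core) * log(mass)
  }
  start <- c(stats::median(core), log(stats::sd(deltas)))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  delta0 <- opt$par[1]
  sigma0 <- exp(opt$par[2])
  if (!is.finite(sigma0) || sigma0 < 1e-12 * stats::sd(deltas)) {
    stop("degenerate central fit (sigma0 -> 0)", call. = FALSE)
  }
  null_mass <- stats::pnorm(qs[2], delta0, sigma0) -
    stats::pnorm(qs[1], delta0, sigma0)
  p0 <- min(1, (length(core) / n) / null_mass)

  ## local fdr on the bin grid, interpolated to the input values
  f0_mid <- stats::dnorm(mids, delta0, sigma0)
  lfdr_mid <- pmin(1, p0 * f0_mid / pmax(f, .Machine$double.xmin))
  lfdr <- stats::approx(mids, lfdr_mid, xout = deltas, rule = 2)$y

  ## two-sided tail-area Fdr, monotone non-increasing outward from delta0
  t_abs <- abs(deltas - delta0)
  ord <- order(t_abs)
  emp_tail <- (n - rank(t_abs, ties.method = "min") + 1) / n
  null_tail <- 2 * stats::pnorm(-t_abs / sigma0)
  fdr_raw <- pmin(1, p0 * null_tail / emp_tail)
  fdr_mono <- numeric(n)
  fdr_mono[ord] <- cummin(fdr_raw[ord])

  structure(
    list(delta0 = delta0, sigma0 = sigma0, p0 = p0,
         breaks = breaks, mids = mids, f = f,
         central_window = qs, n = n,
         lfdr = lfdr, tail_fdr = fdr_mono, deltas = deltas),
    class = "empirical_null_fit"
  )
}

#' @export
print.empirical_null_fit <- function(x, ...) {
  cat(sprintf(
    "empirical_null_fit: delta0 = %.4g, sigma0 = %.4g, p0 = %.3f (n = %d)\n",
    x$delta0, x$sigma0, x$p0, x$n))
  invisible(x)
}

#' Call genetic interactions at a target FDR level
#'
#' Flags every (gene, pair) deviation whose two-sided tail-area Fdr is at or
#' below `fdr_level` (default 5%). Calls are returned sorted by absolute
#' deviation, largest first, together with the local fdr for reference.
#'
#' @param deltas A [delta_matrix()].
#' @param fit An [fit_empirical_null()] result computed on the flattened
#'   values of `deltas` (refitted here if omitted).
#' @param fdr_level Target false discovery rate in (0, 1) (default 0.05).
#' @return A data.frame of class `interaction_calls` with columns `gene`,
#'   `pair`, `delta`, `fdr`, `lfdr`, `is_interaction`.
#' @export
call_interactions <- function(deltas, fit = NULL, fdr_level = 0.05) {
  stopifnot(inherits(deltas, "delta_matrix"),
            fdr_level > 0, fdr_level < 1)
  vals <- as.numeric(deltas)
  if (is.null(fit)) fit <- fit_empirical_null(vals)
  stopifnot(inherits(fit, "empirical_null_fit"), length(fit$tail_fdr) ==
              length(vals))
  out <- data.frame(
    gene = rep(rownames(deltas), times = ncol(deltas)),
    pair = rep(colnames(deltas), each = nrow(deltas)),
    delta = vals,
    fdr = fit$tail_fdr,
    lfdr = fit$lfdr,
    is_interaction = fit$tail_fdr <= fdr_level,
    stringsAsFactors = FALSE
  )
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_calls", "data.frame")
  out
}

#' Classify a genetic interaction
#'
#' Classifies an interacting (gene, pair) entry from the two individual log
#' fold changes, the observed double-perturbation LFC and the additive
#' expectation (all relative to control, for one gene):
#' \itemize{
#'   \item `"other"` if the two individual effects have opposite signs;
#'   \item `"opposite"` if the observed double LFC's sign differs from the
#'     shared sign of the individual effects;
#'   \item `"synergistic"` if the observed double LFC exceeds the additive
#'     expectation in magnitude;
#'   \item `"buffering"` if it lies between 0 and the additive expectation
#'     (boundary ties go to buffering).
#' }
#' The classification is invariant to multiplying all four inputs by a
#' positive constant. Vectorized over the four arguments.
#'
#' @param lfc_a,lfc_b Individual single-perturbation LFCs.
#' @param lfc_ab Observed double-perturbation LFC.
#' @param additive_lfc Additive expectation LFC (normally `lfc_a + lfc_b`).
#' @return Character vector of classes.
#' @export
classify_interaction <- function(lfc_a, lfc_b, lfc_ab, additive_lfc) {
  n <- max(length(lfc_a), length(lfc_b), length(lfc_ab), length(additive_lfc))
  lfc_a <- rep_len(lfc_a, n); lfc_b <- rep_len(lfc_b, n)
  lfc_ab <- rep_len(lfc_ab, n); additive_lfc <- rep_len(additive_lfc, n)
  out <- character(n)
  s <- sign(lfc_a)
  opposite_singles <- sign(lfc_a) * sign(lfc_b) < 0
  out[opposite_singles] <- "other"
  same <- !opposite_singles
  flipped <- same & (sign(lfc_ab) * s < 0)
  out[flipped] <- "opposite"
  rest <- same & !flipped
  synergistic <- rest & (abs(lfc_ab) > abs(additive_lfc))
  out[synergistic] <- "synergistic"
  out[rest & !synergistic] <- "buffering"
  out
}

#' Rank predicted interactions by deviation from additivity
#'
#' For a model's prediction matrix, ranks all (gene, pair) entries by the
#' absolute difference between the prediction and the additive expectation,
#' largest first (ties broken by (gene, pair) index order), and flags those
#' exceeding the threshold `D` as predicted interactions.
#'
#' @param predicted A [prediction_matrix()].
#' @param additive The additive-expectation [prediction_matrix()], aligned.
#' @param D Non-negative threshold; entries with difference `> D` are
#'   flagged (with `D = 0` every entry is flagged).
#' @return A data.frame with columns `gene`, `pair`, `predicted_delta`,
#'   `rank`, `flagged`, ordered by rank.
#' @export
rank_predicted_interactions <- function(predicted, additive, D = 0) {
  pred <- unclass(as.matrix(predicted))
  add <- unclass(as.matrix(additive))
  if (!identical(dim(pred), dim(add))) stop("dimension mismatch", call. = FALSE)
  diffs <- abs(pred - add)
  idx <- seq_along(diffs)
  ord <- order(-as.numeric(diffs), idx)
  out <- data.frame(
    gene = rep(rownames(pred), times = ncol(pred))[ord],
    pair = rep(colnames(pred), each = nrow(pred))[ord],
    predicted_delta = (as.numeric(pred) - as.numeric(add))[ord],
    rank = seq_along(ord),
    flagged = if (D == 0) rep(TRUE, length(ord)) else
      as.numeric(diffs)[ord] > D,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write interaction calls to a tab-separated table
#'
#' @param calls An `interaction_calls` data.frame (optionally carrying a
#'   `class` column from [classify_interaction()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
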