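#' Prediction matrix
#'
#' Predicted log-expression for a set of test perturbations: read-out genes
#' in rows, perturbations in columns, with a tag naming the model that
#' produced it.
#'
#' @param values Numeric matrix, genes x perturbations.
#' @param model Model tag (free text, e.g. `"additive"`, `"linear-pca"`).
#' @return An object of class `prediction_matrix`.
#' @export
prediction_matrix <- function(values, model = "unknown") {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)), !is.null(rownames(values)),
            !is.null(colnames(values)), !anyDuplicated(colnames(values)))
  structure(values, model = model,
            class = c("prediction_matrix", class(values)))
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat("prediction_matrix [", attr(x, "model"), "]: ", nrow(x), " genes x ",
      ncol(x), " perturbations\n", sep = "")
  invisible(x)
}

prediction_model <- function(x) attr(x, "model")

#' The 'no change' baseline
#'
#' Predicts, for every test perturbation, exactly the expression observed in
#' the control condition. Uses no perturbation data at all; it is the floor
#' any informative predictor must beat.
#'
#' @param pb A [pseudobulk_matrix()] supplying the control profile.
#' @param test Canonical labels of the perturbations to predict.
#' @return A [prediction_matrix()] whose columns all equal the control.
#' @export
predict_no_change <- function(pb, test) {
  stopifnot(is_pseudobulk(pb), length(test) >= 1L)
  y0 <- control_profile(pb)
  vals <- matrix(y0, nrow = nrow(pb), ncol = length(test),
                 dimnames = list(rownames(pb), test))
  prediction_matrix(vals, model = "no-change")
}

#' The 'mean' baseline
#'
#' Predicts, for every test perturbation, the row-mean vector of the training
#' conditions (the overall average expression across the training set).
#'
#' @param pb_train A [pseudobulk_matrix()] restricted to training conditions.
#' @param test Canonical labels of the perturbations to predict.
#' @return A [prediction_matrix()] whose columns all equal the training row
#'   means.
#' @export
predict_mean <- function(pb_train, test) {
  stopifnot(is_pseudobulk(pb_train), length(test) >= 1L)
  b <- rowMeans(pb_train)
  vals <- matrix(b, nrow = nrow(pb_train), ncol = length(test),
                 dimnames = list(rownames(pb_train), test))
  prediction_matrix(vals, model = "mean")
}

#' The additive model for double perturbations
#'
#' Predicts the expression after a double perturbation of genes A and B as
#' the additive expectation
#' \deqn{\hat{y}^{add} = y^A + y^B - y^\varnothing,}
#' i.e. the control profile plus the sum of the two single-perturbation log
#' fold changes. Only single-perturbation and control data are used.
#'
#' @param pb A [pseudobulk_matrix()] containing the control and the single
#'   perturbations of both targets.
#' @param pairs Canonical labels of double perturbations to predict.
#' @param sep,control Label dialect (defaults from `pb`).
#' @return A [prediction_matrix()] of additive expectations.
#' @export
predict_additive <- function(pb, pairs,
                             sep = pb_sep(pb), control = pb_control(pb)) {
  stopifnot(is_pseudobulk(pb), length(pairs) >= 1L)
  y0 <- control_profile(pb)
  targets <- label_targets(pairs, sep, control)
  if (any(lengths(targets) != 2L)) {
    stop("additive prediction requires double-perturbation labels",
         call. = FALSE)
  }
  singles <- lapply(targets, function(t) {
    vapply(t, make_label, character(1), sep = sep, control = control)
  })
  missing <- setdiff(unique(unlist(singles)), colnames(pb))
  if (length(missing) > 0L) {
    stop("missing single-perturbation column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- vapply(singles, function(s) {
    pb[, s[1]] + pb[, s[2]] - y0
  }, numeric(nrow(pb)))
  vals <- matrix(vals, nrow = nrow(pb),
                 dimnames = list(rownames(pb), pairs))
  prediction_matrix(vals, model = "additive")
}

#' Fit the bilinear ridge linear model
#'
#' Given a training pseudobulk matrix Y (read-out genes x training
#' perturbations), a gene embedding G and a perturbation embedding P, finds
#' the K x L coefficient matrix W by the two-sided ridge normal equations
#' \deqn{W = (G^T G + \lambda I)^{-1} G^T (Y - b) P (P^T P + \lambda I)^{-1},}
#' where b is the vector of row means of Y and \eqn{\lambda \ge 0} is a small
#' ridge penalty for numerical stability (default 0.1). This closed form is
#' the unique minimizer of the two-sided-penalized least-squares objective
#' \deqn{\|Y - b - G W P^T\|_F^2 + \lambda\|G W\|_F^2 + \lambda\|W P^T\|_F^2
#'   + \lambda^2 \|W\|_F^2} and is fully deterministic.
#'
#' @param Y_train A [pseudobulk_matrix()] of training conditions.
#' @param emb An [embedding_pair()]; `G` rows must cover the genes of
#'   `Y_train` and `P` rows its condition columns.
#' @param lambda Ridge penalty, `>= 0` (default 0.1).
#' @return An object of class `linear_model_fit`: list with `W`, `b`,
#'   `lambda` and the aligned `embedding`.
#' @export
fit_linear_model <- function(Y_train, emb, lambda = 0.1) {
  stopifnot(is_pseudobulk(Y_train), inherits(emb, "embedding_pair"),
            lambda >= 0)
  genes <- rownames(Y_train)
  conds <- colnames(Y_train)
  if (!all(genes %in% rownames(emb$G))) {
    stop("gene embedding does not cover all training genes", call. = FALSE)
  }
  if (!all(conds %in% rownames(emb$P))) {
    stop("perturbation embedding does not cover all training conditions",
         call. = FALSE)
  }
  G <- emb$G[genes, , drop = FALSE]
  P <- emb$P[conds, , drop = FALSE]
  b <- rowMeans(Y_train)
  R <- unclass(Y_train) - b
  GtG <- crossprod(G) + lambda * diag(ncol(G))
  PtP <- crossprod(P) + lambda * diag(ncol(P))
  left <- tryCatch(solve(GtG, crossprod(G, R)), error = function(e) {
    stop("singular gene-side system; use lambda > 0 (", conditionMessage(e),
         ")", call. = FALSE)
  })
  W <- tryCatch(t(solve(PtP, t(left %*% P))), error = function(e) {
    stop("singular perturbation-side system; use lambda > 0 (",
         conditionMessage(e), ")", call. = FALSE)
  })
  structure(
    list(W = W, b = b, lambda = lambda,
         embedding = embedding_pair(G, P, source = emb$source)),
    class = "linear_model_fit"
  )
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat("linear_model_fit: W ", nrow(x$W), "x", ncol(x$W), ", lambda ",
      x$lambda, ", embedding source '", x$embedding$source, "'\n", sep = "")
  invisible(x)
}

#' Predict expression from a fitted linear model
#'
#' Computes \eqn{\hat{Y} = G W \tilde{P}^T + b} where \eqn{\tilde{P}} is the
#' embedding of the test perturbations (by default derived from the fitted
#' gene embedding via [perturbation_rows()]).
#'
#' @param fit A `linear_model_fit` from [fit_linear_model()].
#' @param P_test Numeric matrix (test perturbations x L) with canonical
#'   labels as rownames, or a character vector of labels to embed via
#'   [perturbation_rows()] on the fitted `G`.
#' @param sep,control Label dialect used when `P_test` is a label vector.
#' @return A [prediction_matrix()].
#' @export
predict_linear_model <- function(fit, P_test, sep = "+", control = "ctrl") {
  stopifnot(inherits(fit, "linear_model_fit"))
  if (is.character(P_test)) {
    P_test <- perturbation_rows(fit$embedding$G, P_test, sep, control)
  }
  P_test <- as.matrix(P_test)
  if (ncol(P_test) != ncol(fit$W)) {
    stop("P_test has ", ncol(P_test), " columns; expected ", ncol(fit$W),
         call. = FALSE)
  }
  vals <- fit$embedding$G %*% fit$W %*% t(P_test) + fit$b
  dimnames(vals) <- list(rownames(fit$embedding$G), rownames(P_test))
  prediction_matrix(vals, model = paste0("linear-", fit$embedding$source))
}

#' The additive model expressed as a linear model
#'
#' The additive model is a special case of the bilinear linear model: take
#' the gene embedding to be the single-perturbation data itself
#' (`G = Y^single`), the perturbation embedding to be a binary coding with
#' 1s in the rows of the perturbed genes, `W` the identity, and the intercept
#' \eqn{b = -y^\varnothing}. This constructor builds that fit so the
#' equivalence can be exercised directly.
#'
#' @param pb A [pseudobulk_matrix()] with control and single perturbations.
#' @return A `linear_model_fit` whose [predict_linear_model()] on a binary
#'   double coding equals [predict_additive()] exactly.
#' @export
additive_as_linear_model <- function(pb) {
  stopifnot(is_pseudobulk(pb))
  type <- label_type(colnames(pb), pb_sep(pb), pb_control(pb))
  singles <- colnames(pb)[type == "single"]
  if (length(singles) == 0L) stop("no single perturbations in pseudobulk")
  G <- unclass(pb)[, singles, drop = FALSE]
  single_gene <- vapply(label_targets(singles, pb_sep(pb), pb_control(pb)),
                        `[[`, character(1), 1L)
  colnames(G) <- single_gene
  P <- diag(length(singles))
  dimnames(P) <- list(singles, single_gene)
  structure(
    list(W = diag(length(singles)), b = -control_profile(pb), lambda = 0,
         embedding = embedding_pair(G, P, source = "identity")),
    class = "linear_model_fit"
  )
}

#' Binary double-perturbation coding for the additive special case
#'
#' Builds the binary perturbation embedding whose columns correspond to the
#' single-perturbation axes of [additive_as_linear_model()]: row `A+B` has 1
#' in the columns of genes A and B.
#'
#' @param pb The [pseudobulk_matrix()] used for [additive_as_linear_model()].
#' @param pairs Canonical double-perturbation labels.
#' @return Binary matrix (pairs x single-target genes).
#' @export
binary_double_coding <- function(pb, pairs) {
  type <- label_type(colnames(pb), pb_sep(pb), pb_control(pb))
  singles <- colnames(pb)[type == "single"]
  single_gene <- vapply(label_targets(singles, pb_sep(pb), pb_control(pb)),
                        `[[`, character(1), 1L)
  P <- matrix(0, length(pairs), length(singles),
              dimnames = list(pairs, single_gene))
  tg <- label_targets(pairs, pb_sep(pb), pb_control(pb))
  for (i in seq_along(pairs)) {
    if (!all(tg[[i]] %in% single_gene)) {
      stop(unpredictable_condition(pairs[i], "single perturbation missing"))
    }
    P[i, tg[[i]]] <- 1
  }
  P
}

#' Ridge decoder from perturbation-level embeddings to expression
#'
#' Fits, independently per gene, a ridge regression of training expression on
#' perturbation-level embedding coordinates with an unpenalized intercept:
#' the workhorse for scoring external cell/perturbation embeddings that come
#' without a decoder. At `lambda = 0` a minimum-norm least-squares solution
#' is used, so a one-hot embedding reproduces the training columns exactly;
#' as `lambda` grows, predictions shrink to the per-gene training means.
#'
#' @param E_train Numeric matrix, training perturbations x dims, rownames =
#'   canonical labels aligned with `Y_train` columns.
#' @param Y_train A [pseudobulk_matrix()] (or plain genes x conditions
#'   matrix) of training expression.
#' @param lambda Ridge penalty `>= 0`.
#' @return An object of class `ridge_decoder` with coefficient matrix `beta`
#'   (dims x genes), intercept vector and column centers.
#' @export
fit_ridge_decoder <- function(E_train, Y_train, lambda = 0.1) {
  E_train <- as.matrix(E_train)
  Y <- unclass(as.matrix(Y_train))
  if (!is.null(rownames(E_train)) && !is.null(colnames(Y))) {
    if (!setequal(rownames(E_train), colnames(Y))) {
      stop("embedding rows and training conditions do not align", call. = FALSE)
    }
    E_train <- E_train[colnames(Y), , drop = FALSE]
  } else if (nrow(E_train) != ncol(Y)) {
    stop("embedding rows and training conditions do not align", call. = FALSE)
  }
  stopifnot(lambda >= 0)
  center <- colMeans(E_train)
  Ec <- sweep(E_train, 2, center)
  ybar <- rowMeans(Y)
  Rc <- t(Y - ybar)                      # conditions x genes
  XtX <- crossprod(Ec)
  if (lambda > 0) {
    beta <- solve(XtX + lambda * diag(ncol(Ec)), crossprod(Ec, Rc))
  } else {
    # minimum-norm least squares via SVD pseudoinverse
    sv <- svd(Ec)
    pos <- sv$d > max(dim(Ec)) * .Machine$double.eps * max(sv$d, 0)
    dinv <- ifelse(pos, 1 / sv$d, 0)
    beta <- sv$v %*% (dinv * crossprod(sv$u, Rc))
  }
  rownames(beta) <- colnames(Ec)
  structure(
    list(beta = beta, intercept = ybar, center = center, lambda = lambda),
    class = "ridge_decoder"
  )
}

#' @rdname fit_ridge_decoder
#' @param object A `ridge_decoder`.
#' @param E_new Numeric matrix, new perturbations x dims, rownames = labels.
#' @param ... Unused.
#' @return `predict()` returns a [prediction_matrix()] (genes x
#'   perturbations).
#' @export
predict.ridge_decoder <- function(object, E_new, ...) {
  E_new <- as.matrix(E_new)
  stopifnot(ncol(E_new) == nrow(object$beta))
  Ec <- sweep(E_new, 2, object$center)
  vals <- t(Ec %*% object$beta) + object$intercept
  dimnames(vals) <- list(names(object$intercept), rownames(E_new))
  prediction_matrix(vals, model = "ridge-decoder")
}
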