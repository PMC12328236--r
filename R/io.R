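#' Serialize model fits and predictions as text
#'
#' Fits and predictions are exchanged as tab-separated matrices plus a small
#' key-value sidecar (`<prefix>.meta` with `key<TAB>value` lines) recording
#' the model tag, ridge penalty and embedding dimensions, so that runs are
#' reproducible and diffable.
#'
#' @param fit A `linear_model_fit` from [fit_linear_model()].
#' @param prefix Output path prefix; writes `<prefix>.W.tsv`,
#'   `<prefix>.b.tsv`, `<prefix>.G.tsv`, `<prefix>.P.tsv`, `<prefix>.meta`.
#' @return `prefix`, invisibly.
#' @export
write_linear_model_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "linear_model_fit"))
  write_matrix_tsv(fit$W, paste0(prefix, ".W.tsv"))
  write_matrix_tsv(cbind(b = fit$b), paste0(prefix, ".b.tsv"))
  write_matrix_tsv(fit$embedding$G, paste0(prefix, ".G.tsv"))
  write_matrix_tsv(fit$embedding$P, paste0(prefix, ".P.tsv"))
  writeLines(c(
    paste0("model\tlinear-", fit$embedding$source),
    paste0("lambda\t", format(fit$lambda, digits = 17)),
    paste0("K\t", ncol(fit$embedding$G)),
    paste0("L\t", ncol(fit$embedding$P)),
    paste0("source\t", fit$embedding$source)
  ), paste0(prefix, ".meta"))
  invisible(prefix)
}

#' @rdname write_linear_model_fit
#' @return `read_linear_model_fit()` returns the reconstructed
#'   `linear_model_fit`.
#' @export
read_linear_model_fit <- function(prefix) {
  meta <- utils::read.delim(paste0(prefix, ".meta"), header = FALSE,
                            col.names = c("key", "value"))
  kv <- stats::setNames(meta$value, meta$key)
  W <- read_matrix_tsv(paste0(prefix, ".W.tsv"))
  b <- read_matrix_tsv(paste0(prefix, ".b.tsv"))[, 1]
  G <- read_matrix_tsv(paste0(prefix, ".G.tsv"))
  P <- read_matrix_tsv(paste0(prefix, ".P.tsv"))
  structure(
    list(W = unname_cols(W), b = b, lambda = as.numeric(kv[["lambda"]]),
         embedding = embedding_pair(G, P, source = kv[["source"]])),
    class = "linear_model_fit"
  )
}

#' @rdname write_linear_model_fit
#' @param pred A [prediction_matrix()].
#' @param path Output path for the genes x perturbations table.
#' @export
write_prediction_matrix <- function(pred, path) {
  stopifnot(inherits(pred, "prediction_matrix"))
  write_matrix_tsv(unclass(pred), path)
  invisible(path)
}

#' @rdname write_linear_model_fit
#' @param model Model tag attached to a prediction matrix read from disk.
#' @export
read_prediction_matrix <- function(path, model = "external") {
  prediction_matrix(read_matrix_tsv(path), model = model)
}

write_matrix_tsv <- function(M, path) {
  tab <- data.frame(id = rownames(M) %||% seq_len(nrow(M)), M,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- tab[[1]]
  M
}

unname_cols <- function(M) {
  rn <- rownames(M)
  M <- unname(M)
  rownames(M) <- rn
  M
}
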