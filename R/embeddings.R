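#' Embedding pair for the bilinear linear model
#'
#' The linear model represents each read-out gene by a K-dimensional row of
#' the gene embedding `G` and each perturbation by an L-dimensional row of
#' the perturbation embedding `P`. This constructor bundles the two with
#' their identifier lists and a source tag.
#'
#' @param G Numeric matrix, read-out genes x K, rownames = gene identifiers.
#' @param P Numeric matrix, perturbations x L, rownames = canonical labels.
#' @param source Tag describing provenance: one of `"pca"`, `"spectral"`,
#'   `"reference"`, `"external"`, `"random"`, `"identity"`.
#' @return An object of class `embedding_pair`.
#' @export
embedding_pair <- function(G, P, source = c("pca", "spectral", "reference",
                                            "external", "random", "identity")) {
  source <- match.arg(source)
  G <- as.matrix(G); P <- as.matrix(P)
  stopifnot(ncol(G) >= 1L, ncol(P) >= 1L,
            !is.null(rownames(G)), !is.null(rownames(P)),
            all(is.finite(G)), all(is.finite(P)))
  structure(list(G = G, P = P, source = source), class = "embedding_pair")
}

#' @export
print.embedding_pair <- function(x, ...) {
  cat("embedding_pair [", x$source, "]: G ", nrow(x$G), "x", ncol(x$G),
      ", P ", nrow(x$P), "x", ncol(x$P), "\n", sep = "")
  invisible(x)
}

# Fix per-component signs so the largest-magnitude entry of each column is
# positive; ties (exactly opposite extremes) resolved by the first extreme.
fix_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Gene embedding from a PCA of the training pseudobulk
#'
#' Performs a principal component analysis of the row-centered training
#' matrix (each gene centered by its mean expression across training
#' conditions -- the model intercept b) and returns the gene scores on the
#' top K components. Signs are fixed per component (largest-magnitude score
#' positive) so the result is fully deterministic.
#'
#' @param Y_train A [pseudobulk_matrix()] of training conditions.
#' @param K Number of components; must not exceed the achievable rank
#'   `min(n_genes, n_conditions - 1)`.
#' @return Numeric matrix (genes x K) of PCA scores, rownames = gene ids.
#' @export
pca_gene_embedding <- function(Y_train, K = 10L) {
  stopifnot(is_pseudobulk(Y_train), K >= 1L)
  Yc <- unclass(Y_train) - rowMeans(Y_train)
  achievable <- min(dim(Yc))
  if (K > achievable) {
    stop("K = ", K, " exceeds achievable rank ", achievable, call. = FALSE)
  }
  sv <- svd(Yc, nu = K, nv = 0)
  if (sv$d[K] < max(dim(Yc)) * .Machine$double.eps * sv$d[1]) {
    stop("K = ", K, " exceeds achievable rank ",
         sum(sv$d > max(dim(Yc)) * .Machine$double.eps * sv$d[1]),
         call. = FALSE)
  }
  G <- fix_signs(sv$u) %*% diag(sv$d[seq_len(K)], K)
  dimnames(G) <- list(rownames(Y_train), paste0("PC", seq_len(K)))
  G
}

#' Perturbation embedding from gene-embedding rows of the targets
#'
#' The default perturbation embedding subsets the gene embedding `G` to the
#' rows of the perturbed genes: a single perturbation of gene g is embedded
#' as `G[g, ]`; a double perturbation as the sum of its two target rows (the
#' additive-coding extension, which reduces to plain row selection for
#' singles). Perturbations whose target genes are not among the read-out
#' genes cannot be embedded this way; they raise a condition of class
#' `perturblm_unpredictable` carrying the offending labels so that callers
#' can restrict the evaluation set.
#'
#' @param G Gene embedding matrix with gene identifiers as rownames.
#' @param labels Character vector of canonical perturbation labels.
#' @param sep,control Label dialect.
#' @return Numeric matrix (perturbations x K), rownames = labels. The control
#'   label, if present, is embedded as the zero vector.
#' @export
perturbation_rows <- function(G, labels, sep = "+", control = "ctrl") {
  stopifnot(is.matrix(G), !is.null(rownames(G)))
  targets <- label_targets(labels, sep, control)
  bad <- labels[!vapply(targets, function(t) all(t %in% rownames(G)), logical(1))]
  if (length(bad) > 0L) {
    stop(unpredictable_condition(bad, "target gene absent from gene embedding"))
  }
  P <- do.call(rbind, lapply(targets, function(t) {
    if (length(t) == 0L) numeric(ncol(G)) else colSums(G[t, , drop = FALSE])
  }))
  dimnames(P) <- list(labels, colnames(G))
  P
}

unpredictable_condition <- function(labels, reason) {
  structure(
    class = c("perturblm_unpredictable", "error", "condition"),
    list(message = paste0("unpredictable perturbation(s): ",
                          paste(labels, collapse = ", "), " (", reason, ")"),
         call = NULL, labels = labels)
  )
}

#' Spectral embedding of a pathway-membership matrix
#'
#' Embeds perturbations from a binary membership matrix `M` (perturbations x
#' pathways) by a spectral embedding of the co-membership graph with affinity
#' `M %*% t(M)`: coordinates are the eigenvectors of the symmetric normalized
#' Laplacian for the `L` smallest non-trivial eigenvalues (the trivial
#' constant eigenvector is removed by deflation, which also handles
#' disconnected graphs: the first non-trivial coordinate then separates the
#' components). Perturbations with identical pathway memberships receive
#' identical coordinates.
#'
#' @param M Binary numeric matrix, perturbations x pathways, rownames =
#'   perturbation labels. Every row must have at least one membership.
#' @param L Embedding dimension, `L < nrow(M)`.
#' @return Numeric matrix (perturbations x L), rownames preserved.
#' @export
spectral_membership_embedding <- function(M, L) {
  M <- as.matrix(M)
  stopifnot(all(M %in% c(0, 1)), L >= 1L, L < nrow(M))
  if (any(rowSums(M) == 0)) {
    stop("perturbation(s) with zero pathway memberships: ",
         paste(rownames(M)[rowSums(M) == 0], collapse = ", "), call. = FALSE)
  }
  A <- M %*% t(M)
  d <- rowSums(A)
  Dhalf <- 1 / sqrt(d)
  Lsym <- diag(nrow(A)) - (Dhalf * A) * rep(Dhalf, each = nrow(A))
  Lsym <- (Lsym + t(Lsym)) / 2
  # Deflate the trivial direction(s): push D^{1/2} 1 above the spectrum
  # (eigenvalues of Lsym lie in [0, 2]).
  v0 <- sqrt(d) / sqrt(sum(d))
  B <- Lsym + 3 * tcrossprod(v0)
  es <- eigen(B, symmetric = TRUE)
  idx <- order(es$values)[seq_len(L)]
  U <- fix_signs(es$vectors[, idx, drop = FALSE])
  dimnames(U) <- list(rownames(M), paste0("SE", seq_len(L)))
  U
}

#' Perturbation embedding from PCA of reference perturbation data
#'
#' Fits a PCA on the columns of a reference perturbation-mean matrix (each
#' perturbation is one observation in gene space, genes centered by their
#' reference row means) and transfers the scores to the target dataset's
#' perturbations, matching reference and target perturbations by their
#' target-gene identifier. Target perturbations without a matched reference
#' perturbation raise a `perturblm_unpredictable` condition.
#'
#' @param Y_ref Reference [pseudobulk_matrix()] of single-perturbation means.
#' @param labels Canonical labels of the target perturbations to embed.
#' @param dim Embedding dimension (default 10).
#' @param sep,control Label dialect of `labels`.
#' @return Numeric matrix (perturbations x dim), rownames = `labels`.
#' @export
reference_pca_perturbation_embedding <- function(Y_ref, labels, dim = 10L,
                                                 sep = "+", control = "ctrl") {
  stopifnot(is_pseudobulk(Y_ref), dim >= 1L)
  ref_type <- label_type(colnames(Y_ref), pb_sep(Y_ref), pb_control(Y_ref))
  ref_singles <- colnames(Y_ref)[ref_type == "single"]
  ref_gene <- vapply(label_targets(ref_singles, pb_sep(Y_ref),
                                   pb_control(Y_ref)),
                     `[[`, character(1), 1L)
  Yc <- unclass(Y_ref) - rowMeans(Y_ref)
  achievable <- min(nrow(Yc), ncol(Yc))
  if (dim > achievable) {
    stop("dim = ", dim, " exceeds achievable rank ", achievable, call. = FALSE)
  }
  sv <- svd(Yc, nu = dim, nv = dim)
  # scores of each column (perturbation) on the top principal axes
  scores <- fix_signs(sv$v) %*% diag(sv$d[seq_len(dim)], dim)
  rownames(scores) <- colnames(Y_ref)
  scores <- scores[ref_singles, , drop = FALSE]
  rownames(scores) <- ref_gene

  tgt <- label_targets(labels, sep, control)
  bad <- labels[!vapply(tgt, function(t) length(t) >= 1L &&
                          all(t %in% ref_gene), logical(1))]
  if (length(bad) == length(labels)) {
    stop("no target perturbation shared with the reference data", call. = FALSE)
  }
  if (length(bad) > 0L) {
    stop(unpredictable_condition(bad, "no matching reference perturbation"))
  }
  P <- do.call(rbind, lapply(tgt, function(t) {
    colSums(scores[t, , drop = FALSE])
  }))
  dimnames(P) <- list(labels, paste0("refPC", seq_len(dim)))
  P
}

#' Random embedding matrix
#'
#' Entries are i.i.d. standard Normal draws from a seeded generator, so the
#' matrix is reproducible. Used as the null reference for embedding sources:
#' a pretrained embedding must beat this to carry information.
#'
#' @param ids Character vector of row identifiers (genes or labels).
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @return Numeric matrix (`length(ids)` x `dim`), rownames = `ids`.
#' @export
random_embedding <- function(ids, dim, seed = 1L) {
  stopifnot(length(ids) >= 1L, dim >= 1L)
  vals <- with_seed(seed, stats::rnorm(length(ids) * dim))
  matrix(vals, nrow = length(ids), ncol = dim,
         dimnames = list(ids, paste0("R", seq_len(dim))))
}

#' Load an external embedding table
#'
#' Reads a tab-separated table whose first column holds identifiers (gene
#' symbols or canonical perturbation labels) and whose remaining columns hold
#' coordinates. Identifiers are inner-joined against `ids`; dropped rows and
#' unmatched ids are reported via a message.
#'
#' @param path Path to the TSV file.
#' @param ids Identifiers the embedding must cover (order of the result).
#' @return Numeric matrix (`length(matched ids)` x coordinates).
#' @export
read_embedding_table <- function(path, ids) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  E <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(E) <- "double"
  rownames(E) <- tab[[1]]
  keep <- intersect(ids, rownames(E))
  dropped_file <- setdiff(rownames(E), ids)
  dropped_ids <- setdiff(ids, rownames(E))
  if (length(dropped_file) || length(dropped_ids)) {
    message("external embedding join: ", length(keep), " matched, ",
            length(dropped_file), " file rows dropped, ",
            length(dropped_ids), " dataset ids unmatched")
  }
  if (length(keep) == 0L) stop("no identifiers matched the embedding table")
  E[keep, , drop = FALSE]
}

#' Load a pathway membership matrix from an edge list
#'
#' Reads a two-column (perturbation, pathway) tab-separated edge list and
#' builds the binary membership matrix used by
#' [spectral_membership_embedding()].
#'
#' @param path Path to the TSV edge list (header required).
#' @return Binary numeric matrix, perturbations x pathways.
#' @export
read_membership_edgelist <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 2L)
  perts <- unique(tab[[1]]); paths <- unique(tab[[2]])
  M <- matrix(0, length(perts), length(paths), dimnames = list(perts, paths))
  M[cbind(match(tab[[1]], perts), match(tab[[2]], paths))] <- 1
  M
}
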