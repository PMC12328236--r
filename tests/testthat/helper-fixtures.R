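# Shared fixtures and independent oracles, all built in code.

# Small deterministic pseudobulk: 4 genes, control + 2 singles + 1 double.
toy_pb <- function() {
  vals <- matrix(
    c(1, 2, 3, 4,      # ctrl
      2, 2, 3, 5,      # A+ctrl
      1, 3, 3, 4,      # B+ctrl
      2, 3, 3, 6),     # A+B
    nrow = 4,
    dimnames = list(paste0("g", 1:4), c("ctrl", "A+ctrl", "B+ctrl", "A+B"))
  )
  pseudobulk_matrix(vals)
}

# Random pseudobulk with a given design, via the generator.
rand_pb <- function(n_genes = 50, n_singles = 8, n_doubles = 6, seed = 1,
                    cells = 400, ...) {
  sim <- simulate_dataset(
    synthetic_spec(n_genes = n_genes, n_singles = n_singles,
                   n_doubles = n_doubles, cells_per_condition = cells,
                   true_rank = min(4, n_singles), seed = seed, ...),
    level = "pseudobulk")
  sim$dataset
}

# Brute-force FDP-TPR oracle: ranks entries by repeated which.max (largest
# |pred - add| first, ties by lower flat index), enumerates every prefix,
# then applies the FDP-sort / running-max-TPR transform literally.
oracle_fdp_tpr <- function(pred, add, obs, u) {
  score <- abs(as.numeric(pred) - as.numeric(add))
  truth <- abs(as.numeric(obs) - as.numeric(add)) >= u
  N <- length(score)
  remaining <- seq_len(N)
  ranked <- integer(N)
  for (l in seq_len(N)) {                 # O(N^2) selection, independent of order()
    best <- remaining[which.max(score[remaining])]
    ranked[l] <- best
    remaining <- setdiff(remaining, best)
  }
  fdp <- numeric(N); tpr <- numeric(N)
  for (l in seq_len(N)) {
    sel <- ranked[seq_len(l)]
    fdp[l] <- sum(!truth[sel]) / l
    tpr[l] <- sum(truth[sel]) / sum(truth)
  }
  s <- order(fdp, seq_len(N))
  out_fdp <- fdp[s]
  out_tpr <- numeric(N)
  running <- -Inf
  for (l in seq_len(N)) {
    running <- max(running, tpr[s[l]])
    out_tpr[l] <- running
  }
  data.frame(fdp = out_fdp, tpr = out_tpr)
}

# Iterative minimizer of the two-sided-penalized bilinear objective
#   ||R - G W P'||_F^2 + lambda ||G W||^2 + lambda ||W P'||^2 + lambda^2 ||W||^2
# used as the independent oracle for the ridge normal equations.
oracle_bilinear_fit <- function(R, G, P, lambda, maxit = 2000) {
  K <- ncol(G); L <- ncol(P)
  obj <- function(w) {
    W <- matrix(w, K, L)
    E <- R - G %*% W %*% t(P)
    sum(E^2) + lambda * sum((G %*% W)^2) + lambda * sum((W %*% t(P))^2) +
      lambda^2 * sum(W^2)
  }
  grad <- function(w) {
    W <- matrix(w, K, L)
    E <- R - G %*% W %*% t(P)
    g <- -2 * t(G) %*% E %*% P + 2 * lambda * crossprod(G) %*% W +
      2 * lambda * W %*% crossprod(P) + 2 * lambda^2 * W
    as.numeric(g)
  }
  opt <- stats::optim(numeric(K * L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  list(W = matrix(opt$par, K, L), value = opt$value, objective = obj)
}

# Write a tiny h5ad fixture through Python/anndata; returns the path.
make_h5ad_fixture <- function(path, X, genes, labels,
                              condition_field = "condition") {
  dir <- dirname(path)
  write.table(X, file.path(dir, "_X.tsv"), sep = "\t", row.names = FALSE,
              col.names = FALSE)
  writeLines(genes, file.path(dir, "_genes.txt"))
  writeLines(labels, file.path(dir, "_labels.txt"))
  script <- file.path(dir, "_make.py")
  writeLines(c(
    "import sys",
    "import numpy as np, pandas as pd, anndata as ad",
    "d = sys.argv[1]; out = sys.argv[2]; field = sys.argv[3]",
    "X = np.loadtxt(d + '/_X.tsv')",
    "X = X.reshape(-1, 1) if X.ndim == 1 else X",
    "genes = open(d + '/_genes.txt').read().split()",
    "labels = open(d + '/_labels.txt').read().split()",
    "a = ad.AnnData(X=X, obs=pd.DataFrame({field: labels}),",
    "               var=pd.DataFrame(index=genes))",
    "a.write_h5ad(out)"
  ), script)
  status <- system2("python", c(script, dir, path, condition_field),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  path
}
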