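test_that("pca_gene_embedding matches an eigen-decomposition oracle", {
  set.seed(101)
  vals <- matrix(rnorm(20 * 8), 20,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 c("ctrl", paste0("p", 1:7, "+ctrl"))))
  pb <- pseudobulk_matrix(vals)
  G <- pca_gene_embedding(pb, K = 3)

  # oracle: scores via eigen-decomposition of the Gram matrix
  Yc <- vals - rowMeans(vals)
  eg <- eigen(crossprod(Yc), symmetric = TRUE)
  scores <- Yc %*% eg$vectors[, 1:3]
  expect_equal(abs(unname(G)), abs(unname(scores)), tolerance = 1e-8)

  # component scores mutually orthogonal
  cp <- crossprod(G)
  expect_equal(unname(cp - diag(diag(cp))), matrix(0, 3, 3), tolerance = 1e-8)

  # sign convention: largest-magnitude score positive
  for (k in 1:3) expect_gt(G[which.max(abs(G[, k])), k], 0)
})

test_that("rank-1 training matrix gives one component with all the variance", {
  u <- rnorm(10); v <- c(0, rnorm(3))    # first column is the control
  vals <- outer(u, v) + 5
  dimnames(vals) <- list(paste0("g", 1:10),
                         c("ctrl", paste0("p", 1:3, "+ctrl")))
  pb <- pseudobulk_matrix(vals)
  G <- pca_gene_embedding(pb, K = 1)
  Yc <- vals - rowMeans(vals)
  expect_equal(sum(G^2), sum(Yc^2), tolerance = 1e-8)  # 100% of variance
  expect_error(pca_gene_embedding(pb, K = 2), "achievable rank")
  expect_error(pca_gene_embedding(pb, K = 11), "achievable rank")
})

test_that("perturbation_rows selects and sums gene-embedding rows", {
  G <- matrix(1:6, 3, dimnames = list(c("A", "B", "C"), NULL))
  P <- perturbation_rows(G, c("A+ctrl", "A+B", "ctrl"))
  expect_equal(P["A+ctrl", ], G["A", ], ignore_attr = TRUE)
  expect_equal(P["A+B", ], G["A", ] + G["B", ], ignore_attr = TRUE)
  expect_equal(P["ctrl", ], c(0, 0), ignore_attr = TRUE)

  err <- tryCatch(perturbation_rows(G, c("A+ctrl", "Z+ctrl")),
                  perturblm_unpredictable = identity)
  expect_s3_class(err, "perturblm_unpredictable")
  expect_identical(err$labels, "Z+ctrl")
})

test_that("spectral embedding separates disjoint blocks and matches the Laplacian", {
  # two disjoint 3-perturbation blocks sharing one pathway each
  M <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 1))
  rownames(M) <- paste0("p", 1:6)
  U <- spectral_membership_embedding(M, L = 1)
  expect_true(all(sign(U[1:3, 1]) == sign(U[1, 1])))
  expect_true(all(sign(U[4:6, 1]) == -sign(U[1, 1])))

  # oracle: the coordinate is a null vector of the symmetric normalized
  # Laplacian, orthogonal to the trivial direction D^{1/2} 1
  A <- M %*% t(M); d <- rowSums(A)
  Lsym <- diag(6) - diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  expect_equal(as.numeric(Lsym %*% U[, 1]), numeric(6), tolerance = 1e-10)
  expect_equal(sum(sqrt(d) * U[, 1]), 0, tolerance = 1e-10)

  # identical membership rows -> identical embedding rows
  expect_equal(U[1, ], U[2, ], ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("spectral embedding spans the oracle eigenspaces", {
  set.seed(7)
  M <- matrix(rbinom(20, 1, 0.5), 5, 4)
  M[rowSums(M) == 0, 1] <- 1
  rownames(M) <- paste0("p", 1:5)
  U <- spectral_membership_embedding(M, L = 2)

  A <- M %*% t(M); d <- rowSums(A)
  Lsym <- diag(5) - diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  Lsym <- (Lsym + t(Lsym)) / 2
  v0 <- sqrt(d) / sqrt(sum(d))
  # oracle: eigen-decomposition of the Laplacian restricted to the
  # orthogonal complement of the trivial direction. The restricted spectrum
  # is the spectrum of Q Lsym Q minus one zero (contributed by Q v0 = 0).
  Q <- diag(5) - tcrossprod(v0)
  es <- eigen(Q %*% Lsym %*% Q, symmetric = TRUE)
  vals_all <- sort(es$values)
  restricted <- vals_all[-1]
  sel_vals <- restricted[1:2]
  # returned columns are orthonormal and orthogonal to v0
  expect_equal(unname(crossprod(U)), diag(2), tolerance = 1e-8)
  expect_equal(as.numeric(crossprod(U, v0)), c(0, 0), tolerance = 1e-8)
  # their Rayleigh quotients equal the two smallest restricted eigenvalues
  expect_equal(sort(unname(diag(crossprod(U, Lsym %*% U)))), sel_vals,
               tolerance = 1e-8)
  # and they lie in the span of the oracle eigenvectors with eigenvalues up
  # to the selected cutoff (sign/rotation-free subspace comparison)
  oracle <- es$vectors[, es$values <= max(sel_vals) + 1e-8, drop = FALSE]
  proj <- oracle %*% crossprod(oracle, U)
  expect_equal(unname(proj), unname(U), tolerance = 1e-8)

  expect_error(spectral_membership_embedding(rbind(M, 0), L = 2),
               "zero pathway")
})

test_that("reference PCA embedding matches a transpose-PCA oracle", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:50)
  ref_conds <- c("ctrl", paste0(genes[1:12], "+ctrl"))
  vals <- matrix(rnorm(50 * 13), 50, dimnames = list(genes, ref_conds))
  Y_ref <- pseudobulk_matrix(vals)
  labels <- paste0(genes[2:6], "+ctrl")
  P <- reference_pca_perturbation_embedding(Y_ref, labels, dim = 4)
  expect_identical(rownames(P), labels)

  # oracle: score of column j = (column j - row means) projected on the
  # top-4 eigenvectors of the gene-space covariance
  Yc <- vals - rowMeans(vals)
  eg <- eigen(tcrossprod(Yc), symmetric = TRUE)
  scores <- t(Yc) %*% eg$vectors[, 1:4]
  expect_equal(abs(unname(P)), abs(unname(scores[labels, ])),
               tolerance = 1e-8)

  # identical reference columns give identical embedding rows
  vals2 <- vals
  vals2[, "g02+ctrl"] <- vals2[, "g03+ctrl"]
  P2 <- reference_pca_perturbation_embedding(pseudobulk_matrix(vals2),
                                             c("g02+ctrl", "g03+ctrl"),
                                             dim = 3)
  expect_equal(P2[1, ], P2[2, ], ignore_attr = TRUE, tolerance = 1e-10)

  # unmatched target perturbations raise the unpredictable condition
  err <- tryCatch(
    reference_pca_perturbation_embedding(Y_ref, c("g02+ctrl", "zz+ctrl"), 2),
    perturblm_unpredictable = identity)
  expect_s3_class(err, "perturblm_unpredictable")
  expect_error(
    reference_pca_perturbation_embedding(Y_ref, "zz+ctrl", 2), "shared")
})

test_that("random embeddings are seeded and standard Normal", {
  E1 <- random_embedding(paste0("g", 1:100), 10, seed = 4)
  E2 <- random_embedding(paste0("g", 1:100), 10, seed = 4)
  expect_identical(E1, E2)
  expect_false(identical(E1, random_embedding(paste0("g", 1:100), 10, 5)))
  big <- random_embedding(paste0("g", 1:1000), 1000, seed = 6)
  expect_lt(abs(mean(big)), 0.01)      # 10^6 entries, LLN
  expect_equal(sd(big), 1, tolerance = 0.01)
})

test_that("external embedding and membership tables load with an inner join", {
  dir <- withr::local_tempdir()
  tab <- data.frame(id = c("A", "B", "Z"), x = 1:3, y = 4:6)
  write.table(tab, file.path(dir, "emb.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_message(E <- read_embedding_table(file.path(dir, "emb.tsv"),
                                           c("A", "B", "C")),
                 "join")
  expect_identical(rownames(E), c("A", "B"))
  expect_equal(E["B", "y"], 5)

  edges <- data.frame(pert = c("p1", "p1", "p2"),
                      pathway = c("w1", "w2", "w2"))
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  M <- read_membership_edgelist(file.path(dir, "edges.tsv"))
  expect_equal(M["p1", "w2"], 1)
  expect_equal(M["p2", "w1"], 0)
})
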