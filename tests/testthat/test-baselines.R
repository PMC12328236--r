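test_that("no-change predicts the control profile for every perturbation", {
  pb <- toy_pb()
  pred <- predict_no_change(pb, c("A+B", "A+ctrl"))
  expect_equal(pred[, "A+B"], control_profile(pb), ignore_attr = TRUE)
  expect_equal(pred[, "A+ctrl"], control_profile(pb), ignore_attr = TRUE)
  expect_equal(l2_error(pred[, "A+B"], control_profile(pb)), 0)
  # degenerate Pearson delta is NA, not 0
  expect_message(
    pd <- pearson_delta(pred[, "A+B"], pb[, "A+B"], control_profile(pb)),
    "undefined")
  expect_true(is.na(pd))
})

test_that("mean model predicts training row means", {
  vals <- matrix(c(0, 0, 1, 2, 3, 4), nrow = 1,
                 dimnames = list("g1", c("ctrl", "A+ctrl", "B+ctrl",
                                         "C+ctrl", "D+ctrl", "E+ctrl")))
  pb <- pseudobulk_matrix(vals)
  train <- subset_conditions(pb, c("A+ctrl", "B+ctrl"))  # + ctrl
  pred <- predict_mean(train, c("C+ctrl", "D+ctrl"))
  expect_equal(unname(pred[1, ]), c(1 / 3, 1 / 3))  # mean of 0, 0, 1
  # degenerate subset: fewer than 2 conditions is rejected
  expect_error(subset_conditions(pb, character(0)))
  # all training columns equal to control -> coincides with no-change
  vals2 <- matrix(c(2, 2, 2, 9), nrow = 1,
                  dimnames = list("g1", c("ctrl", "A+ctrl", "B+ctrl", "A+B")))
  pb2 <- pseudobulk_matrix(vals2)
  tr2 <- subset_conditions(pb2, c("ctrl", "A+ctrl", "B+ctrl"))
  expect_equal(unclass(predict_mean(tr2, "A+B")),
               unclass(predict_no_change(pb2, "A+B")), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("additive model computes y_A + y_B - y_ctrl", {
  vals <- matrix(c(1, 2, 3, 0), nrow = 1,
                 dimnames = list("g1", c("ctrl", "A+ctrl", "B+ctrl", "A+B")))
  pb <- pseudobulk_matrix(vals)
  expect_equal(unname(predict_additive(pb, "A+B")[1, 1]), 4)

  # y_A = y_ctrl -> prediction equals y_B
  vals[1, "A+ctrl"] <- 1
  pb <- pseudobulk_matrix(vals)
  expect_equal(unname(predict_additive(pb, "A+B")[1, 1]), 3)
  # y_A = y_B = y_ctrl -> prediction equals control
  vals[1, "B+ctrl"] <- 1
  pb <- pseudobulk_matrix(vals)
  expect_equal(unname(predict_additive(pb, "A+B")[1, 1]), 1)

  expect_error(predict_additive(pb, "A+Q"), "Q\\+ctrl")
  expect_error(predict_additive(pb, "A+ctrl"), "double")
})

test_that("identity embeddings at lambda 0 recover Y - b", {
  pb <- toy_pb()
  G <- diag(4); dimnames(G) <- list(rownames(pb), NULL)
  P <- diag(4); dimnames(P) <- list(colnames(pb), NULL)
  fit <- fit_linear_model(pb, embedding_pair(G, P, "identity"), lambda = 0)
  expect_equal(unname(fit$W), unname(unclass(pb) - rowMeans(pb)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # predictions on the training embedding reproduce fitted values
  pred <- predict_linear_model(fit, P)
  expect_equal(unclass(pred), unclass(pb), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("heavy ridge shrinks W towards zero; shrinkage is monotone", {
  pb <- rand_pb(n_genes = 15, n_singles = 5, n_doubles = 2, seed = 31)
  G <- pca_gene_embedding(pb, 3)
  P <- perturbation_rows(G, colnames(pb))
  emb <- embedding_pair(G, P, "pca")
  fit_big <- fit_linear_model(pb, emb, lambda = 1e6)
  R <- unclass(pb) - rowMeans(pb)
  expect_lt(sqrt(sum(fit_big$W^2)), 1e-3 * sqrt(sum(R^2)))

  norms <- vapply(c(0.01, 0.1, 1, 10), function(l) {
    sqrt(sum(fit_linear_model(pb, emb, l)$W^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("singular embeddings at lambda 0 advise a positive penalty", {
  pb <- toy_pb()
  G <- cbind(1, 1); rownames(G) <- NULL
  G <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 4,
              dimnames = list(rownames(pb), NULL))   # rank 1, K = 2
  P <- diag(4); dimnames(P) <- list(colnames(pb), NULL)
  expect_error(fit_linear_model(pb, embedding_pair(G, P, "identity"), 0),
               "lambda > 0")
})

test_that("W = 0 reduces the linear model to the mean model", {
  pb <- toy_pb()
  G <- diag(4); dimnames(G) <- list(rownames(pb), NULL)
  P <- diag(4); dimnames(P) <- list(colnames(pb), NULL)
  fit <- fit_linear_model(pb, embedding_pair(G, P, "identity"), lambda = 0)
  fit$W <- matrix(0, 4, 4)
  pred <- predict_linear_model(fit, P)
  mean_pred <- predict_mean(pb, colnames(pb))
  expect_equal(unclass(pred), unclass(mean_pred), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("the additive model is an exact special case of the linear model", {
  for (seed in 1:3) {
    pb <- rand_pb(n_genes = 25, n_singles = 6, n_doubles = 5, seed = seed)
    doubles <- colnames(pb)[label_type(colnames(pb)) == "double"]
    fit <- additive_as_linear_model(pb)
    P_test <- binary_double_coding(pb, doubles)
    lm_pred <- predict_linear_model(fit, P_test)
    add_pred <- predict_additive(pb, doubles)
    expect_equal(unclass(lm_pred), unclass(add_pred), ignore_attr = TRUE,
                 tolerance = 1e-14)
  }
})

test_that("ridge normal equations match the iterative oracle objective", {
  set.seed(55)
  for (i in 1:5) {
    R <- matrix(rnorm(15 * 6), 15, 6)
    G <- matrix(rnorm(15 * 3), 15, 3,
                dimnames = list(sprintf("g%02d", 1:15), NULL))
    P <- matrix(rnorm(6 * 3), 6, 3,
                dimnames = list(c("ctrl", paste0("p", 1:5, "+ctrl")), NULL))
    vals <- R + 2
    dimnames(vals) <- list(rownames(G), rownames(P))
    pb <- pseudobulk_matrix(vals)
    fit <- fit_linear_model(pb, embedding_pair(G, P, "external"), 0.1)
    Rc <- unclass(pb) - rowMeans(pb)
    oracle <- oracle_bilinear_fit(Rc, G, P, 0.1)
    expect_equal(oracle$objective(as.numeric(fit$W)), oracle$value,
                 tolerance = 1e-7)
  }
})

test_that("linear model recovers planted bilinear structure", {
  # held-out singles: error approaches the pseudobulk noise floor (with the
  # ~2K/n_train estimated-embedding inflation; the strict 10% band is
  # exercised in test-acceptance.R) and beats the mean baseline
  ratios <- beats <- numeric(0)
  for (seed in 1:5) {
    spec <- synthetic_spec(n_genes = 400, n_singles = 40, n_doubles = 2,
                           cells_per_condition = 100, true_rank = 4,
                           effect_scale = 0.25, seed = seed)
    sim <- simulate_dataset(spec, level = "pseudobulk")
    pb <- sim$dataset
    sp <- make_single_split(pb, 0.2, seed = seed)
    train <- subset_conditions(pb, sp$train_labels)
    G <- pca_gene_embedding(train, 4)
    fit <- fit_linear_model(train,
                            embedding_pair(G, perturbation_rows(G, sp$train_labels), "pca"),
                            0.1)
    pred <- predict_linear_model(fit, sp$test_labels)
    mpred <- predict_mean(train, sp$test_labels)
    l2 <- mean(vapply(sp$test_labels, function(p)
      l2_error(pred[, p], pb[, p]), numeric(1)))
    l2m <- mean(vapply(sp$test_labels, function(p)
      l2_error(mpred[, p], pb[, p]), numeric(1)))
    ratios <- c(ratios, l2 / (sqrt(400) / sqrt(100)))
    beats <- c(beats, l2 < l2m)
  }
  expect_lt(mean(ratios), 1.30)
  expect_true(all(beats == 1))
})

test_that("ridge decoder matches the augmented normal-equations oracle", {
  set.seed(77)
  E <- matrix(rnorm(8 * 3), 8, 3,
              dimnames = list(paste0("p", 1:8, "+ctrl"), NULL))
  Y <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(paste0("g", 1:12), rownames(E)))
  lambda <- 0.3
  dec <- fit_ridge_decoder(E, Y, lambda)
  Enew <- matrix(rnorm(4 * 3), 4, 3,
                 dimnames = list(paste0("q", 1:4, "+ctrl"), NULL))
  pred <- predict(dec, Enew)

  # oracle: per-gene ridge with unpenalized intercept via augmented solve
  X <- cbind(1, E)
  Pen <- diag(c(0, rep(lambda, 3)))
  coef <- solve(crossprod(X) + Pen, crossprod(X, t(Y)))
  oracle <- t(cbind(1, Enew) %*% coef)
  expect_equal(unname(unclass(pred)), unname(oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("one-hot decoder at lambda 0 is exact; infinite ridge collapses", {
  Y <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(paste0("g", 1:10),
                              paste0("p", 1:4, "+ctrl")))
  E <- diag(4); rownames(E) <- colnames(Y)
  dec0 <- fit_ridge_decoder(E, Y, lambda = 0)
  expect_equal(unname(unclass(predict(dec0, E))), unname(Y),
               tolerance = 1e-8, ignore_attr = TRUE)
  dec_inf <- fit_ridge_decoder(E, Y, lambda = 1e12)
  expect_equal(unname(unclass(predict(dec_inf, E))),
               unname(matrix(rowMeans(Y), 10, 4)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(fit_ridge_decoder(E[1:3, ], Y), "align")
})

test_that("linear model fits serialize and round-trip as text", {
  pb <- rand_pb(n_genes = 12, n_singles = 4, n_doubles = 2, seed = 8)
  G <- pca_gene_embedding(pb, 2)
  P <- perturbation_rows(G, colnames(pb))
  fit <- fit_linear_model(pb, embedding_pair(G, P, "pca"), 0.1)
  prefix <- file.path(withr::local_tempdir(), "fit")
  write_linear_model_fit(fit, prefix)
  fit2 <- read_linear_model_fit(prefix)
  expect_equal(fit2$lambda, 0.1)
  p1 <- predict_linear_model(fit, colnames(pb))
  p2 <- predict_linear_model(fit2, colnames(pb))
  expect_equal(unclass(p2), unclass(p1), tolerance = 1e-10)
})
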