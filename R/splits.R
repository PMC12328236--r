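#' Test-train splits over perturbation conditions
#'
#' Two protocols are provided. `make_double_split()` implements the double
#' perturbation benchmark: every single perturbation and the control go to
#' the training set and a seeded random fraction of the double perturbations
#' is held out for testing. `make_single_split()` holds out a seeded random
#' fraction of the single perturbations (a plain uniform holdout; reports
#' label it as such). The same seed always reproduces the same split.
#'
#' @param pb A [pseudobulk_matrix()].
#' @param test_fraction Fraction of eligible conditions held out; the test
#'   count is `ceiling(test_fraction * n_eligible)` (default 0.5 for doubles,
#'   matching a half-half split).
#' @param seed Integer seed driving the shuffle.
#'
#' @return An object of class `split_spec`: list with `seed`, `protocol`,
#'   `train_labels`, `test_labels` (canonical condition labels; training
#'   always includes the control).
#' @export
make_double_split <- function(pb, test_fraction = 0.5, seed = 1L) {
  stopifnot(is_pseudobulk(pb), test_fraction > 0, test_fraction <= 1)
  type <- label_type(colnames(pb), pb_sep(pb), pb_control(pb))
  doubles <- colnames(pb)[type == "double"]
  if (length(doubles) < 2L) {
    stop("double-holdout split requires >= 2 double perturbations",
         call. = FALSE)
  }
  n_test <- min(length(doubles), ceiling(test_fraction * length(doubles)))
  shuffled <- seeded_sample(doubles, seed)
  test <- sort(shuffled[seq_len(n_test)], method = "radix")
  train <- sort(setdiff(colnames(pb), test), method = "radix")
  new_split(seed, "double-holdout", train, test)
}

#' @rdname make_double_split
#' @export
make_single_split <- function(pb, test_fraction = 0.2, seed = 1L) {
  stopifnot(is_pseudobulk(pb), test_fraction > 0, test_fraction <= 1)
  type <- label_type(colnames(pb), pb_sep(pb), pb_control(pb))
  singles <- colnames(pb)[type == "single"]
  if (length(singles) < 2L) {
    stop("single-holdout split requires >= 2 single perturbations",
         call. = FALSE)
  }
  n_test <- min(length(singles), ceiling(test_fraction * length(singles)))
  shuffled <- seeded_sample(singles, seed)
  test <- sort(shuffled[seq_len(n_test)], method = "radix")
  train <- sort(setdiff(colnames(pb), test), method = "radix")
  new_split(seed, "single-holdout", train, test)
}

new_split <- function(seed, protocol, train, test) {
  stopifnot(length(intersect(train, test)) == 0L)
  structure(
    list(seed = as.integer(seed), protocol = protocol,
         train_labels = train, test_labels = test),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat("split_spec [", x$protocol, "] seed ", x$seed, ": ",
      length(x$train_labels), " train / ", length(x$test_labels),
      " test conditions\n", sep = "")
  invisible(x)
}

# Draw a seeded permutation without disturbing the caller's RNG state.
seeded_sample <- function(x, seed) {
  with_seed(seed, sample(x))
}

# Evaluate `expr` under a local RNG seed, restoring the global state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
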