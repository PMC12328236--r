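#' Specification of a synthetic perturbation dataset
#'
#' Describes the stated world that the generator emulates: log-transformed
#' per-condition expression around a gene baseline, single-perturbation
#' effects drawn from the low-rank bilinear family the linear model fits,
#' double perturbations equal to the additive expectation plus planted
#' interactions of declared classes, and i.i.d. Normal per-cell noise.
#'
#' Defaults mirror a typical CRISPRa double-perturbation screen: 2000
#' measured genes, 100 single and 124 double perturbations, ~300 cells per
#' condition, unit per-cell noise on the log scale, rank-10 effect structure
#' with per-gene effect standard deviation ~0.3 (a moderate log fold
#' change). `interaction_magnitude` is expressed in units of the null
#' standard deviation of the deviation-from-additivity statistic
#' (`2 * noise_sd / sqrt(cells_per_condition)`), so a magnitude of 6 plants
#' interactions at >= 6 sigma of the empirical null.
#'
#' @param n_genes,n_singles,n_doubles,cells_per_condition Counts (all >= 1;
#'   `n_singles <= n_genes`, `n_doubles <= choose(n_singles, 2)`).
#' @param true_rank Rank K* of the bilinear effect structure.
#' @param effect_scale Standard deviation of per-gene single-perturbation
#'   effects (log fold change units).
#' @param noise_sd Per-cell Normal noise standard deviation.
#' @param interaction_fraction Fraction of (gene, pair) entries with planted
#'   interactions, in `[0, 1]`.
#' @param interaction_classes Named mixing weights over
#'   `c("buffering", "synergistic", "opposite")`, summing to 1.
#' @param interaction_magnitude Minimum planted deviation, in null-sd units.
#' @param seed Integer master seed; fanned out to per-component substreams
#'   so adding conditions does not perturb existing draws.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_singles = 100L,
                           n_doubles = 124L, cells_per_condition = 300L,
                           true_rank = 10L, effect_scale = 0.3,
                           noise_sd = 1, interaction_fraction = 0,
                           interaction_classes = c(buffering = 0.65,
                                                   synergistic = 0.35,
                                                   opposite = 0),
                           interaction_magnitude = 6, seed = 1L) {
  stopifnot(n_genes >= 1L, n_singles >= 1L, n_singles <= n_genes,
            n_doubles >= 1L, n_doubles <= choose(n_singles, 2),
            cells_per_condition >= 1L, true_rank >= 1L,
            effect_scale > 0, noise_sd >= 0,
            interaction_fraction >= 0, interaction_fraction <= 1,
            abs(sum(interaction_classes) - 1) < 1e-8,
            all(names(interaction_classes) %in%
                  c("buffering", "synergistic", "opposite")),
            interaction_magnitude > 0)
  structure(
    list(n_genes = as.integer(n_genes), n_singles = as.integer(n_singles),
         n_doubles = as.integer(n_doubles),
         cells_per_condition = as.integer(cells_per_condition),
         true_rank = as.integer(true_rank), effect_scale = effect_scale,
         noise_sd = noise_sd, interaction_fraction = interaction_fraction,
         interaction_classes = interaction_classes,
         interaction_magnitude = interaction_magnitude,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Fan one master seed out into named substreams (31-bit, reproducible).
substreams <- function(seed, names) {
  s <- with_seed(seed, sample.int(2147483646L, length(names)))
  stats::setNames(s, names)
}

#' Simulate a perturbation dataset with known ground truth
#'
#' Draws a dataset from the world described by a [synthetic_spec()]. The
#' control mean is the gene baseline b*; single-perturbation means are
#' `b* + G* W* p*` with `p*` the gene-embedding row of the target (so the
#' generating family matches the linear model's default construction);
#' double-perturbation means equal the additive expectation plus the planted
#' deviation (zero for non-interacting entries). Cells are drawn i.i.d.
#' Normal around the condition means; `level = "pseudobulk"` instead draws
#' the per-condition mean directly with the equivalent
#' `noise_sd / sqrt(cells_per_condition)` noise, which is distributionally
#' identical at the pseudobulk level and much cheaper for large designs.
#'
#' Planted interactions respect their class by construction: buffering and
#' synergistic deviations shrink or exceed the additive expectation of
#' same-signed single effects, opposite deviations flip its sign. If the
#' single effects cannot accommodate a requested class (e.g. a buffering
#' deviation larger than every additive expectation), an error is raised.
#'
#' @param spec A [synthetic_spec()].
#' @param level `"cells"` (default) for a single-cell dataset or
#'   `"pseudobulk"` for condition-level draws.
#' @return A list with `dataset` (a [perturb_dataset()] or
#'   [pseudobulk_matrix()]) and `truth` (class `synthetic_truth`: `G_star`,
#'   `W_star`, `P_star`, `b_star`, per-gene single `effects`, the noiseless
#'   `condition_means`, the `planted` interaction table and `sigma_delta0`,
#'   the null sd of pseudobulk deviations from additivity).
#' @export
simulate_dataset <- function(spec, level = c("cells", "pseudobulk")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  level <- match.arg(level)
  ss <- substreams(spec$seed, c("structure", "pairs", "planted", "noise"))

  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  single_targets <- genes[seq_len(spec$n_singles)]
  K <- spec$true_rank

  st <- with_seed(ss[["structure"]], {
    list(
      b = stats::rgamma(spec$n_genes, shape = 2, scale = 1),
      G = matrix(stats::rnorm(spec$n_genes * K), spec$n_genes, K)
    )
  })
  b_star <- st$b
  G_star <- st$G
  dimnames(G_star) <- list(genes, paste0("k", seq_len(K)))
  names(b_star) <- genes
  # decreasing diagonal spectrum, scaled for per-gene effect sd ~ effect_scale
  w_diag <- spec$effect_scale * seq(1.5, 0.5, length.out = K) /
    sqrt(mean(seq(1.5, 0.5, length.out = K)^2) * K)
  W_star <- diag(w_diag, K)
  P_star <- G_star[single_targets, , drop = FALSE]
  effects <- G_star %*% W_star %*% t(P_star)   # genes x singles
  single_labels <- unname(vapply(single_targets, make_label, character(1)))
  colnames(effects) <- single_labels

  pairs <- with_seed(ss[["pairs"]], {
    all_pairs <- utils::combn(single_targets, 2)
    sel <- sample.int(ncol(all_pairs), spec$n_doubles)
    all_pairs[, sel, drop = FALSE]
  })
  pair_labels <- apply(pairs, 2, function(t) make_label(t))

  additive_lfc <- effects[, vapply(pairs[1, ], make_label, character(1))] +
    effects[, vapply(pairs[2, ], make_label, character(1))]
  colnames(additive_lfc) <- pair_labels

  sigma_delta0 <- 2 * spec$noise_sd / sqrt(spec$cells_per_condition)
  planted <- plant_interactions(spec, effects, additive_lfc, pairs,
                                pair_labels, sigma_delta0, ss[["planted"]])
  deviation <- matrix(0, spec$n_genes, spec$n_doubles,
                      dimnames = list(genes, pair_labels))
  if (nrow(planted) > 0L) {
    deviation[cbind(match(planted$gene, genes),
                    match(planted$pair, pair_labels))] <- planted$deviation
  }

  means <- cbind(
    ctrl = b_star,
    b_star + effects,
    b_star + additive_lfc + deviation
  )
  colnames(means) <- c("ctrl", single_labels, pair_labels)

  truth <- structure(
    list(G_star = G_star, W_star = W_star, P_star = P_star, b_star = b_star,
         effects = effects, condition_means = means, planted = planted,
         sigma_delta0 = sigma_delta0, single_labels = single_labels,
         pair_labels = pair_labels),
    class = "synthetic_truth"
  )

  sd_pb <- spec$noise_sd / sqrt(spec$cells_per_condition)
  if (level == "pseudobulk") {
    noise <- with_seed(ss[["noise"]], {
      matrix(stats::rnorm(length(means), sd = sd_pb), nrow(means), ncol(means))
    })
    dataset <- pseudobulk_matrix(means + noise)
  } else {
    n_cells <- spec$cells_per_condition * ncol(means)
    cell_labels <- rep(colnames(means), each = spec$cells_per_condition)
    expr <- with_seed(ss[["noise"]], {
      mu <- t(means)[rep(seq_len(ncol(means)),
                         each = spec$cells_per_condition), , drop = FALSE]
      mu + matrix(stats::rnorm(n_cells * spec$n_genes, sd = spec$noise_sd),
                  n_cells, spec$n_genes)
    })
    dataset <- perturb_dataset(expr, gene_ids = genes,
                               cell_labels = cell_labels)
  }
  list(dataset = dataset, truth = truth)
}

# Place planted interactions so every deviation is consistent with its class
# given the single effects. Buffering and synergistic require same-signed
# single effects; buffering additionally requires the additive expectation
# to exceed the planted magnitude (the double stays on the same side of 0).
plant_interactions <- function(spec, effects, additive_lfc, pairs,
                               pair_labels, sigma_delta0, seed) {
  empty <- data.frame(gene = character(), pair = character(),
                      class = character(), deviation = numeric(),
                      stringsAsFactors = FALSE)
  n_entries <- length(additive_lfc)
  n_plant <- floor(spec$interaction_fraction * n_entries)
  if (n_plant == 0L) return(empty)

  genes <- rownames(additive_lfc)
  effA <- effects[, vapply(pairs[1, ], make_label, character(1)), drop = FALSE]
  effB <- effects[, vapply(pairs[2, ], make_label, character(1)), drop = FALSE]
  same_sign <- sign(effA) * sign(effB) > 0

  with_seed(seed, {
    classes <- sample(names(spec$interaction_classes), n_plant, replace = TRUE,
                      prob = spec$interaction_classes)
    mags <- sigma_delta0 * (spec$interaction_magnitude + abs(stats::rnorm(n_plant)))
    a_abs <- abs(additive_lfc)

    pool <- which(same_sign)           # eligible flat indices, unused so far
    used <- logical(n_entries)
    rows <- vector("list", n_plant)
    # handle buffering in decreasing magnitude order so the tightest
    # constraints grab the largest additive expectations first
    ord <- order(classes != "buffering", -mags)
    for (i in ord) {
      cl <- classes[i]
      if (cl == "buffering") {
        ok <- pool[!used[pool] & a_abs[pool] > mags[i] * 1.05]
      } else {
        ok <- pool[!used[pool]]
      }
      if (length(ok) == 0L) {
        stop("cannot place a '", cl, "' interaction of magnitude ",
             format(mags[i]), ": no eligible (gene, pair) entry left; ",
             "reduce interaction_fraction or interaction_magnitude",
             call. = FALSE)
      }
      idx <- ok[sample.int(length(ok), 1L)]
      used[idx] <- TRUE
      a <- additive_lfc[idx]
      dev <- switch(cl,
        synergistic = sign(a) * mags[i],
        buffering   = -sign(a) * mags[i],
        opposite    = -sign(a) * (abs(a) + mags[i])
      )
      gi <- (idx - 1L) %% nrow(additive_lfc) + 1L
      pi <- (idx - 1L) %/% nrow(additive_lfc) + 1L
      rows[[i]] <- data.frame(gene = genes[gi], pair = pair_labels[pi],
                              class = cl, deviation = dev,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a two-component deviation mixture
#'
#' Direct input for empirical-null tests: `n` values, a fraction `p0` from
#' the null `Normal(0, null_sd^2)` and the rest from the signal
#' `Normal(0, signal_sd^2)`, with truth labels.
#'
#' @param n Number of values.
#' @param p0 Null proportion in (0, 1].
#' @param null_sd,signal_sd Component standard deviations.
#' @param seed Integer seed.
#' @return A data.frame with columns `value` and `is_null`.
#' @export
simulate_delta_mixture <- function(n, p0 = 0.95, null_sd = 1, signal_sd = 6,
                                   seed = 1L) {
  stopifnot(n >= 1L, p0 > 0, p0 <= 1, null_sd > 0, signal_sd > 0)
  with_seed(seed, {
    is_null <- stats::runif(n) < p0
    value <- ifelse(is_null, stats::rnorm(n, 0, null_sd),
                    stats::rnorm(n, 0, signal_sd))
    data.frame(value = value, is_null = is_null)
  })
}

#' Write a simulated dataset and its truth sidecar to disk
#'
#' Writes the dataset in the pseudobulk tabular interchange format plus a
#' `*.truth.tsv` sidecar table of planted interactions, so command-line runs
#' on synthetic data are file-for-file identical to real-data runs.
#'
#' @param sim Result of [simulate_dataset()].
#' @param path Output path for the expression table (truth sidecar written
#'   next to it).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  pb <- if (is_pseudobulk(sim$dataset)) sim$dataset else pseudobulk(sim$dataset)
  write_pseudobulk(pb, path)
  utils::write.table(sim$truth$planted,
                     paste0(sub("\\.tsv$", "", path), ".truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
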