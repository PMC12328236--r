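#' Parse a perturbation condition label
#'
#' Condition labels follow the string dialect used by the distributed
#' Perturb-seq datasets: `"ctrl"` for the unperturbed control, `"GENE+ctrl"`
#' for a single perturbation and `"GENEA+GENEB"` for a double perturbation.
#' Parsing strips control tokens, rejects malformed strings and produces a
#' canonical form in which the targets of a double are sorted
#' lexicographically, so that `"CNN1+CBL"` and `"CBL+CNN1"` name the same
#' condition.
#'
#' @param text A single condition label string.
#' @param sep Token separator (default `"+"`).
#' @param control Control token (default `"ctrl"`).
#'
#' @return An object of class `perturbation_label`: a list with elements
#'   `targets` (character vector of 0, 1 or 2 gene identifiers, sorted) and
#'   `canonical_string` (the canonical text form).
#'
#' @examples
#' parse_condition_label("ctrl")$targets
#' parse_condition_label("KLF1+ctrl")$canonical_string
#' parse_condition_label("CNN1+CBL")$canonical_string  # "CBL+CNN1"
#' @export
parse_condition_label <- function(text, sep = "+", control = "ctrl") {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text), nzchar(text))
  tokens <- strsplit(text, sep, fixed = TRUE)[[1]]
  if (length(tokens) == 0L || any(!nzchar(tokens))) {
    stop("malformed condition label (empty token): '", text, "'", call. = FALSE)
  }
  targets <- tokens[tokens != control]
  if (length(targets) > 2L) {
    stop("malformed condition label (more than 2 non-control tokens): '",
         text, "'", call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop("malformed condition label (duplicate target): '", text, "'",
         call. = FALSE)
  }
  targets <- sort(targets, method = "radix")
  canonical <- if (length(targets) == 0L) {
    control
  } else if (length(targets) == 1L) {
    paste(targets, control, sep = sep)
  } else {
    paste(targets, collapse = sep)
  }
  structure(
    list(targets = targets, canonical_string = canonical),
    class = "perturbation_label"
  )
}

#' @export
format.perturbation_label <- function(x, ...) x$canonical_string

#' @export
print.perturbation_label <- function(x, ...) {
  type <- c("control", "single perturbation", "double perturbation")[
    length(x$targets) + 1L]
  cat("<", x$canonical_string, "> (", type, ")\n", sep = "")
  invisible(x)
}

#' Canonicalize a vector of condition labels
#'
#' Vectorized companion of [parse_condition_label()]: maps every label to its
#' canonical string form. Errors name the first offending label.
#'
#' @param x Character vector of condition labels.
#' @inheritParams parse_condition_label
#' @return Character vector of canonical labels, same length as `x`.
#' @export
canonicalize_labels <- function(x, sep = "+", control = "ctrl") {
  vapply(x, function(s) parse_condition_label(s, sep, control)$canonical_string,
         character(1), USE.NAMES = FALSE)
}

#' Extract the target genes of condition labels
#'
#' @inheritParams canonicalize_labels
#' @return A list of character vectors (sorted targets; empty for control).
#' @export
label_targets <- function(x, sep = "+", control = "ctrl") {
  lapply(x, function(s) parse_condition_label(s, sep, control)$targets)
}

n_targets <- function(x, sep = "+", control = "ctrl") {
  lengths(label_targets(x, sep, control))
}

#' Classify condition labels as control, single or double
#'
#' @inheritParams canonicalize_labels
#' @return Character vector with values `"control"`, `"single"`, `"double"`.
#' @export
label_type <- function(x, sep = "+", control = "ctrl") {
  c("control", "single", "double")[n_targets(x, sep, control) + 1L]
}

is_control_label <- function(x, ...) label_type(x, ...) == "control"
is_single_label  <- function(x, ...) label_type(x, ...) == "single"
is_double_label  <- function(x, ...) label_type(x, ...) == "double"

#' Compose the canonical label for a set of targets
#'
#' @param targets Character vector of 0, 1 or 2 gene identifiers.
#' @inheritParams parse_condition_label
#' @return Canonical label string.
#' @export
make_label <- function(targets, sep = "+", control = "ctrl") {
  stopifnot(length(targets) <= 2L, !anyDuplicated(targets))
  targets <- sort(as.character(targets), method = "radix")
  if (length(targets) == 0L) return(control)
  if (length(targets) == 1L) return(paste(targets, control, sep = sep))
  paste(targets, collapse = sep)
}
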