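#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confidence null distribution
#'
#' @param x A `dar_confdist` from [confidence_distribution()].
#' @param ... Unused.
#' @return A plain tibble of atoms (`value`, `numerator`, `denominator`,
#'   `prob`).
#' @method tidy dar_confdist
#' @export
tidy.dar_confdist <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of a confidence null distribution
#'
#' @param x A `dar_confdist`.
#' @param ... Unused.
#' @return A one-row tibble: the construction parameters, atom count, mean,
#'   standard deviation and the probability mass lost to the Z = 0 event
#'   before conditioning.
#' @method glance dar_confdist
#' @export
glance.dar_confdist <- function(x, ...) {
  mu <- sum(x$value * x$prob)
  tibble::tibble(
    n = attr(x, "n"), p1 = attr(x, "p1"), p2 = attr(x, "p2"),
    n_atoms = nrow(x),
    mean = mu,
    sd = sqrt(sum((x$value - mu)^2 * x$prob)),
    pr_no_antecedent = 1 - attr(x, "normalizer")
  )
}

#' Tidy a mined rule set
#'
#' @param x A `dar_rules` tibble.
#' @param ... Unused.
#' @return The rules as a plain tibble.
#' @method tidy dar_rules
#' @export
tidy.dar_rules <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of a mined rule set
#'
#' @param x A `dar_rules` tibble.
#' @param ... Unused.
#' @return A one-row tibble: candidate count, rules retained, meaningful
#'   rules, final rules (if screened), final genes, and alpha.
#' @method glance dar_rules
#' @export
glance.dar_rules <- function(x, ...) {
  tibble::tibble(
    n_candidates = attr(x, "n_candidates") %||% NA_integer_,
    n_rules = nrow(x),
    n_meaningful = sum(x$meaningful),
    n_final = if ("final" %in% names(x)) sum(x$final) else NA_integer_,
    n_final_genes = length(final_gene_set(
      if ("final" %in% names(x)) x else dplyr::filter(x, .data$meaningful)
    )),
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

unclass_keep_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  for (a in c(
    "n", "p1", "p2", "normalizer", "alpha", "mode", "n_candidates",
    "max_antecedent", "screened", "preset"
  )) {
    attr(x, a) <- NULL
  }
  x
}
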