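#' Validate and assemble rule count tallies
#'
#' A rule `A -> B` over `n` baskets (samples) is summarised by four tallies:
#' `n` baskets in total, `n_A` containing every antecedent item, `n_B`
#' containing the consequent, and `n_AB` containing both. All estimators and
#' dynamic thresholds in the package are functions of these tallies.
#'
#' @param n Total number of baskets (samples). Must be >= 1.
#' @param n_A Baskets containing all antecedent items.
#' @param n_B Baskets containing the consequent.
#' @param n_AB Baskets containing both. Must satisfy
#'   `0 <= n_AB <= min(n_A, n_B) <= n`.
#' @return A tibble with columns `n`, `n_A`, `n_B`, `n_AB` (integer),
#'   one row per rule. Inputs are recycled to a common length.
#' @examples
#' rule_counts(1000, 300, 700, 210)
#' @export
rule_counts <- function(n, n_A, n_B, n_AB) {
  counts <- tibble::tibble(
    n = as.integer(n), n_A = as.integer(n_A),
    n_B = as.integer(n_B), n_AB = as.integer(n_AB)
  )
  validate_rule_counts(counts)
  counts
}

validate_rule_counts <- function(counts) {
  need <- c("n", "n_A", "n_B", "n_AB")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    stop("rule counts are missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  with(counts, {
    if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
    if (any(n_A < 0 | n_B < 0 | n_AB < 0)) {
      stop("counts must be non-negative", call. = FALSE)
    }
    if (any(n_A > n | n_B > n)) {
      stop("`n_A` and `n_B` cannot exceed `n`", call. = FALSE)
    }
    if (any(n_AB > pmin(n_A, n_B))) {
      stop("`n_AB` cannot exceed min(n_A, n_B)", call. = FALSE)
    }
  })
  invisible(counts)
}

#' Estimate marginal, joint and conditional item probabilities
#'
#' Plug-in estimates from rule tallies: `p1 = n_A/n` (antecedent),
#' `p2 = n_B/n` (consequent), `p12 = n_AB/n` (joint, the estimated support)
#' and `p2_given_1 = n_AB/n_A` (conditional, the estimated confidence;
#' `NA` when `n_A = 0`).
#'
#' @param counts A data frame with columns `n`, `n_A`, `n_B`, `n_AB`, e.g.
#'   from [rule_counts()].
#' @return The input tibble with columns `p1`, `p2`, `p12`, `p2_given_1`
#'   appended.
#' @examples
#' estimate_item_probabilities(rule_counts(1000, 300, 700, 210))
#' @export
estimate_item_probabilities <- function(counts) {
  validate_rule_counts(counts)
  dplyr::mutate(
    tibble::as_tibble(counts),
    p1 = .data$n_A / .data$n,
    p2 = .data$n_B / .data$n,
    p12 = .data$n_AB / .data$n,
    p2_given_1 = ifelse(.data$n_A > 0, .data$n_AB / .data$n_A, NA_real_)
  )
}

#' One-sided upper standard-normal quantile
#'
#' Returns the upper-alpha standard normal quantile used in the minimum-support
#' bound. With `compat = "printed"` (the default) the quantile is rounded to
#' three decimals (1.645 at alpha = 0.05, 1.282 at 0.10), the figure customary
#' in printed worked examples; `compat = "exact"` uses the full-precision
#' quantile.
#'
#' @param alpha One-sided significance level, in (0, 0.5].
#' @param compat `"printed"` (3-decimal quantile) or `"exact"`.
#' @return The scalar z value; 0 when `alpha = 0.5`.
#' @export
z_alpha <- function(alpha, compat = c("printed", "exact")) {
  compat <- match.arg(compat)
  check_alpha(alpha)
  z <- stats::qnorm(1 - alpha)
  if (compat == "printed") z <- round(z, 3)
  z
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
    any(alpha <= 0) || any(alpha > 0.5)) {
    stop("`alpha` must lie in (0, 0.5]", call. = FALSE)
  }
  invisible(alpha)
}

check_proportion <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`", name, "` must be a proportion in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Dynamic minimum support under independence
#'
#' The null distribution of the estimated support `n_AB/n` under independence
#' of antecedent and consequent is Binomial(n, p1*p2)/n, approximately normal.
#' The minimum support is its one-sided (1 - alpha) upper bound:
#' \deqn{s_{min} = p_1 p_2 + z_\alpha \sqrt{p_1 p_2 (1 - p_1 p_2)/n}.}
#' A rule is support-meaningful only if its estimated support strictly
#' exceeds this bound.
#'
#' @param p1,p2 Estimated marginal probabilities of antecedent and consequent,
#'   each in \[0, 1\]. Vectorised.
#' @param n Number of baskets (samples), >= 1.
#' @param alpha One-sided significance level in (0, 0.5].
#' @param compat Normal-quantile convention passed to [z_alpha()].
#' @param method `"normal"` (the closed-form bound above, default) or
#'   `"exact-binomial"` (the (1-alpha) quantile of Binomial(n, p1*p2)/n).
#' @return Numeric vector of minimum supports. When `p1*p2` is 0 or 1 the
#'   variance term vanishes and `p1*p2` itself is returned.
#' @examples
#' minimum_support(0.3, 0.7, n = 1000, alpha = 0.05) # 0.2312 to 4 decimals
#' @export
minimum_support <- function(p1, p2, n, alpha = 0.05,
                            compat = c("printed", "exact"),
                            method = c("normal", "exact-binomial")) {
  method <- match.arg(method)
  compat <- match.arg(compat)
  check_proportion(p1, "p1")
  check_proportion(p2, "p2")
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  check_alpha(alpha)
  minimum_support_joint(p1 * p2, n, alpha, compat = compat, method = method)
}

# same bound parameterised by the joint probability p12 directly
minimum_support_joint <- function(p12, n, alpha = 0.05,
                                  compat = "printed", method = "normal") {
  z <- z_alpha(alpha, compat)
  if (method == "exact-binomial") {
    out <- stats::qbinom(1 - alpha, n, p12) / n
  } else {
    out <- p12 + z * sqrt(p12 * (1 - p12) / n)
  }
  # degenerate joint probability: no sampling variance
  deg <- p12 %in% c(0, 1)
  out[deg] <- p12[deg]
  out
}

#' Back-solve the minimum-support bound for the joint probability
#'
#' Inverts the minimum-support equation: given a support level `s`, finds the
#' joint probability `p_star` whose (1 - alpha) upper bound equals `s`, by
#' solving the quadratic
#' \deqn{(n + z^2) p^2 - (2 n s + z^2) p + n s^2 = 0}
#' and taking the smaller root (the larger root is extraneous, introduced by
#' squaring). Consequents whose marginal `p2` falls below `p_star / p1` cannot
#' support a rule whose null upper bound reaches `s`, which is the basis of
#' the candidate screen in [mine_rules()].
#'
#' @param n Number of baskets.
#' @param s Target support level, in (0, 1).
#' @param alpha One-sided significance level in (0, 0.5].
#' @param compat Normal-quantile convention passed to [z_alpha()].
#' @return The root `p_star` in (0, s\]; plugging it back into the
#'   minimum-support formula recovers `s` to 1e-9.
#' @examples
#' p_star <- back_solve_joint_probability(1000, 0.2312, 0.05)
#' minimum_support_from_joint <- p_star + 1.645 * sqrt(p_star * (1 - p_star) / 1000)
#' @export
back_solve_joint_probability <- function(n, s, alpha = 0.05,
                                         compat = c("printed", "exact")) {
  compat <- match.arg(compat)
  if (any(s <= 0) || any(s >= 1)) stop("`s` must lie in (0, 1)", call. = FALSE)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  check_alpha(alpha)
  z <- z_alpha(alpha, compat)
  a <- n + z^2
  b <- -(2 * n * s + z^2)
  cc <- n * s^2
  disc <- b^2 - 4 * a * cc
  if (any(disc < 0)) {
    stop("no real root: support level unattainable for given n and alpha",
      call. = FALSE
    )
  }
  (-b - sqrt(disc)) / (2 * a)
}
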