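#' Simulate a two-group expression matrix with planted signal
#'
#' Null genes are drawn Normal(0, `noise_sd`) in both groups; planted-up genes
#' are shifted by `+effect * noise_sd` in the case group, planted-down genes
#' by `-effect * noise_sd`. Gene ids encode the ground truth (`up_0001`,
#' `down_0001`, `null_0001`), so recovery can be scored without bookkeeping.
#' Values are on an additive (log-like) scale; set `linear_scale = TRUE` to
#' exponentiate (base 2) for exercising linear fold-change labelling.
#'
#' Defaults mirror a small two-colour / two-condition screen: 100 genes of
#' which 5 up- and 5 down-regulated, 8 samples per group, unit noise, a
#' 4-standard-deviation shift.
#'
#' @param n_genes Total genes.
#' @param n_per_group Samples per group (groups `"case"` and `"control"`).
#' @param n_planted_up,n_planted_down Planted differentially expressed genes;
#'   their sum cannot exceed `n_genes`.
#' @param effect Mean shift in units of `noise_sd`.
#' @param noise_sd Residual standard deviation, > 0.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param linear_scale Exponentiate values (base 2) before returning.
#' @return A list with elements `expr` (tibble: `gene_id` + sample columns),
#'   `groups` (tibble: `sample_id`, `group`) and `truth` (tibble: `gene_id`,
#'   `planted` in c("up", "down", "null")). Samples are named
#'   `case_1..case_k`, `control_1..control_k`.
#' @export
simulate_two_group_matrix <- function(n_genes = 100, n_per_group = 8,
                                      n_planted_up = 5, n_planted_down = 5,
                                      effect = 4, noise_sd = 1,
                                      seed = NULL, linear_scale = FALSE) {
  if (n_genes < 1 || n_per_group < 1) {
    stop("`n_genes` and `n_per_group` must be >= 1", call. = FALSE)
  }
  if (n_planted_up + n_planted_down > n_genes) {
    stop("planted genes cannot exceed `n_genes`", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  n_null <- n_genes - n_planted_up - n_planted_down
  gene_id <- c(
    sprintf("up_%04d", seq_len(n_planted_up)),
    sprintf("down_%04d", seq_len(n_planted_down)),
    sprintf("null_%04d", seq_len(n_null))
  )
  planted <- rep(c("up", "down", "null"), c(n_planted_up, n_planted_down, n_null))
  samples <- c(
    paste0("case_", seq_len(n_per_group)),
    paste0("control_", seq_len(n_per_group))
  )
  m <- matrix(stats::rnorm(n_genes * 2 * n_per_group, 0, noise_sd),
    nrow = n_genes, dimnames = list(gene_id, samples)
  )
  case_cols <- seq_len(n_per_group)
  shift <- effect * noise_sd
  m[planted == "up", case_cols] <- m[planted == "up", case_cols] + shift
  m[planted == "down", case_cols] <- m[planted == "down", case_cols] - shift
  if (linear_scale) m <- 2^m
  list(
    expr = tibble::tibble(gene_id = gene_id, tibble::as_tibble(m)),
    groups = tibble::tibble(
      sample_id = samples,
      group = rep(c("case", "control"), each = n_per_group)
    ),
    truth = tibble::tibble(gene_id = gene_id, planted = planted)
  )
}

#' Simulate independent Bernoulli baskets for one rule
#'
#' Draws `n` baskets in which the antecedent item is present with probability
#' `p1` and the consequent class membership is drawn independently with
#' probability `p2` — the null model under which the dynamic thresholds are
#' derived.
#'
#' @param n Number of baskets (samples).
#' @param p1 Antecedent probability.
#' @param p2 Consequent (class) probability.
#' @param seed Optional integer seed.
#' @return A list with `labels` (tibble: one gene `item` whose label is +1
#'   when the antecedent is present, else 0) and `groups` (tibble: classes
#'   `"B"` / `"notB"`), directly consumable by [count_rule()] and
#'   [mine_rules()].
#' @export
simulate_independent_baskets <- function(n, p1, p2, seed = NULL) {
  check_proportion(p1, "p1")
  check_proportion(p2, "p2")
  if (!is.null(seed)) withr::local_seed(seed)
  a <- stats::rbinom(n, 1, p1)
  b <- stats::rbinom(n, 1, p2)
  samples <- paste0("s", seq_len(n))
  labels <- tibble::tibble(gene_id = "item")
  labels[samples] <- as.list(as.integer(a))
  list(
    labels = labels,
    groups = tibble::tibble(
      sample_id = samples,
      group = ifelse(b == 1, "B", "notB")
    )
  )
}

#' Simulate rule tallies under independence, in bulk
#'
#' Tally-level equivalent of repeating [simulate_independent_baskets()]:
#' per replicate, `n_A ~ Bin(n, p1)`, `n_B ~ Bin(n, p2)` and, by independence,
#' `n_AB | n_A ~ Bin(n_A, p2)`. Used for Monte-Carlo calibration of the
#' dynamic thresholds at scale.
#'
#' @param n_replicates Number of independent basket sets.
#' @param n Baskets per set.
#' @param p1,p2 Marginal probabilities.
#' @param seed Optional integer seed.
#' @return A tibble with columns `n`, `n_A`, `n_B`, `n_AB`, `support`,
#'   `confidence` (`NA` where `n_A = 0`).
#' @export
simulate_rule_counts <- function(n_replicates, n, p1, p2, seed = NULL) {
  check_proportion(p1, "p1")
  check_proportion(p2, "p2")
  if (!is.null(seed)) withr::local_seed(seed)
  n_A <- stats::rbinom(n_replicates, n, p1)
  n_AB <- stats::rbinom(n_replicates, n_A, p2)
  # n_B must agree with n_AB on the n_A antecedent baskets
  n_B <- n_AB + stats::rbinom(n_replicates, n - n_A, p2)
  tibble::tibble(
    n = n, n_A = n_A, n_B = n_B, n_AB = n_AB,
    support = n_AB / n,
    confidence = ifelse(n_A > 0, n_AB / n_A, NA_real_)
  )
}
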