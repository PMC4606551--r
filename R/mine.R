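#' Enumerate candidate rules
#'
#' Candidate antecedents are single items `(gene, level)` or unordered pairs
#' of items over two distinct genes, crossed with every consequent class.
#' Enumeration order is deterministic: gene index (pairs in `i < j` order),
#' then level in -1 < 0 < +1 order, then class in the order given.
#'
#' @param labels Label tibble (`gene_id` plus sample columns with values in
#'   \{-1, 0, 1\}).
#' @param classes Character vector of consequent class labels.
#' @param max_antecedent Antecedent size, 1 or 2.
#' @param levels Subset of `c(-1, 0, 1)` to mine. Default `c(-1, 1)`:
#'   up/down-regulation rules; include 0 to also mine "not differentially
#'   expressed" rules.
#' @return A tibble with columns `antecedent` (serialized as
#'   `"+1:geneA"` or `"+1:geneA,-1:geneB"`, pair members sorted by gene id)
#'   and `consequent`.
#' @export
enumerate_candidates <- function(labels, classes, max_antecedent = 1,
                                 levels = c(-1, 1)) {
  labels <- check_expression(labels)
  if (!max_antecedent %in% c(1, 2)) {
    stop("`max_antecedent` must be 1 or 2", call. = FALSE)
  }
  if (!all(levels %in% c(-1, 0, 1)) || length(levels) == 0) {
    stop("`levels` must be a non-empty subset of c(-1, 0, 1)", call. = FALSE)
  }
  items <- item_grid(labels$gene_id, levels, max_antecedent)
  tidyr::expand_grid(antecedent = items, consequent = as.character(classes))
}

# serialized antecedents in deterministic order
item_grid <- function(gene_ids, levels, max_antecedent) {
  levels <- sort(levels)
  if (max_antecedent == 1) {
    g <- tidyr::expand_grid(gene = gene_ids, level = levels)
    return(item_string(g$level, g$gene))
  }
  ng <- length(gene_ids)
  if (ng < 2) {
    return(character(0))
  }
  pairs <- utils::combn(ng, 2)
  out <- character(0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    for (l1 in levels) {
      for (l2 in levels) {
        out <- c(out, paste(
          item_string(l1, gene_ids[i]),
          item_string(l2, gene_ids[j]),
          sep = ","
        ))
      }
    }
  }
  out
}

item_string <- function(level, gene) {
  paste0(ifelse(level >= 0, "+", ""), level, ":", gene)
}

#' Parse a serialized antecedent
#'
#' @param antecedent Character vector of serialized antecedents, e.g.
#'   `"+1:geneA,-1:geneB"`.
#' @return A tibble with columns `antecedent`, `gene_id`, `level` (one row
#'   per item).
#' @export
parse_antecedent <- function(antecedent) {
  items <- strsplit(antecedent, ",", fixed = TRUE)
  purrr::map2_dfr(antecedent, items, function(a, it) {
    m <- regmatches(it, regexec("^([+-]?[01]):(.+)$", it))
    bad <- vapply(m, length, integer(1)) != 3
    if (any(bad)) {
      stop("malformed antecedent item(s): ", paste(it[bad], collapse = ", "),
        call. = FALSE
      )
    }
    tibble::tibble(
      antecedent = a,
      gene_id = vapply(m, `[`, "", 3),
      level = as.integer(vapply(m, `[`, "", 2))
    )
  })
}

#' Count rule tallies in a labelled dataset
#'
#' @param labels Label tibble (`gene_id` plus sample columns).
#' @param groups Groups tibble (`sample_id`, `group`).
#' @param antecedent Serialized antecedent (see [parse_antecedent()]).
#' @param consequent Class label.
#' @return A one-row tibble of tallies as in [rule_counts()]: `n` samples,
#'   `n_A` matching every antecedent item, `n_B` in the consequent class,
#'   `n_AB` matching both.
#' @export
count_rule <- function(labels, groups, antecedent, consequent) {
  labels <- check_expression(labels)
  groups <- check_groups(groups, labels)
  if (!consequent %in% groups$group) {
    stop("unknown class: ", consequent, call. = FALSE)
  }
  items <- parse_antecedent(antecedent)
  missing <- setdiff(items$gene_id, labels$gene_id)
  if (length(missing) > 0) {
    stop("unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- setdiff(names(labels), "gene_id")
  m <- as.matrix(labels[samples])
  rownames(m) <- labels$gene_id
  match_a <- rep(TRUE, length(samples))
  for (r in seq_len(nrow(items))) {
    match_a <- match_a & (m[items$gene_id[r], ] == items$level[r])
  }
  in_b <- groups$group[match(samples, groups$sample_id)] == consequent
  rule_counts(
    n = length(samples), n_A = sum(match_a),
    n_B = sum(in_b), n_AB = sum(match_a & in_b)
  )
}

#' Mine association rules with dynamic or fixed thresholds
#'
#' Enumerates every candidate rule (see [enumerate_candidates()]), tallies it,
#' and flags it `meaningful` when its estimated support and confidence both
#' strictly exceed their thresholds. In `"dynamic"` mode the thresholds are
#' recomputed per rule from its own estimated marginals: the minimum support
#' from the one-sided normal bound ([minimum_support()]) and the minimum
#' confidence from the exact null distribution of the confidence ratio
#' ([minimum_confidence()]), both at `p1 = n_A/n` and `p2 = n_B/n`. In
#' `"fixed"` mode user-supplied `min_support` and `min_confidence` are used
#' instead. Rules whose antecedent matches no sample (`n_A = 0`) are dropped.
#'
#' No multiple-testing correction is applied; a message reports how many
#' candidates were evaluated.
#'
#' @inheritParams enumerate_candidates
#' @param groups Groups tibble (`sample_id`, `group`); at least two classes.
#' @param alpha One-sided significance level in (0, 0.5].
#' @param classes Consequent classes; defaults to every group, in order of
#'   first appearance.
#' @param mode `"dynamic"` (per-rule thresholds) or `"fixed"`.
#' @param min_support,min_confidence Fixed-mode thresholds.
#' @param prune_by_backsolve In dynamic mode, skip candidates whose maximum
#'   achievable support `min(n_A, n_B)/n` cannot strictly exceed their dynamic
#'   minimum support — the quadratic-inversion screen of
#'   [back_solve_joint_probability()]. Pruned candidates are provably not
#'   meaningful, so the meaningful rule set is unchanged; only the returned
#'   non-meaningful rows (and runtime) differ.
#' @param compat Normal-quantile convention passed to [minimum_support()].
#' @param convention,step Confidence-quantile convention passed to
#'   [minimum_confidence()].
#' @return A tibble of class `dar_rules` with columns `antecedent`,
#'   `consequent`, `n`, `n_A`, `n_B`, `n_AB`, `support`, `confidence`,
#'   `s_min`, `c_min`, `meaningful`. Attributes record `alpha`, `mode` and
#'   the candidate count.
#' @export
mine_rules <- function(labels, groups, alpha = 0.05, max_antecedent = 1,
                       levels = c(-1, 1), classes = NULL,
                       mode = c("dynamic", "fixed"),
                       min_support = NULL, min_confidence = NULL,
                       prune_by_backsolve = FALSE,
                       compat = c("printed", "exact"),
                       convention = c("grid", "atom"), step = 0.001) {
  mode <- match.arg(mode)
  compat <- match.arg(compat)
  convention <- match.arg(convention)
  labels <- check_expression(labels)
  groups <- check_groups(groups, labels)
  check_alpha(alpha)
  if (length(unique(groups$group)) < 2) {
    stop("at least two classes are required for mining", call. = FALSE)
  }
  if (is.null(classes)) classes <- unique(groups$group)
  if (mode == "fixed" && (is.null(min_support) || is.null(min_confidence))) {
    stop("fixed mode needs `min_support` and `min_confidence`", call. = FALSE)
  }

  tallies <- tally_candidates(labels, groups, classes, max_antecedent, levels)
  rlang::inform(
    paste0(
      "evaluated ", nrow(tallies), " candidate rules without ",
      "multiple-testing correction"
    ),
    class = "darules_candidate_count"
  )
  rules <- tallies |> dplyr::filter(.data$n_A > 0)

  if (mode == "dynamic") {
    rules <- rules |>
      dplyr::mutate(
        s_min = minimum_support(.data$n_A / .data$n, .data$n_B / .data$n,
          .data$n, alpha,
          compat = compat
        )
      )
    if (prune_by_backsolve) {
      rules <- rules |>
        dplyr::filter(pmin(.data$n_A, .data$n_B) / .data$n > .data$s_min)
    }
    # the confidence threshold depends only on (n, n_A, n_B, alpha): memoize
    thr <- rules |>
      dplyr::distinct(.data$n, .data$n_A, .data$n_B) |>
      dplyr::mutate(c_min = purrr::pmap_dbl(
        list(.data$n, .data$n_A, .data$n_B),
        function(n, a, b) {
          minimum_confidence(n, a / n, b / n, alpha,
            convention = convention, step = step
          )
        }
      ))
    rules <- dplyr::left_join(rules, thr, by = c("n", "n_A", "n_B"))
  } else {
    rules <- rules |>
      dplyr::mutate(s_min = min_support, c_min = min_confidence)
  }

  rules <- rules |>
    dplyr::mutate(
      support = .data$n_AB / .data$n,
      confidence = .data$n_AB / .data$n_A,
      meaningful = .data$support > .data$s_min & .data$confidence > .data$c_min
    ) |>
    dplyr::select(
      "antecedent", "consequent", "n", "n_A", "n_B", "n_AB",
      "support", "confidence", "s_min", "c_min", "meaningful"
    )
  new_dar_rules(rules,
    alpha = alpha, mode = mode, n_candidates = nrow(tallies),
    max_antecedent = max_antecedent
  )
}

new_dar_rules <- function(rules, ...) {
  attrs <- list(...)
  rules <- tibble::as_tibble(rules)
  for (nm in names(attrs)) attr(rules, nm) <- attrs[[nm]]
  class(rules) <- unique(c("dar_rules", class(rules)))
  rules
}

# vectorised tallies for all candidates: indicator matrices over samples
tally_candidates <- function(labels, groups, classes, max_antecedent, levels) {
  if (!max_antecedent %in% c(1, 2)) {
    stop("`max_antecedent` must be 1 or 2", call. = FALSE)
  }
  if (!all(levels %in% c(-1, 0, 1)) || length(levels) == 0) {
    stop("`levels` must be a non-empty subset of c(-1, 0, 1)", call. = FALSE)
  }
  levels <- sort(levels)
  samples <- setdiff(names(labels), "gene_id")
  n <- length(samples)
  m <- as.matrix(labels[samples])
  grp <- groups$group[match(samples, groups$sample_id)]

  # one indicator row per (gene, level), gene-major, levels ascending
  items <- tidyr::expand_grid(gene = labels$gene_id, level = levels)
  ind <- matrix(0L, nrow(items), n)
  for (k in seq_along(levels)) {
    rows <- which(items$level == levels[k])
    ind[rows, ] <- (m == levels[k]) + 0L
  }
  class_ind <- lapply(classes, function(cl) as.integer(grp == cl))
  names(class_ind) <- classes

  if (max_antecedent == 1) {
    ante <- item_string(items$level, items$gene)
    n_A <- as.integer(rowSums(ind))
    per_class <- purrr::map_dfr(classes, function(cl) {
      b <- class_ind[[cl]]
      tibble::tibble(
        antecedent = ante, consequent = cl,
        n = n, n_A = n_A, n_B = sum(b),
        n_AB = as.integer(ind %*% b)
      )
    })
    # deterministic order: gene index, level, class as given
    per_class <- per_class |>
      dplyr::mutate(.item = rep(seq_len(nrow(items)), length(classes))) |>
      dplyr::arrange(.data$.item, match(.data$consequent, classes)) |>
      dplyr::select(-".item")
    return(per_class)
  }

  ng <- length(labels$gene_id)
  if (ng < 2) {
    return(tibble::tibble(
      antecedent = character(0), consequent = character(0),
      n = integer(0), n_A = integer(0), n_B = integer(0), n_AB = integer(0)
    ))
  }
  # pair tallies via cross products of item indicators
  co_all <- ind %*% t(ind)
  co_class <- lapply(classes, function(cl) {
    sel <- ind[, class_ind[[cl]] == 1L, drop = FALSE]
    sel %*% t(sel)
  })
  names(co_class) <- classes
  nl <- length(levels)
  item_row <- function(g, l) (g - 1L) * nl + match(l, levels)
  pairs <- utils::combn(ng, 2)
  recs <- vector("list", ncol(pairs) * nl * nl)
  idx <- 0L
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    for (l1 in levels) {
      for (l2 in levels) {
        idx <- idx + 1L
        r1 <- item_row(i, l1)
        r2 <- item_row(j, l2)
        recs[[idx]] <- list(
          antecedent = paste(
            item_string(l1, labels$gene_id[i]),
            item_string(l2, labels$gene_id[j]),
            sep = ","
          ),
          n_A = co_all[r1, r2],
          n_AB = unname(vapply(classes, function(cl) co_class[[cl]][r1, r2], numeric(1)))
        )
      }
    }
  }
  purrr::map_dfr(recs, function(r) {
    tibble::tibble(
      antecedent = r$antecedent, consequent = classes,
      n = n, n_A = as.integer(r$n_A),
      n_B = unname(vapply(classes, function(cl) sum(class_ind[[cl]]), integer(1))),
      n_AB = as.integer(r$n_AB)
    )
  })
}
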