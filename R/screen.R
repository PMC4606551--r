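#' Find ambiguous (conflicting) meaningful rules
#'
#' Two conflict types are flagged among meaningful rules:
#'
#' * Type A (consequent conflict): the identical antecedent itemset is
#'   meaningful towards two or more different consequents.
#' * Type B (level conflict): the same gene is meaningful at both +1 and -1
#'   towards the same consequent. Applied to single-antecedent rules only —
#'   a gene genuinely interacting with others can legitimately appear at both
#'   levels inside double antecedents. Level-0 rules never conflict.
#'
#' Every member of a conflicting group is marked for removal; no tie-break
#' retains one side.
#'
#' @param rules A `dar_rules` tibble whose rows are all meaningful (e.g.
#'   `dplyr::filter(rules, meaningful)`).
#' @return A list of class `dar_ambiguity` with elements `conflicts` (tibble:
#'   `type`, one list-column `members` of row indices), `removed` and
#'   `retained` (integer row indices into `rules`).
#' @export
find_ambiguous <- function(rules) {
  if (nrow(rules) > 0 && !all(rules$meaningful)) {
    stop("`find_ambiguous()` expects meaningful rules only", call. = FALSE)
  }
  conflicts <- list()
  # type A: same antecedent, different consequents
  by_ante <- split(seq_len(nrow(rules)), rules$antecedent)
  for (idx in by_ante) {
    if (length(unique(rules$consequent[idx])) > 1) {
      conflicts[[length(conflicts) + 1]] <- list(type = "consequent-conflict", members = idx)
    }
  }
  # type B: single-antecedent, same gene at +1 and -1, same consequent
  single <- which(!grepl(",", rules$antecedent, fixed = TRUE))
  if (length(single) > 0) {
    items <- parse_antecedent(rules$antecedent[single])
    info <- tibble::tibble(
      row = single,
      gene_id = items$gene_id, level = items$level,
      consequent = rules$consequent[single]
    )
    grps <- dplyr::group_by(info, .data$gene_id, .data$consequent)
    keys <- dplyr::group_split(grps)
    for (g in keys) {
      if (all(c(-1L, 1L) %in% g$level)) {
        idx <- g$row[g$level %in% c(-1L, 1L)]
        conflicts[[length(conflicts) + 1]] <- list(type = "level-conflict", members = idx)
      }
    }
  }
  removed <- sort(unique(unlist(lapply(conflicts, `[[`, "members"))))
  if (is.null(removed)) removed <- integer(0)
  structure(
    list(
      conflicts = tibble::tibble(
        type = vapply(conflicts, `[[`, "", "type"),
        members = lapply(conflicts, `[[`, "members")
      ),
      removed = removed,
      retained = setdiff(seq_len(nrow(rules)), removed)
    ),
    class = "dar_ambiguity"
  )
}

#' Screen ambiguous rules out of a mined rule set
#'
#' Keeps the meaningful rules, removes every member of each conflicting group
#' found by [find_ambiguous()], and returns the survivors. Idempotent. With
#' `keep_all = TRUE` the full input is returned instead, annotated with
#' logical columns `ambiguous` and `final` (meaningful and not ambiguous).
#'
#' @param rules A `dar_rules` tibble from [mine_rules()].
#' @param keep_all Return all rules annotated rather than survivors only.
#' @return A `dar_rules` tibble.
#' @export
screen_rules <- function(rules, keep_all = FALSE) {
  meaningful <- dplyr::filter(rules, .data$meaningful)
  report <- find_ambiguous(meaningful)
  survivors <- meaningful[report$retained, , drop = FALSE]
  if (!keep_all) {
    return(new_dar_rules(survivors,
      alpha = attr(rules, "alpha"), mode = attr(rules, "mode"),
      screened = TRUE
    ))
  }
  ambiguous_ante <- meaningful$antecedent[report$removed]
  ambiguous_cons <- meaningful$consequent[report$removed]
  key <- paste(rules$antecedent, rules$consequent, sep = "\r")
  amb <- key %in% paste(ambiguous_ante, ambiguous_cons, sep = "\r")
  out <- dplyr::mutate(rules,
    ambiguous = amb & .data$meaningful,
    final = .data$meaningful & !amb
  )
  new_dar_rules(out,
    alpha = attr(rules, "alpha"), mode = attr(rules, "mode"),
    screened = TRUE
  )
}

#' Final gene set of a screened rule set
#'
#' The sorted union of gene ids appearing in any surviving antecedent.
#'
#' @param rules A `dar_rules` tibble of surviving rules (see
#'   [screen_rules()]); if annotated with a `final` column, only final rules
#'   are used.
#' @return Character vector of gene ids, sorted, deduplicated.
#' @export
final_gene_set <- function(rules) {
  if ("final" %in% names(rules)) rules <- dplyr::filter(rules, .data$final)
  if (nrow(rules) == 0) {
    return(character(0))
  }
  sort(unique(parse_antecedent(rules$antecedent)$gene_id))
}
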