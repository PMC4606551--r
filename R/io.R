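#' Read and write expression matrices and group files
#'
#' The expression format is tab-separated with gene ids in the first column
#' and sample ids in the header; the group file is two tab-separated columns
#' `sample_id` and `group` (header optional but recommended). Ids are
#' preserved verbatim.
#'
#' @param path File path.
#' @return `read_expression_matrix()`: a tibble `gene_id` + numeric sample
#'   columns. `read_groups()`: a tibble `sample_id`, `group`.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_expression_matrix <- function(path) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 2) stop("expression file needs gene ids plus >= 1 sample", call. = FALSE)
  names(raw)[1] <- "gene_id"
  if (anyDuplicated(raw$gene_id)) {
    stop("duplicate gene ids: ",
      paste(unique(raw$gene_id[duplicated(raw$gene_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  for (s in names(raw)[-1]) {
    x <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(x) & !is.na(raw[[s]]) & raw[[s]] != "NA")
    if (length(bad) > 0) {
      stop("non-numeric value for gene '", raw$gene_id[bad[1]],
        "', sample '", s, "': ", raw[[s]][bad[1]],
        call. = FALSE
      )
    }
    raw[[s]] <- x
  }
  raw
}

#' @rdname expression_io
#' @export
read_groups <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^sample_id\t", first)
  groups <- readr::read_tsv(path,
    col_names = if (has_header) TRUE else c("sample_id", "group"),
    skip = 0,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("sample_id", "group") %in% names(groups))) {
    names(groups)[1:2] <- c("sample_id", "group")
  }
  groups[c("sample_id", "group")]
}

#' @rdname expression_io
#' @param expr,groups Tibbles as returned by the readers.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(check_expression(expr), path, progress = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
write_groups <- function(groups, path) {
  readr::write_tsv(check_groups(groups), path, progress = FALSE)
  invisible(path)
}

#' Read and write mined rule tables
#'
#' Tab-separated with the column contract of [mine_rules()] (plus `ambiguous`
#' and `final` when screened): `antecedent`, `consequent`, `n`, `n_A`, `n_B`,
#' `n_AB`, `support`, `confidence`, `s_min`, `c_min`, `meaningful`
#' \[, `ambiguous`, `final`\]. Proportions are serialized at 6 decimal
#' places; antecedents as `"+1:geneA,-1:geneB"`.
#'
#' @param rules A `dar_rules` tibble.
#' @param path File path.
#' @return `write_rule_table()` returns `path` invisibly;
#'   `read_rule_table()` returns a `dar_rules` tibble.
#' @name rule_io
NULL

rule_float_cols <- c("support", "confidence", "s_min", "c_min")

#' @rdname rule_io
#' @export
write_rule_table <- function(rules, path) {
  out <- tibble::as_tibble(rules)
  for (cl in intersect(rule_float_cols, names(out))) {
    out[[cl]] <- sprintf("%.6f", out[[cl]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname rule_io
#' @export
read_rule_table <- function(path) {
  spec <- readr::cols(
    antecedent = readr::col_character(),
    consequent = readr::col_character(),
    n = readr::col_integer(), n_A = readr::col_integer(),
    n_B = readr::col_integer(), n_AB = readr::col_integer(),
    support = readr::col_double(), confidence = readr::col_double(),
    s_min = readr::col_double(), c_min = readr::col_double(),
    meaningful = readr::col_logical(),
    .default = readr::col_logical()
  )
  rules <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  parse_antecedent(rules$antecedent) # validates serialization
  new_dar_rules(rules)
}

#' Write a critical-value table in block layout
#'
#' Renders the long table from [critical_value_table()] in the reference
#' layout: blocks by consequent marginal `p2`, rows by confidence level,
#' columns by antecedent marginal `p1`.
#'
#' @param table Long tibble from [critical_value_table()].
#' @param path File path.
#' @export
write_critical_value_table <- function(table, path) {
  wide <- table |>
    tidyr::pivot_wider(
      names_from = "p1", values_from = "c_min",
      names_prefix = "p1_"
    ) |>
    dplyr::mutate(level = sprintf("%.0f%%", 100 * .data$level))
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
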