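#' Lowess normalization of two-colour log-ratios (MA normalization)
#'
#' Removes the intensity-dependent trend from two-colour array log-ratios:
#' `M = log2(R/G)` is replaced by `M - c(A)`, where `c(A)` is the lowess fit
#' of M on the average log-intensity `A = log2(sqrt(R*G))`.
#'
#' @param M Per-spot log-ratios.
#' @param A Per-spot average log-intensities, same length as `M`.
#' @param span Lowess smoother fraction, in (0, 1]. Default 2/3, the
#'   conventional choice.
#' @return Normalized log-ratios `M - c(A)`.
#' @examples
#' A <- runif(100, 6, 14)
#' M <- 0.2 * A + rnorm(100, sd = 0.1)
#' M_norm <- normalize_ma_lowess(M, A)
#' @export
normalize_ma_lowess <- function(M, A, span = 2 / 3) {
  if (length(M) != length(A)) {
    stop("`M` and `A` must have the same length", call. = FALSE)
  }
  if (length(M) < 10) {
    stop("at least 10 spots are needed to fit the smoother", call. = FALSE)
  }
  if (!is.numeric(span) || span <= 0 || span > 1) {
    stop("`span` must lie in (0, 1]", call. = FALSE)
  }
  fit <- stats::lowess(A, M, f = span)
  trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  M - trend
}

#' Per-sample median/IQR normalization
#'
#' Centres every sample column at its median and scales it by its
#' interquartile range, the preprocessing used for single-channel intensity
#' cohorts before per-gene labelling.
#'
#' @param expr Expression tibble: a `gene_id` column plus one numeric column
#'   per sample.
#' @return The tibble with every sample column transformed to
#'   `(x - median) / (Q3 - Q1)` (median 0, IQR 1).
#' @export
normalize_median_iqr <- function(expr) {
  expr <- check_expression(expr)
  samples <- setdiff(names(expr), "gene_id")
  for (s in samples) {
    x <- expr[[s]]
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    if (!is.finite(iqr) || iqr == 0) {
      stop("sample '", s, "' has zero interquartile range; cannot scale",
        call. = FALSE
      )
    }
    expr[[s]] <- (x - stats::median(x, na.rm = TRUE)) / iqr
  }
  expr
}

#' Label expression values by fixed thresholds
#'
#' Maps each (already normalized) value to a label in \{-1, 0, +1\}:
#' `+1` when the value is >= `up`, `-1` when <= `down`, `0` otherwise.
#' Boundaries are inclusive. Missing values are labelled 0 (treated as not
#' differentially expressed).
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param up,down Upper and lower cutoffs; defaults +1/-1, the standard
#'   cutoffs for log2-ratio data. `up` must exceed `down`.
#' @return A label tibble of the same shape with integer entries in
#'   \{-1, 0, 1\}.
#' @export
label_by_threshold <- function(expr, up = 1, down = -1) {
  expr <- check_expression(expr)
  if (!(up > down)) stop("`up` must exceed `down`", call. = FALSE)
  label_with(expr, function(x) {
    ifelse(is.na(x), 0L, ifelse(x >= up, 1L, ifelse(x <= down, -1L, 0L)))
  })
}

#' Label expression values by fold change against a baseline group
#'
#' Each gene's baseline is the mean of its values over the baseline-group
#' samples. On the linear scale a value is labelled `+1` when
#' `value/baseline > up_ratio` and `-1` when `< down_ratio` (strict
#' inequalities); on the log2 scale the difference `value - baseline` is
#' compared against the cutoffs directly (so `up_ratio = 1, down_ratio = -1`
#' corresponds to a two-fold change in either direction). Missing values are
#' labelled 0.
#'
#' Presets used in the case studies: two-fold (`up_ratio = 2,
#' down_ratio = 0.5`, linear), 1.5-fold (`up_ratio = 1.5, down_ratio = 2/3`,
#' linear) and log-ratio (`up_ratio = 1, down_ratio = -1`, log2).
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param groups Groups tibble (`sample_id`, `group`).
#' @param baseline_group Group label whose per-gene mean serves as baseline.
#' @param up_ratio,down_ratio Cutoffs; `up_ratio > down_ratio` and, on the
#'   linear scale, both positive.
#' @param scale `"linear"` (ratios) or `"log2"` (differences).
#' @param on_zero_baseline On the linear scale, what to do with genes whose
#'   baseline mean is 0: `"error"` (default) or `"skip"` (label the gene 0
#'   everywhere, with a warning naming the genes).
#' @return A label tibble of the same shape with entries in \{-1, 0, 1\}.
#' @export
label_by_fold_change <- function(expr, groups, baseline_group,
                                 up_ratio = 2, down_ratio = 0.5,
                                 scale = c("linear", "log2"),
                                 on_zero_baseline = c("error", "skip")) {
  scale <- match.arg(scale)
  on_zero_baseline <- match.arg(on_zero_baseline)
  expr <- check_expression(expr)
  groups <- check_groups(groups, expr)
  if (!(up_ratio > down_ratio)) {
    stop("`up_ratio` must exceed `down_ratio`", call. = FALSE)
  }
  if (scale == "linear" && down_ratio <= 0) {
    stop("linear-scale ratios must be positive", call. = FALSE)
  }
  base_samples <- groups$sample_id[groups$group == baseline_group]
  if (length(base_samples) == 0) {
    stop("baseline group '", baseline_group, "' has no samples", call. = FALSE)
  }
  samples <- setdiff(names(expr), "gene_id")
  baseline <- rowMeans(as.matrix(expr[base_samples]), na.rm = TRUE)
  if (scale == "linear" && any(baseline == 0)) {
    bad <- expr$gene_id[baseline == 0]
    if (on_zero_baseline == "error") {
      stop("zero baseline mean for gene(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    warning("zero baseline mean; labelling gene(s) 0 throughout: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out <- expr
  for (s in samples) {
    x <- expr[[s]]
    if (scale == "linear") {
      r <- ifelse(baseline == 0, NA_real_, x / baseline)
      out[[s]] <- ifelse(is.na(r), 0L,
        ifelse(r > up_ratio, 1L, ifelse(r < down_ratio, -1L, 0L))
      )
    } else {
      d <- x - baseline
      out[[s]] <- ifelse(is.na(d), 0L,
        ifelse(d > up_ratio, 1L, ifelse(d < down_ratio, -1L, 0L))
      )
    }
  }
  out
}

#' Label expression values by per-gene z-score (transitional state
#' discrimination)
#'
#' Each gene row is standardised to `z = (x - mean)/sd` across all samples and
#' labelled `+1` when `z >= 1`, `-1` when `z <= -1`, `0` otherwise (inclusive
#' boundaries). Genes with zero variance are labelled 0 throughout; missing
#' values are labelled 0. Labels are invariant to positive affine transforms
#' of a gene row.
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return A label tibble of the same shape with entries in \{-1, 0, 1\}.
#' @export
label_by_tsd <- function(expr, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  expr <- check_expression(expr)
  samples <- setdiff(names(expr), "gene_id")
  m <- as.matrix(expr[samples])
  mu <- rowMeans(m, na.rm = TRUE)
  cen <- m - mu
  denom <- rowSums(!is.na(m)) - (sd_type == "sample")
  sdv <- sqrt(rowSums(cen^2, na.rm = TRUE) / pmax(denom, 1))
  z <- cen / ifelse(sdv > 0, sdv, Inf)
  lab <- ifelse(is.na(z), 0L, ifelse(z >= 1, 1L, ifelse(z <= -1, -1L, 0L)))
  out <- expr
  out[samples] <- as.data.frame(lab)
  out
}

#' Discretize an expression matrix with a named preset
#'
#' One-call composition of the normalization and labelling scheme used in each
#' case study:
#'
#' * `"threshold"`: [label_by_threshold()] with cutoffs +/-1 on values assumed
#'   already normalized (e.g. lowess-normalized log-ratios).
#' * `"fold2"`: [label_by_fold_change()] with ratios 2 and 0.5 on the linear
#'   scale against `baseline_group`.
#' * `"fold1.5"`: [label_by_fold_change()] with ratios 1.5 and 2/3.
#' * `"maqc-log"`: [label_by_fold_change()] on the log2 scale with cutoffs
#'   +/-1 against `baseline_group`.
#' * `"tsd"`: [normalize_median_iqr()] followed by [label_by_tsd()].
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param groups Groups tibble; required by the fold-change presets.
#' @param preset Scheme name (see Details).
#' @param baseline_group Baseline group for fold-change presets.
#' @param up,down Optional overrides of the preset cutoffs.
#' @return A label tibble, with the preset recorded in attribute `preset`.
#' @export
discretize <- function(expr, groups = NULL,
                       preset = c("threshold", "fold2", "fold1.5", "maqc-log", "tsd"),
                       baseline_group = NULL, up = NULL, down = NULL) {
  preset <- match.arg(preset)
  need_baseline <- preset %in% c("fold2", "fold1.5", "maqc-log")
  if (need_baseline && (is.null(groups) || is.null(baseline_group))) {
    stop("preset '", preset, "' needs `groups` and `baseline_group`", call. = FALSE)
  }
  labels <- switch(preset,
    "threshold" = label_by_threshold(expr, up %||% 1, down %||% -1),
    "fold2" = label_by_fold_change(expr, groups, baseline_group,
      up %||% 2, down %||% 0.5,
      scale = "linear"
    ),
    "fold1.5" = label_by_fold_change(expr, groups, baseline_group,
      up %||% 1.5, down %||% (2 / 3),
      scale = "linear"
    ),
    "maqc-log" = label_by_fold_change(expr, groups, baseline_group,
      up %||% 1, down %||% -1,
      scale = "log2"
    ),
    "tsd" = label_by_tsd(normalize_median_iqr(expr))
  )
  attr(labels, "preset") <- preset
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

label_with <- function(expr, f) {
  samples <- setdiff(names(expr), "gene_id")
  out <- expr
  for (s in samples) out[[s]] <- f(expr[[s]])
  out
}

check_expression <- function(expr) {
  if (!is.data.frame(expr)) stop("expression data must be a data frame", call. = FALSE)
  if (!"gene_id" %in% names(expr)) {
    stop("expression data must have a `gene_id` column", call. = FALSE)
  }
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicate gene ids: ",
      paste(unique(expr$gene_id[duplicated(expr$gene_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  samples <- setdiff(names(expr), "gene_id")
  if (length(samples) == 0) stop("no sample columns", call. = FALSE)
  bad <- samples[!vapply(expr[samples], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric sample columns: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(expr)
}

check_groups <- function(groups, expr = NULL) {
  if (!is.data.frame(groups) || !all(c("sample_id", "group") %in% names(groups))) {
    stop("`groups` must be a data frame with columns `sample_id` and `group`",
      call. = FALSE
    )
  }
  groups <- tibble::as_tibble(groups)
  groups$sample_id <- as.character(groups$sample_id)
  groups$group <- as.character(groups$group)
  if (!is.null(expr)) {
    samples <- setdiff(names(expr), "gene_id")
    missing <- setdiff(samples, groups$sample_id)
    if (length(missing) > 0) {
      stop("samples missing from the group file: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    extra <- setdiff(groups$sample_id, samples)
    if (length(extra) > 0) {
      warning("group file lists unknown sample(s), ignored: ",
        paste(extra, collapse = ", "),
        call. = FALSE
      )
      groups <- groups[groups$sample_id %in% samples, ]
    }
  }
  groups
}
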