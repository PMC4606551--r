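#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the exact null distribution of the confidence
#'
#' Needle plot of the probability mass on the achievable ratios, optionally
#' with the dynamic minimum confidence marked.
#'
#' @param object A `dar_confdist` from [confidence_distribution()].
#' @param alpha If non-NULL, draw the minimum confidence at this level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dar_confdist
#' @export
autoplot.dar_confdist <- function(object, alpha = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value, y = .data$prob)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$value, yend = 0)) +
    ggplot2::labs(
      x = "confidence under independence",
      y = "probability",
      title = sprintf(
        "Null confidence distribution (n = %d, p1 = %.3g, p2 = %.3g)",
        attr(object, "n"), attr(object, "p1"), attr(object, "p2")
      )
    )
  if (!is.null(alpha)) {
    cmin <- minimum_confidence(attr(object, "n"), attr(object, "p1"),
      attr(object, "p2"),
      alpha = alpha
    )
    p <- p + ggplot2::geom_vline(xintercept = cmin, linetype = "dashed")
  }
  p
}

#' Plot a mined rule set against its dynamic thresholds
#'
#' Each rule is placed at (support excess, confidence excess), i.e. its
#' estimated support and confidence minus the rule's own dynamic thresholds;
#' meaningful rules are the ones strictly in the upper-right quadrant.
#'
#' @param object A `dar_rules` tibble from [mine_rules()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dar_rules
#' @export
autoplot.dar_rules <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(
      support_excess = .data$support - .data$s_min,
      confidence_excess = .data$confidence - .data$c_min
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(.data$support_excess, .data$confidence_excess,
      colour = .data$meaningful
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "support - dynamic minimum support",
      y = "confidence - dynamic minimum confidence",
      colour = "meaningful"
    )
}
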