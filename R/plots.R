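#' Box plot of colonization frequency by tissue and season
#'
#' Distribution of per-cell CF values across tissues, filled by season — the
#' standard at-a-glance view of tissue and seasonal effects in a colonization
#' survey.
#'
#' @param x A long CF tibble.
#' @param positive_only Drop exact-zero (not isolated) entries before
#'   plotting; zeros dominate sparse surveys and flatten the boxes.
#' @return A ggplot object.
#' @examples
#' plot_cf(load_survey_cf())
#' @export
plot_cf <- function(x, positive_only = TRUE) {
  d <- if (positive_only) dplyr::filter(x, .data$cf > 0) else x
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tissue, y = .data$cf,
                                  fill = .data$season)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Colonization frequency (%)",
                  fill = "Season") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-mycodiv
#' @method autoplot mycodiv_diversity
#' @export
autoplot.mycodiv_diversity <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"label",
                              names_to = "index", values_to = "value")
  long$index <- factor(long$index,
                       levels = c("S", "Np", "G", "GR", "D", "one_minus_D",
                                  "H", "E"))
  long$label <- factor(long$label, levels = unique(object$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plots for mycodiv result objects
#'
#' `autoplot()` methods: a faceted index panel for diversity tables, a
#' similarity heat map for Jaccard matrices, and an F-ratio dot chart for
#' three-way ANOVA fits.
#'
#' @param object A `mycodiv_diversity`, `mycodiv_jaccard` or `mycodiv_anova`
#'   object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-mycodiv
#' @rdname autoplot-mycodiv
#' @method autoplot mycodiv_jaccard
#' @export
autoplot.mycodiv_jaccard <- function(object, ...) {
  d <- tidy.mycodiv_jaccard(object)
  d$from <- factor(d$from, levels = rownames(object))
  d$to <- factor(d$to, levels = rev(colnames(object)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$from, y = .data$to,
                                  fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$similarity)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-mycodiv
#' @method autoplot mycodiv_anova
#' @export
autoplot.mycodiv_anova <- function(object, ...) {
  d <- object$table[object$table$term != "Residuals", ]
  d$term <- factor(d$term, levels = rev(d$term))
  d$sig <- significance_label(d$p.value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic, y = .data$term)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "F ratio", y = NULL) +
    ggplot2::theme_minimal()
}
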