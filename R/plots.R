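#' Plot precision and recall per criterion
#'
#' Dodged bar chart of precision and recall for every criterion, faceted by
#' experimental arm (weighting scheme or classification unit) when an `arm`
#' column is present.
#'
#' @param object An `hon_metrics` tibble from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hon_metrics
#' @export
autoplot.hon_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("criterion", intersect("arm", names(object)),
                          "precision", "recall")],
    cols = c("precision", "recall"),
    names_to = "metric", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$criterion, y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if ("arm" %in% names(long)) p <- p + ggplot2::facet_wrap(~arm)
  p
}

#' Plot the most indicative terms of a trained detector
#'
#' Shows, per criterion, the vocabulary terms with the largest
#' positive-vs-negative log-likelihood ratio (cf. [tidy.hon_detector()]).
#'
#' @param object An `hon_detector`.
#' @param n_terms Terms per criterion.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hon_detector
#' @export
autoplot.hon_detector <- function(object, n_terms = 8, ...) {
  top <- tidy(object, n_terms = n_terms)
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$log_odds,
    y = stats::reorder(paste(.data$criterion, .data$term, sep = ": "), .data$log_odds)
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "log likelihood ratio (compliant vs rest)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
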