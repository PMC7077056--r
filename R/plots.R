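#' @import ggplot2
NULL

#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: the prioritized
#' score list (overall score, log scale, against final rank, top candidates
#' labelled), the ROC curve with its chance diagonal, and the degree
#' histogram with the fitted log-log line.
#'
#' @param object A result object.
#' @param top How many top candidates to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @name lncrank-autoplot
NULL

#' @rdname lncrank-autoplot
#' @export
autoplot.lnc_prioritization <- function(object, top = 10L, ...) {
  df <- tidy(object)
  lab <- utils::head(df, top)
  ggplot(df, aes(x = .data$final_rank, y = .data$overall_score)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_point(data = lab, colour = "firebrick", size = 1.6) +
    geom_text(data = lab, aes(label = .data$node_id), hjust = -0.15,
              size = 2.8, colour = "firebrick") +
    scale_y_log10() +
    labs(x = "Final rank", y = "Overall score (smaller = stronger)",
         title = sprintf("Prioritized candidates (%s)", attr(object, "cancer") %||% "")) +
    theme_minimal()
}

#' @rdname lncrank-autoplot
#' @export
autoplot.lnc_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' @rdname lncrank-autoplot
#' @export
autoplot.power_law_summary <- function(object, ...) {
  p <- ggplot(object$histogram, aes(x = .data$degree, y = .data$count)) +
    geom_point() +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "Degree", y = "Number of nodes") +
    theme_minimal()
  if (!object$undefined) {
    p <- p +
      geom_abline(slope = object$slope, intercept = object$intercept,
                  colour = "firebrick") +
      labs(title = sprintf("Degree distribution (log-log slope %.2f)", object$slope))
  }
  p
}

#' @rdname lncrank-autoplot
#' @export
autoplot.lnc_loocv <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !.data$unrankable)
  ggplot(df, aes(x = .data$rank / .data$rank_among)) +
    geom_histogram(bins = 20, boundary = 0, fill = "steelblue", colour = "white") +
    labs(x = "Normalized rank of held-out known (0 = top)", y = "Count",
         title = "Leave-one-out recovery of known cancer lncRNAs") +
    theme_minimal()
}
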