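#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_tile
#'   facet_wrap labs scale_fill_manual theme_minimal ylim
#' @export
ggplot2::autoplot

#' Plot GA fitness trajectories
#'
#' Best and mean population fitness per generation, one panel per restart.
#' Monotone best curves reflect elitism; the gap to the mean shows how much
#' diversity each restart retains.
#'
#' @param object A `"ga_biclusters"` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_biclusters <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("best", "mean"),
                           names_to = "series", values_to = "dcm")
  ggplot(h, aes(x = .data$generation, y = .data$dcm,
                colour = .data$series)) +
    geom_line() +
    facet_wrap(~restart, labeller = ggplot2::label_both) +
    labs(x = "generation", y = "DCM fitness", colour = NULL,
         title = "GA biclustering fitness trajectories") +
    theme_minimal()
}

#' Plot an evaluation result
#'
#' Bar chart of precision, recall and F1 at the configured match threshold.
#'
#' @param object A `"complex_evaluation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.complex_evaluation <- function(object, ...) {
  d <- tidy(object)
  d$metric <- factor(d$metric, levels = c("precision", "recall", "f1"))
  ggplot(d, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "steelblue") +
    ylim(0, 1) +
    labs(x = NULL, y = "score",
         title = sprintf("Complex detection at delta = %g", object$delta)) +
    theme_minimal()
}

#' Plot a discretized expression matrix
#'
#' Symbol heatmap (genes by time-points) with down-regulation in blue, no
#' regulation in grey and up-regulation in red.
#'
#' @param object A `"discretized_matrix"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discretized_matrix <- function(object, ...) {
  d <- tibble(gene = rep(rownames(object), times = ncol(object)),
              time_point = rep(colnames(object), each = nrow(object)),
              symbol = as.vector(unclass(object)))
  d$gene <- factor(d$gene, levels = rev(rownames(object)))
  d$time_point <- factor(d$time_point, levels = colnames(object))
  ggplot(d, aes(x = .data$time_point, y = .data$gene, fill = .data$symbol)) +
    geom_tile() +
    scale_fill_manual(values = c(D = "#2166ac", N = "grey85", U = "#b2182b")) +
    labs(x = "time-point", y = NULL,
         title = sprintf("Discretized expression (%s)",
                         attr(object, "technique"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
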