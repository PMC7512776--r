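#' Plot a centrality ranking
#'
#' Horizontal lollipop chart of node scores in rank order (total influence
#' for entropy tables, the method's score for baselines).
#'
#' @param object A `centrality_ranking` tibble.
#' @param top_n Show only the `top_n` highest-ranked nodes (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_ranking <- function(object, top_n = NULL, ...) {
  score_col <- if (inherits(object, "entropy_centrality")) "total_influence" else "score"
  d <- as_tibble(unclass_ranking(object))
  d$score <- d[[score_col]]
  d <- arrange(d, .data$rank)
  if (!is.null(top_n)) d <- head(d, top_n)
  d$node <- factor(d$node, levels = rev(d$node))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$node), colour = "grey60") +
    ggplot2::geom_point(size = 2.5, colour = "#2c7fb8") +
    ggplot2::labs(
      x = if (score_col == "total_influence") "total influence" else
        paste0(attr(object, "method") %||% "", " score"),
      y = NULL,
      title = sprintf("%s centrality ranking", attr(object, "method") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an SI spreading trajectory
#'
#' Mean infected-count curve over time with a +/- 1 sd ribbon.
#'
#' @param object An `si_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.si_result <- function(object, ...) {
  d <- object$trajectory
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$mean_infected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_infected - .data$sd_infected,
                                      ymax = .data$mean_infected + .data$sd_infected),
                         fill = "#2c7fb8", alpha = 0.2) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time step", y = "mean infected nodes",
                  title = sprintf("SI spread (%s, beta = %g, %d seeds)",
                                  object$config$model, object$config$beta,
                                  length(object$seeds))) +
    ggplot2::theme_minimal()
}

#' Plot a method comparison
#'
#' Mean influence-spread curves per ranking method, faceted by seed-set size
#' `k`.
#'
#' @param object An `si_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.si_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t, y = .data$mean_infected,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$k), labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time step", y = "mean infected nodes",
                  colour = "method") +
    ggplot2::theme_minimal()
}
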