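#' Plot running-mean-ED curves with their envelope bounds
#'
#' @param object An `edge_curves` tibble from [running_mean_ed()].
#' @param ... Unused.
#' @return A ggplot: mean ED of the top-n list against n (log y scale), one
#'   line per scheme, bounds in black.
#' @export
autoplot.edge_curves <- function(object, ...) {
  is_bound <- object$scheme %in% c("upper_bound", "lower_bound")
  ggplot2::ggplot(object[!is_bound, ],
                  ggplot2::aes(x = .data$n, y = .data$mean_ed,
                               colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = object[is_bound, ],
                       ggplot2::aes(group = .data$scheme),
                       colour = "black", linewidth = 0.9) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "top-n list size", y = "mean ED of top n (My)",
                  colour = "scheme") +
    ggplot2::theme_minimal()
}

#' Plot the replicate similarity distribution of an experiment
#'
#' @param object An `edge_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot histogram of per-replicate top-list similarity, with the
#'   mean marked.
#' @export
autoplot.edge_experiment <- function(object, ...) {
  reps <- tidy(object)
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$similarity)) +
    ggplot2::geom_histogram(binwidth = 1 / object$top_n, fill = "grey40") +
    ggplot2::geom_vline(xintercept = mean(reps$similarity),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = sprintf("top-%d similarity to reference", object$top_n),
                  y = "replicates") +
    ggplot2::theme_minimal()
}

#' Histogram of the ED distribution
#'
#' ED distributions from large, partly unresolved phylogenies are strongly
#' right-skewed ("J-shaped"): most species sit well below the mean and a few
#' ancient lineages carry very large scores. This plot is the standard first
#' look at a new ED table.
#'
#' @param data A data frame with an `ed` column (e.g. from
#'   [ed_polytomy_corrected()]).
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_ed_distribution <- function(data, bins = 60) {
  ggplot2::ggplot(tibble::as_tibble(data), ggplot2::aes(x = .data$ed)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "Evolutionary Distinctiveness (My)", y = "species") +
    ggplot2::theme_minimal()
}
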