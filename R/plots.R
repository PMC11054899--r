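#' Plot a deviation summary
#'
#' Bar chart of mean normalized deviation from tissue per platform with SEM
#' error bars, one facet per level — the package's standard view of
#' platform fidelity (lower bars = more tissue-faithful).
#'
#' @param object A `deviation_summary` (from [summarize_deviation()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deviation_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$platform <- factor(df$platform, levels = platform_conditions())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$platform, y = .data$mean_deviation)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_deviation - .data$sem,
                                        ymax = .data$mean_deviation + .data$sem),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = NULL, y = "normalized deviation from tissue (mean ± SEM)") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.deviation_summary
#' @export
autoplot.fidelity_report <- function(object, ...) {
  autoplot(object$summary, ...)
}

#' Volcano-style view of a marker selection
#'
#' t statistic against `-log10(q)`, with the selection threshold drawn and
#' selected genes highlighted.
#'
#' @param object A `marker_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marker_selection <- function(object, ...) {
  df <- tidy(object)
  thr <- attr(object, "threshold")
  df$neg_log10_q <- -log10(pmax(df$q.value, .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$neg_log10_q,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "t statistic (normal vs tumor)", y = "-log10 q") +
    ggplot2::theme_bw()
}

#' Enrichment-score heat map
#'
#' Tile view of a set-by-sample enrichment matrix (e.g. TF activity),
#' the data behind the study-style activity heat maps.
#'
#' @param es A sets-by-samples enrichment matrix (see [gsva_scores()]).
#' @param max_sets Show at most this many sets (by variance, descending).
#' @return A ggplot object.
#' @export
plot_enrichment_heatmap <- function(es, max_sets = 50L) {
  stopifnot(is.matrix(es))
  if (nrow(es) > max_sets) {
    keep <- order(apply(es, 1L, stats::var), decreasing = TRUE)[seq_len(max_sets)]
    es <- es[sort(keep), , drop = FALSE]
  }
  df <- as_tibble(as.data.frame.table(es, responseName = "score"))
  names(df)[1:2] <- c("set", "sample")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$set,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
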