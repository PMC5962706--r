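#' Volcano plot of a detection result
#'
#' Probe log2 fold change against -log10 BH-adjusted p, with the
#' significance thresholds drawn as dashed lines.
#'
#' @param object A `pathosig_detection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathosig_detection
#' @export
autoplot.pathosig_detection <- function(object, ...) {
  d <- object$probe_stats
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$adj_p, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = object$thresholds$min_log2fc, linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(object$thresholds$max_adj_p), linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change (case - control)",
      y = expression(-log[10] ~ "adjusted p"),
      colour = "significant",
      title = sprintf("%s vs %s", object$case_group, object$control_group)
    ) +
    ggplot2::theme_minimal()
}

#' CH-index curve of a clustering result
#'
#' @param object A `pathosig_clusters` object.
#' @param ... Unused.
#' @return A ggplot object with the selected k highlighted.
#' @method autoplot pathosig_clusters
#' @export
autoplot.pathosig_clusters <- function(object, ...) {
  if (is.null(object$ch_curve)) abort("No CH curve available for this clustering.")
  ggplot2::ggplot(object$ch_curve, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$ch_curve$k) +
    ggplot2::labs(
      x = "number of clusters k", y = "Calinski-Harabasz index",
      title = sprintf("selected k = %d", object$selected_k)
    ) +
    ggplot2::theme_minimal()
}

#' Case and control prevalence of reported signatures
#'
#' @param signatures Signature tibble from [detect_signatures()].
#' @return A ggplot bar chart of case and control prevalence per organism.
#' @export
plot_prevalence <- function(signatures) {
  assert_df_cols(signatures,
    c("organism", "case_prevalence_pct", "control_prevalence_pct"),
    "signatures"
  )
  d <- signatures |>
    select("organism", "case_prevalence_pct", "control_prevalence_pct") |>
    tidyr::pivot_longer(-"organism", names_to = "side", values_to = "prevalence") |>
    mutate(side = ifelse(.data$side == "case_prevalence_pct", "case", "control"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$organism, .data$prevalence),
    y = .data$prevalence, fill = .data$side
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "prevalence (% of group)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Percent-of-total signal shares per organism class
#'
#' @param shares Output of [percent_signal_share()] (with `group` and
#'   `organism_class` columns).
#' @return A stacked ggplot bar chart, one bar per (group, class) cell.
#' @export
plot_signal_shares <- function(shares) {
  assert_df_cols(shares, c("organism", "percent_share"), "shares")
  if (!"group" %in% names(shares)) shares$group <- "all"
  if (!"organism_class" %in% names(shares)) shares$organism_class <- "all"
  ggplot2::ggplot(shares, ggplot2::aes(
    x = .data$group, y = .data$percent_share, fill = .data$organism
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$organism_class)) +
    ggplot2::labs(x = NULL, y = "% of total hybridization signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Signature heatmap in dendrogram leaf order
#'
#' Tile heatmap of signature profiles with samples ordered by the cluster
#' dendrogram (no optimal leaf reordering).
#'
#' @param profiles Profile data frame (`sample_id` + organism columns).
#' @param clusters Optional `pathosig_clusters` object used for the sample
#'   order; default clusters `profiles` itself.
#' @return A ggplot object.
#' @export
plot_signature_heatmap <- function(profiles, clusters = NULL) {
  if (is.null(clusters)) clusters <- cluster_samples(profiles, k_range = NULL)
  ord <- clusters$leaf_order
  d <- profiles |>
    tidyr::pivot_longer(-"sample_id", names_to = "organism", values_to = "signal") |>
    mutate(sample_id = factor(.data$sample_id, levels = ord))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$sample_id, y = .data$organism, fill = .data$signal
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "normalized\nsignal (log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Outcome box plots for selected signatures
#'
#' @param outcome_long Long tibble from [outcome_long()].
#' @return A ggplot object: one panel per organism, signals split by
#'   outcome.
#' @export
plot_outcome <- function(outcome_long) {
  assert_df_cols(outcome_long, c("organism", "signal", "outcome"), "outcome_long")
  ggplot2::ggplot(outcome_long, ggplot2::aes(
    x = .data$outcome, y = .data$signal, fill = .data$outcome
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$organism), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "signature signal (log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
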