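#' Tidy a detection result
#'
#' @param x A `pathosig_detection` object.
#' @param ... Unused.
#' @return The probe-level statistics tibble (`probe_id`, `t`, `df`, `p`,
#'   `adj_p`, `log2fc`, group means, `significant`).
#' @method tidy pathosig_detection
#' @export
tidy.pathosig_detection <- function(x, ...) {
  x$probe_stats
}

#' One-row summary of a detection result
#'
#' @param x A `pathosig_detection` object.
#' @param ... Unused.
#' @return Tibble with the comparison labels, probe and signature counts.
#' @method glance pathosig_detection
#' @export
glance.pathosig_detection <- function(x, ...) {
  tibble(
    case_group = x$case_group,
    control_group = x$control_group,
    n_probes = nrow(x$probe_stats),
    n_significant_probes = sum(x$probe_stats$significant),
    n_signatures = nrow(x$signatures),
    min_log2fc = x$thresholds$min_log2fc,
    max_adj_p = x$thresholds$max_adj_p
  )
}

#' Tidy a clustering result
#'
#' @param x A `pathosig_clusters` object.
#' @param k Cluster count whose labels to return; default the selected k.
#' @param ... Unused.
#' @return Tibble `sample_id`, `cluster`.
#' @method tidy pathosig_clusters
#' @export
tidy.pathosig_clusters <- function(x, k = NULL, ...) {
  k <- k %||% x$selected_k
  if (is.na(k)) abort("No cluster count selected; pass `k` explicitly.")
  labels <- cut_clusters(x, k)
  tibble(sample_id = names(labels), cluster = as.integer(labels))
}

#' One-row summary of a clustering result
#'
#' @param x A `pathosig_clusters` object.
#' @param ... Unused.
#' @return Tibble with sample count, selected k and its CH value.
#' @method glance pathosig_clusters
#' @export
glance.pathosig_clusters <- function(x, ...) {
  tibble(
    n_samples = length(x$hclust$order),
    selected_k = x$selected_k,
    ch_max = if (is.null(x$ch_curve)) NA_real_ else max(x$ch_curve$ch),
    ch_k_evaluated = if (is.null(x$ch_curve)) 0L else nrow(x$ch_curve)
  )
}

#' Tidy normalized signals
#'
#' @param x A `pathosig_normalized` object.
#' @param ... Unused.
#' @return The long normalized-signal tibble.
#' @method tidy pathosig_normalized
#' @export
tidy.pathosig_normalized <- function(x, ...) {
  x$normalized
}

#' One-row summary of normalized signals
#'
#' @param x A `pathosig_normalized` object.
#' @param ... Unused.
#' @return Tibble with dimensions, mode and the scale-factor range.
#' @method glance pathosig_normalized
#' @export
glance.pathosig_normalized <- function(x, ...) {
  tibble(
    n_probes = length(unique(x$normalized$probe_id)),
    n_samples = nrow(x$scale_factors),
    mode = x$mode,
    sf_min = min(x$scale_factors$scale_factor),
    sf_max = max(x$scale_factors$scale_factor)
  )
}
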