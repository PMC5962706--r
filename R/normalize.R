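#' Per-array scale factors from human reference probes
#'
#' Each hybridization carries its own Cy3 (sample) / Cy5 (human reference)
#' pair, so the scale factor is computed per sample: the sum of green signals
#' over human probes divided by the sum of red signals over human probes.
#'
#' @param signals Long signal tibble (see [read_signal_table()]).
#' @param annotation Probe annotation tibble; probes with `is_human == 1`
#'   define the scale factor.
#' @return A tibble with columns `sample_id`, `scale_factor`.
#' @export
#' @examples
#' sig <- tibble::tibble(
#'   probe_id = rep(c("H1", "H2", "M1"), 2),
#'   sample_id = rep(c("s1", "s2"), each = 3),
#'   green_signal = c(10, 20, 5, 30, 30, 5),
#'   red_signal = c(10, 10, 5, 20, 10, 5)
#' )
#' ann <- tibble::tibble(
#'   probe_id = c("H1", "H2", "M1"),
#'   organism = c("Homo sapiens", "Homo sapiens", "Mycoplasma"),
#'   organism_class = c("human", "human", "bacterium"),
#'   is_human = c(1L, 1L, 0L)
#' )
#' scale_factors(sig, ann) # s1: 30/20 = 1.5, s2: 60/30 = 2
scale_factors <- function(signals, annotation) {
  assert_df_cols(signals, c("probe_id", "sample_id", "green_signal", "red_signal"),
    what = "signals"
  )
  assert_df_cols(annotation, c("probe_id", "is_human"), what = "annotation")
  human_ids <- annotation$probe_id[annotation$is_human == 1L]
  if (length(human_ids) == 0) {
    abort("No human probes in the annotation; the scale factor is undefined.")
  }
  hs <- signals[signals$probe_id %in% human_ids, ]
  if (nrow(hs) == 0) {
    abort("No human-probe signals present in the signal table.")
  }
  out <- hs |>
    group_by(.data$sample_id) |>
    summarise(
      scale_factor = sum(.data$green_signal) / sum(.data$red_signal),
      .groups = "drop"
    )
  if (any(!is.finite(out$scale_factor)) || any(out$scale_factor <= 0)) {
    abort("Scale factor non-positive or non-finite; check signal flooring.")
  }
  out[match(unique(signals$sample_id), out$sample_id), ]
}

#' Normalize microbial probe signals with per-array scale factors
#'
#' Applies the scale-factor normalization to every non-human probe and drops
#' human probes from the output. Two readings of the normalization are
#' provided:
#' \describe{
#'   \item{`"literal"` (default)}{`N = log2(g) - sf * log2(r)`: the scale
#'     factor multiplies the log2 red signal.}
#'   \item{`"ratio"`}{`N = log2(g) - log2(sf * r) = log2(g / (sf * r))`: the
#'     scale factor rescales the red channel before the log.}
#' }
#' When `sf = 1` the two modes agree exactly (`log2 g - log2 r`).
#'
#' @param signals Long signal tibble; non-positive values are floored at
#'   `signal_floor` first (see [validate_signals()]).
#' @param annotation Probe annotation tibble.
#' @param mode `"literal"` or `"ratio"`.
#' @param signal_floor Floor applied to raw signals before taking logs.
#' @return A `pathosig_normalized` object: list with
#'   \describe{
#'     \item{normalized}{long tibble `probe_id`, `sample_id`, `normalized`
#'       (log2 units), microbial probes only}
#'     \item{scale_factors}{tibble `sample_id`, `scale_factor`}
#'     \item{annotation}{the microbial rows of the annotation}
#'     \item{mode}{the mode used}
#'   }
#' @export
normalize_signals <- function(signals, annotation,
                              mode = c("literal", "ratio"),
                              signal_floor = 1) {
  mode <- match.arg(mode)
  signals <- suppressWarnings(validate_signals(signals, signal_floor))
  annotation <- validate_annotation(annotation)
  sf <- scale_factors(signals, annotation)

  micro <- annotation[annotation$is_human == 0L, ]
  x <- signals[signals$probe_id %in% micro$probe_id, ] |>
    left_join(sf, by = "sample_id")
  n <- if (mode == "literal") {
    log2(x$green_signal) - x$scale_factor * log2(x$red_signal)
  } else {
    log2(x$green_signal) - log2(x$scale_factor * x$red_signal)
  }
  if (any(!is.finite(n))) {
    i <- which(!is.finite(n))[1]
    abort(sprintf(
      "Non-finite normalized signal for probe %s, sample %s.",
      x$probe_id[i], x$sample_id[i]
    ))
  }
  structure(
    list(
      normalized = tibble(
        probe_id = x$probe_id, sample_id = x$sample_id, normalized = n
      ),
      scale_factors = sf,
      annotation = micro,
      mode = mode
    ),
    class = "pathosig_normalized"
  )
}

#' @export
print.pathosig_normalized <- function(x, ...) {
  cat("<pathosig normalized signals>\n")
  cat(sprintf(
    "  %d microbial probes x %d samples, mode = %s\n",
    length(unique(x$normalized$probe_id)), nrow(x$scale_factors), x$mode
  ))
  cat(sprintf(
    "  scale factors: %.4g .. %.4g\n",
    min(x$scale_factors$scale_factor), max(x$scale_factors$scale_factor)
  ))
  invisible(x)
}

# normalized long tibble -> probe x sample matrix
normalized_matrix <- function(normalized) {
  x <- if (inherits(normalized, "pathosig_normalized")) normalized$normalized else normalized
  probes <- unique(x$probe_id)
  samples <- unique(x$sample_id)
  m <- matrix(NA_real_, length(probes), length(samples),
    dimnames = list(probes, samples)
  )
  m[cbind(match(x$probe_id, probes), match(x$sample_id, samples))] <- x$normalized
  if (anyNA(m)) abort("Normalized signals do not form a complete grid.")
  m
}
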