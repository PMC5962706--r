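#' Associate signature signals with clinical outcome
#'
#' One-sided Welch t-test per organism of aggregated signature signals
#' between deceased and alive samples (unknown outcomes excluded listwise).
#' `direction = "deceased_greater"` tests for signals elevated in the
#' deceased group, `"alive_greater"` for the opposite; `logfc` is always
#' `mean(deceased) - mean(alive)` regardless of direction. Nominal
#' (unadjusted) p-values drive the `significant` flag at `alpha`; a
#' BH-adjusted column is emitted alongside for reference. Non-significant
#' organisms are kept and flagged `"trend"`.
#'
#' @param profiles Profile data frame (`sample_id` + organism columns) or
#'   matrix of aggregated signature signals, typically for one case group.
#' @param metadata Sample metadata with an `outcome` column (`alive`,
#'   `deceased`, or NA).
#' @param direction `"deceased_greater"` (default) or `"alive_greater"`.
#' @param alpha Nominal significance level for the flag. Default 0.05.
#' @return Tibble `organism`, `direction`, `t`, `df`, `p`, `adj_p`, `logfc`,
#'   `n_deceased`, `n_alive`, `flag` (`"significant"` / `"trend"`).
#' @export
outcome_association <- function(profiles, metadata,
                                direction = c("deceased_greater", "alive_greater"),
                                alpha = 0.05) {
  direction <- match.arg(direction)
  metadata <- validate_metadata(metadata)
  m <- profile_matrix(profiles)
  known <- metadata[!is.na(metadata$outcome) & metadata$sample_id %in% rownames(m), ]
  dec <- known$sample_id[known$outcome == "deceased"]
  alv <- known$sample_id[known$outcome == "alive"]
  if (length(dec) < 2 || length(alv) < 2) {
    abort(sprintf(
      "Outcome test needs >= 2 samples per outcome (got %d deceased, %d alive).",
      length(dec), length(alv)
    ))
  }
  res <- row_t_test(
    t(m), match(dec, rownames(m)), match(alv, rownames(m)),
    alternative = if (direction == "deceased_greater") "greater" else "less"
  )
  t_dir <- if (direction == "deceased_greater") res$t else -res$t
  tibble(
    organism = colnames(m),
    direction = direction,
    t = t_dir,
    df = res$df,
    p = res$p,
    adj_p = bh_adjust(res$p),
    logfc = res$mean_1 - res$mean_2,
    n_deceased = length(dec),
    n_alive = length(alv),
    flag = ifelse(res$p < alpha, "significant", "trend")
  ) |>
    arrange(.data$p)
}

#' Outcome composition of each cluster
#'
#' Counts of alive, deceased and unknown outcomes per cluster, with the
#' deceased percentage among samples of known outcome. Clusters whose
#' outcomes are all unknown get an `NA` percentage.
#'
#' @param labels Cluster label per sample, named by sample id (e.g. from
#'   [cut_clusters()]).
#' @param metadata Sample metadata with `sample_id` and `outcome`.
#' @return Tibble `cluster`, `n`, `n_alive`, `n_deceased`, `n_unknown`,
#'   `deceased_pct`.
#' @export
#' @examples
#' md <- tibble::tibble(
#'   sample_id = paste0("s", 1:8), group = "BRTN",
#'   outcome = c(rep("deceased", 5), rep("alive", 3))
#' )
#' cluster_outcome_summary(
#'   stats::setNames(rep(1, 8), md$sample_id), md
#' ) # 5/8 deceased = 62.5%
cluster_outcome_summary <- function(labels, metadata) {
  metadata <- validate_metadata(metadata)
  if (is.null(names(labels))) {
    abort("`labels` must be named by sample id.")
  }
  missing <- setdiff(names(labels), metadata$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Sample `%s` missing from metadata.", missing[1]))
  }
  tibble(
    sample_id = names(labels),
    cluster = as.vector(labels)
  ) |>
    left_join(metadata[, c("sample_id", "outcome")], by = "sample_id") |>
    group_by(.data$cluster) |>
    summarise(
      n = dplyr::n(),
      n_alive = sum(.data$outcome == "alive", na.rm = TRUE),
      n_deceased = sum(.data$outcome == "deceased", na.rm = TRUE),
      n_unknown = sum(is.na(.data$outcome)),
      deceased_pct = ifelse(.data$n_alive + .data$n_deceased > 0,
        100 * .data$n_deceased / (.data$n_alive + .data$n_deceased),
        NA_real_
      ),
      .groups = "drop"
    ) |>
    arrange(.data$cluster)
}

#' Long-format export for outcome box plots
#'
#' @param profiles Profile data frame or matrix.
#' @param metadata Sample metadata with outcomes.
#' @param organisms Organisms to include; default all.
#' @return Long tibble `organism`, `sample_id`, `signal`, `outcome`, ready
#'   for box plotting; unknown outcomes excluded.
#' @export
outcome_long <- function(profiles, metadata, organisms = NULL) {
  metadata <- validate_metadata(metadata)
  m <- profile_matrix(profiles)
  if (is.null(organisms)) organisms <- colnames(m)
  tibble(
    sample_id = rep(rownames(m), times = length(organisms)),
    organism = rep(organisms, each = nrow(m)),
    signal = as.vector(m[, organisms, drop = FALSE])
  ) |>
    inner_join(metadata[, c("sample_id", "outcome")], by = "sample_id") |>
    filter(!is.na(.data$outcome)) |>
    select("organism", "sample_id", "signal", "outcome")
}
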