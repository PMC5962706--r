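#' Aggregate significant probes to organism-level signature signals
#'
#' The organism-level hybridization signal of a reported signature in a
#' group is the mean over its significant probes of each probe's mean
#' normalized signal across the group's samples.
#'
#' @param normalized A `pathosig_normalized` object or long normalized tibble.
#' @param signatures Signature tibble from [detect_signatures()] /
#'   [filter_signatures()] (needs `organism`, `significant_probe_ids`).
#' @param metadata Sample metadata tibble.
#' @param groups Group labels to aggregate over; default all.
#' @return Tibble `organism`, `organism_class` (if available), `group`,
#'   `mean_signal` (log2 units).
#' @export
aggregate_signatures <- function(normalized, signatures, metadata,
                                 groups = NULL) {
  assert_df_cols(signatures, c("organism", "significant_probe_ids"), "signatures")
  metadata <- validate_metadata(metadata)
  if (is.null(groups)) groups <- unique(metadata$group)
  if (!all(groups %in% metadata$group)) {
    abort(sprintf(
      "Group `%s` has no samples.", setdiff(groups, metadata$group)[1]
    ))
  }
  if (nrow(signatures) == 0) {
    return(tibble(
      organism = character(), organism_class = character(),
      group = character(), mean_signal = double()
    ))
  }
  m <- normalized_matrix(normalized)
  probe_map <- signatures |>
    select("organism", "significant_probe_ids") |>
    mutate(probe_id = strsplit(.data$significant_probe_ids, ",", fixed = TRUE)) |>
    select("organism", "probe_id") |>
    tidyr::unnest("probe_id")
  missing <- setdiff(probe_map$probe_id, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf(
      "Significant probe %s absent from the normalized matrix.", missing[1]
    ))
  }
  rows <- purrr::map(groups, function(g) {
    ids <- intersect(colnames(m), metadata$sample_id[metadata$group == g])
    probe_means <- rowMeans(m[, ids, drop = FALSE])
    probe_map |>
      mutate(pm = probe_means[.data$probe_id]) |>
      group_by(.data$organism) |>
      summarise(mean_signal = mean(.data$pm), .groups = "drop") |>
      mutate(group = g)
  })
  out <- bind_rows(rows)
  if ("organism_class" %in% names(signatures)) {
    out <- out |>
      left_join(signatures[, c("organism", "organism_class")], by = "organism")
  }
  out |>
    select(dplyr::any_of(c("organism", "organism_class")), "group", "mean_signal") |>
    arrange(.data$group, .data$organism)
}

#' Per-sample signature signal profiles
#'
#' Samples-by-organisms matrix of aggregated signature signals: for each
#' sample, the mean normalized signal over each organism's significant
#' probes. This is the input to hierarchical clustering and the outcome
#' tests.
#'
#' @inheritParams aggregate_signatures
#' @param sample_ids Samples to include; default all samples in `normalized`.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per organism.
#' @export
signature_profiles <- function(normalized, signatures, sample_ids = NULL) {
  assert_df_cols(signatures, c("organism", "significant_probe_ids"), "signatures")
  m <- normalized_matrix(normalized)
  if (is.null(sample_ids)) sample_ids <- colnames(m)
  if (!all(sample_ids %in% colnames(m))) {
    abort(sprintf(
      "Sample `%s` absent from the normalized signals.",
      setdiff(sample_ids, colnames(m))[1]
    ))
  }
  out <- tibble(sample_id = sample_ids)
  for (i in seq_len(nrow(signatures))) {
    probes <- strsplit(signatures$significant_probe_ids[i], ",", fixed = TRUE)[[1]]
    out[[signatures$organism[i]]] <-
      unname(colMeans(m[probes, sample_ids, drop = FALSE]))
  }
  out
}

#' Percent-of-total hybridization signal per organism
#'
#' Within one case group and organism class, each organism's share of the
#' summed signature signals, in percent. Normalized log2 signals can be
#' negative; when any mean in a cell is negative, all means in that cell are
#' shifted uniformly by minus the minimum (bringing the smallest to zero)
#' before shares are computed, and the shift is reported.
#'
#' @param signature_means Tibble with columns `organism`, `mean_signal`, and
#'   optionally `group` and `organism_class`; shares are computed within
#'   each (`group`, `organism_class`) cell present.
#' @return The input with `shift` and `percent_share` columns added; shares
#'   within a cell sum to 100 when the shifted total is positive. Cells with
#'   zero total get `NA` shares with a warning.
#' @export
#' @examples
#' percent_signal_share(tibble::tibble(
#'   organism = c("A", "B", "C"), mean_signal = c(2, 3, 5)
#' ))
percent_signal_share <- function(signature_means) {
  assert_df_cols(signature_means, c("organism", "mean_signal"), "signature_means")
  x <- as_tibble(signature_means)
  cell_vars <- intersect(c("group", "organism_class"), names(x))
  x <- x |>
    group_by(across(dplyr::all_of(cell_vars))) |>
    mutate(
      shift = max(0, -min(.data$mean_signal)),
      .total = sum(.data$mean_signal + .data$shift),
      percent_share = ifelse(.data$.total > 0,
        100 * (.data$mean_signal + .data$shift) / .data$.total, NA_real_
      )
    ) |>
    ungroup()
  if (anyNA(x$percent_share)) {
    warn("Some cells have zero total signal after shifting; shares undefined (NA).")
  }
  x |> select(-".total")
}

#' Partition signatures into unique and shared sets across case groups
#'
#' Assigns every organism to the exact subset of case groups that report it
#' (the cells of a Venn diagram). Cells are disjoint and their union is the
#' union of the per-group signature sets.
#'
#' @param signature_sets Named list: group label -> character vector of
#'   reported organisms.
#' @return Tibble `subset` (group labels joined with `+`), `n_groups`,
#'   `organism`; ordered by subset size then subset label then organism.
#' @export
#' @examples
#' partition_signatures(list(BRER = c("A", "B"), BRTN = "B"))
partition_signatures <- function(signature_sets) {
  if (!is.list(signature_sets) || is.null(names(signature_sets)) ||
    anyDuplicated(names(signature_sets))) {
    abort("`signature_sets` must be a list with unique group-label names.")
  }
  labels <- names(signature_sets)
  orgs <- sort(unique(unlist(signature_sets, use.names = FALSE)))
  if (length(orgs) == 0) {
    return(tibble(subset = character(), n_groups = integer(), organism = character()))
  }
  membership <- vapply(
    labels, function(g) orgs %in% signature_sets[[g]],
    logical(length(orgs))
  )
  membership <- matrix(membership, nrow = length(orgs), dimnames = list(orgs, labels))
  subset_of <- apply(membership, 1, function(row) {
    paste(labels[row], collapse = "+")
  })
  tibble(
    organism = orgs,
    subset = unname(subset_of),
    n_groups = as.integer(unname(rowSums(membership)))
  ) |>
    arrange(.data$n_groups, .data$subset, .data$organism) |>
    select("subset", "n_groups", "organism")
}

#' Venn partition as JSON
#'
#' @param partition Output of [partition_signatures()].
#' @param path Optional file to write.
#' @return JSON string mapping each subset label to its organisms.
#' @export
venn_json <- function(partition, path = NULL) {
  assert_df_cols(partition, c("subset", "organism"), "partition")
  cells <- split(partition$organism, partition$subset)
  # keep subset-size ordering rather than alphabetical
  cells <- cells[unique(partition$subset)]
  js <- jsonlite::toJSON(cells, auto_unbox = FALSE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
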