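#' Read a long-format two-channel signal table
#'
#' Reads the tab-delimited signal table (`probe_id`, `sample_id`,
#' `green_signal`, `red_signal`, header required) and validates that it forms
#' a complete probe-by-sample grid. Duplicate and missing (probe, sample)
#' cells are errors, never silently filled. Non-positive raw signals are
#' floored at `signal_floor` with a warning: the log2-based normalization
#' needs strictly positive signals and scanner exports can contain zeros.
#'
#' @param path Path to the signal table.
#' @param signal_floor Minimum raw signal; values below it (including zeros
#'   and negatives) are raised to this floor. Default 1 fluorescence unit.
#' @return A tibble in long format with strictly positive signals, carrying
#'   every (probe, sample) combination exactly once.
#' @export
read_signal_table <- function(path, signal_floor = 1) {
  x <- readr::read_tsv(path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      sample_id = readr::col_character(),
      green_signal = readr::col_double(),
      red_signal = readr::col_double()
    )
  )
  assert_df_cols(x, c("probe_id", "sample_id", "green_signal", "red_signal"),
    what = "signal table"
  )
  validate_signals(x, signal_floor)
}

#' Validate an in-memory signal table
#'
#' The checks of [read_signal_table()] applied to a data frame that is
#' already in memory (for example straight from [simulate_experiment()]).
#'
#' @inheritParams read_signal_table
#' @param signals Data frame with columns `probe_id`, `sample_id`,
#'   `green_signal`, `red_signal`.
#' @return The validated tibble.
#' @export
validate_signals <- function(signals, signal_floor = 1) {
  assert_df_cols(signals,
    c("probe_id", "sample_id", "green_signal", "red_signal"),
    what = "signals"
  )
  x <- as_tibble(signals)
  key <- paste(x$probe_id, x$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    abort(sprintf(
      "Duplicate (probe_id, sample_id) row at line %d: (%s, %s).",
      i + 1, x$probe_id[i], x$sample_id[i]
    ))
  }
  probes <- unique(x$probe_id)
  samples <- unique(x$sample_id)
  if (nrow(x) != length(probes) * length(samples)) {
    full <- tidyr::expand_grid(probe_id = probes, sample_id = samples)
    miss <- dplyr::anti_join(full, x, by = c("probe_id", "sample_id"))
    abort(sprintf(
      "Signal table is not a complete probe x sample grid; first missing cell: (%s, %s) (%d missing).",
      miss$probe_id[1], miss$sample_id[1], nrow(miss)
    ))
  }
  if (any(!is.finite(x$green_signal)) || any(!is.finite(x$red_signal))) {
    abort("Signal table contains non-finite signal values.")
  }
  n_floor <- sum(x$green_signal < signal_floor) + sum(x$red_signal < signal_floor)
  if (n_floor > 0) {
    warn(sprintf(
      "%d signal value%s below the floor of %g raised to the floor.",
      n_floor, if (n_floor > 1) "s" else "", signal_floor
    ))
    x$green_signal <- pmax(x$green_signal, signal_floor)
    x$red_signal <- pmax(x$red_signal, signal_floor)
  }
  x
}

#' Read a probe annotation table
#'
#' Columns `probe_id`, `organism`, `organism_class` (one of virus, bacterium,
#' fungus, parasite, human) and `is_human` (0/1). Organism names are
#' whitespace-trimmed, case preserved. Human probes must carry class `human`
#' and vice versa; every non-human probe needs a non-empty organism.
#'
#' @param path Path to the annotation table.
#' @return A validated annotation tibble.
#' @export
read_probe_annotations <- function(path) {
  x <- readr::read_tsv(path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      organism = readr::col_character(),
      organism_class = readr::col_character(),
      is_human = readr::col_integer()
    )
  )
  validate_annotation(x)
}

#' Validate an in-memory probe annotation table
#'
#' @param annotation Data frame with the columns of
#'   [read_probe_annotations()].
#' @return The validated tibble.
#' @export
validate_annotation <- function(annotation) {
  assert_df_cols(annotation,
    c("probe_id", "organism", "organism_class", "is_human"),
    what = "annotation"
  )
  x <- as_tibble(annotation)
  x$organism <- trimws(x$organism)
  allowed <- c(.organism_classes, "human")
  bad <- setdiff(unique(x$organism_class), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown organism_class value%s: %s. Allowed: %s.",
      if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "),
      paste(allowed, collapse = ", ")
    ))
  }
  if (anyDuplicated(x$probe_id)) {
    abort(sprintf(
      "Duplicated probe_id: %s.",
      x$probe_id[which(duplicated(x$probe_id))[1]]
    ))
  }
  if (!all(x$is_human %in% c(0L, 1L))) {
    abort("`is_human` must be 0 or 1.")
  }
  mismatch <- xor(x$is_human == 1L, x$organism_class == "human")
  if (any(mismatch)) {
    abort(sprintf(
      "Row %d: is_human flag and organism_class disagree (probe %s).",
      which(mismatch)[1], x$probe_id[which(mismatch)[1]]
    ))
  }
  empty <- x$is_human == 0L & !nzchar(x$organism)
  if (any(empty)) {
    abort(sprintf(
      "Row %d: non-human probe %s has an empty organism.",
      which(empty)[1], x$probe_id[which(empty)[1]]
    ))
  }
  x
}

#' Read a sample metadata table
#'
#' Columns `sample_id`, `group`, `outcome` (alive, deceased, or NA for
#' unknown). Unknown outcomes are permitted; they are excluded from outcome
#' tests only.
#'
#' @param path Path to the metadata table.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      group = readr::col_character(),
      outcome = readr::col_character()
    ),
    na = c("", "NA")
  )
  validate_metadata(x)
}

#' Validate an in-memory sample metadata table
#'
#' @param metadata Data frame with columns `sample_id`, `group`, `outcome`.
#' @return The validated tibble.
#' @export
validate_metadata <- function(metadata) {
  assert_df_cols(metadata, c("sample_id", "group"), what = "metadata")
  x <- as_tibble(metadata)
  if (!"outcome" %in% names(x)) x$outcome <- NA_character_
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf(
      "Duplicated sample_id: %s.",
      x$sample_id[which(duplicated(x$sample_id))[1]]
    ))
  }
  bad <- !is.na(x$outcome) & !x$outcome %in% c("alive", "deceased")
  if (any(bad)) {
    abort(sprintf(
      "Row %d: outcome must be alive, deceased or NA (got %s).",
      which(bad)[1], x$outcome[which(bad)[1]]
    ))
  }
  x
}

#' Read a fixture directory written by [write_experiment()]
#'
#' @param dir Directory containing `signals.tsv`, `annotation.tsv`,
#'   `metadata.tsv` and (optionally) `truth.tsv`.
#' @param signal_floor Passed to [read_signal_table()].
#' @return A `pathosig_experiment` (with `config = NULL` and `truth = NULL`
#'   when no truth table is present).
#' @export
read_experiment <- function(dir, signal_floor = 1) {
  truth_path <- file.path(dir, "truth.tsv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- readr::read_tsv(truth_path,
      col_types = readr::cols(
        organism = readr::col_character(),
        sample_id = readr::col_character(),
        carrier = readr::col_integer()
      )
    )
  }
  structure(
    list(
      signals = read_signal_table(file.path(dir, "signals.tsv"), signal_floor),
      annotation = read_probe_annotations(file.path(dir, "annotation.tsv")),
      metadata = read_sample_metadata(file.path(dir, "metadata.tsv")),
      truth = truth, config = NULL
    ),
    class = "pathosig_experiment"
  )
}

# long signals -> named list of probe x sample matrices (g, r)
signal_matrices <- function(signals) {
  probes <- unique(signals$probe_id)
  samples <- unique(signals$sample_id)
  idx <- cbind(
    match(signals$probe_id, probes),
    match(signals$sample_id, samples)
  )
  g <- matrix(NA_real_, length(probes), length(samples),
    dimnames = list(probes, samples)
  )
  r <- g
  g[idx] <- signals$green_signal
  r[idx] <- signals$red_signal
  list(g = g, r = r)
}

#' Export a dendrogram as a Newick string
#'
#' Converts the merge tree of [cluster_samples()] to Newick format so any
#' standard phylogenetics tool can re-draw the heatmap dendrogram.
#'
#' @param clusters A `pathosig_clusters` object or an `hclust` tree.
#' @param path Optional file to write; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to file.
#' @export
export_newick <- function(clusters, path = NULL) {
  tree <- if (inherits(clusters, "pathosig_clusters")) clusters$hclust else clusters
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) {
    return(ape::write.tree(phy))
  }
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write result tables of a pipeline run
#'
#' Writes each element of a named list of data frames as
#' `<name>.tsv` under `dir`, tab-delimited with full numeric precision
#' (re-reading reproduces values well beyond 6 significant digits).
#'
#' @param results Named list of data frames.
#' @param dir Output directory (created if absent).
#' @return Named vector of paths written, invisibly.
#' @export
write_tables <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(results), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(results[[nm]]), p)
    p
  }, character(1))
  invisible(paths)
}
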