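# vectorized Welch / pooled t over matrix rows; the workhorse of all
# group-contrast statistics in the package
row_t_test <- function(m, idx1, idx2,
                       alternative = c("greater", "less", "two.sided"),
                       var_equal = FALSE) {
  alternative <- match.arg(alternative)
  n1 <- length(idx1)
  n2 <- length(idx2)
  if (n1 < 2 || n2 < 2) {
    abort(sprintf("Both groups need >= 2 samples (got %d and %d).", n1, n2))
  }
  x1 <- m[, idx1, drop = FALSE]
  x2 <- m[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, nrow(m))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  # degenerate rows: no variance in either group
  degen <- se2 == 0
  if (any(degen)) {
    tied <- degen & diff == 0
    t[tied] <- 0
    df[degen] <- NA_real_
    apart <- degen & diff != 0
    if (any(apart)) {
      t[apart] <- sign(diff[apart]) * Inf
      warn(sprintf(
        "%d probe(s) constant within both groups but with different means; p-value set by direction.",
        sum(apart)
      ))
    }
  }
  p <- switch(alternative,
    greater = pt(t, df, lower.tail = FALSE),
    less = pt(t, df, lower.tail = TRUE),
    two.sided = 2 * pt(-abs(t), df, lower.tail = TRUE)
  )
  if (any(degen)) {
    # constant equal groups carry no evidence either way
    p[degen & diff == 0] <- if (alternative == "two.sided") 1 else 0.5
    apart <- degen & diff != 0
    p[apart] <- switch(alternative,
      greater = ifelse(diff[apart] > 0, 0, 1),
      less = ifelse(diff[apart] < 0, 0, 1),
      two.sided = 0
    )
  }
  tibble(
    t = unname(t), df = unname(df), p = unname(p),
    mean_1 = unname(m1), mean_2 = unname(m2)
  )
}

#' Probe-level differential test of case versus control
#'
#' Per-probe t-test of normalized signals (default: Welch, unequal
#' variances) with the one-sided alternative that cases exceed controls —
#' the direction that means "significantly present in the cases". Probes
#' constant and equal in both groups get `t = 0`, one-sided `p = 0.5` by
#' convention.
#'
#' @param normalized A `pathosig_normalized` object or its long `normalized`
#'   tibble.
#' @param metadata Sample metadata tibble (`sample_id`, `group`).
#' @param case_group,control_group Group labels to contrast.
#' @param alternative `"greater"` (case > control, default), `"less"`, or
#'   `"two.sided"`.
#' @param var_equal Use the pooled-variance t instead of Welch. Default FALSE.
#' @return Tibble with one row per microbial probe: `probe_id`, `t`, `df`,
#'   `p`, `log2fc` (mean case - mean control), `mean_case`, `mean_control`.
#' @export
test_probes <- function(normalized, metadata, case_group,
                        control_group = "control",
                        alternative = "greater", var_equal = FALSE) {
  metadata <- validate_metadata(metadata)
  m <- normalized_matrix(normalized)
  case_ids <- intersect(colnames(m), metadata$sample_id[metadata$group == case_group])
  ctrl_ids <- intersect(colnames(m), metadata$sample_id[metadata$group == control_group])
  res <- row_t_test(m, match(case_ids, colnames(m)), match(ctrl_ids, colnames(m)),
    alternative = alternative, var_equal = var_equal
  )
  tibble(
    probe_id = rownames(m),
    t = res$t, df = res$df, p = res$p,
    log2fc = res$mean_1 - res$mean_2,
    mean_case = res$mean_1, mean_control = res$mean_2
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment: rank p ascending, multiply by m/rank, enforce
#' monotonicity from the largest rank down, cap at 1; returned in input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' bh_adjust(c(0.001, 0.5)) # 0.002, 0.5
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Per-sample probe presence calls
#'
#' The prevalence statistic needs a per-sample detection rule: a probe is
#' called present in a sample when its normalized signal exceeds the mean
#' control-sample signal of that probe by at least `presence_delta` log2
#' units (default 1, mirroring the log2 fold-change significance cut-off at
#' the single-sample level). Control samples are called against the same
#' control-mean baseline.
#'
#' @inheritParams test_probes
#' @param presence_delta Detection margin over the control mean, log2 units.
#' @return Long tibble `probe_id`, `sample_id`, `detected` (logical),
#'   covering every probe and sample of `normalized`.
#' @export
probe_presence <- function(normalized, metadata, control_group = "control",
                           presence_delta = 1) {
  metadata <- validate_metadata(metadata)
  m <- normalized_matrix(normalized)
  ctrl_ids <- intersect(colnames(m), metadata$sample_id[metadata$group == control_group])
  if (length(ctrl_ids) < 1) {
    abort(sprintf("Need at least 1 sample in control group `%s`.", control_group))
  }
  baseline <- rowMeans(m[, ctrl_ids, drop = FALSE])
  det <- (m - baseline) >= presence_delta
  tibble(
    probe_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    detected = as.vector(det)
  )
}

#' Organism-level prevalence from probe presence calls
#'
#' Prevalence of a signature in a group is the percentage of the group's
#' samples in which the signature is detected. Under the default `"union"`
#' rule a sample counts as positive when at least one of the organism's
#' probes is detected in it; under the `"max"` rule the prevalence is the
#' maximum over the organism's probes of the per-probe detected sample count.
#'
#' @param presence Long presence tibble from [probe_presence()].
#' @param annotation Probe annotation tibble (maps probes to organisms).
#' @param metadata Sample metadata tibble.
#' @param groups Group labels to compute prevalence for; default all groups
#'   present in `metadata`.
#' @param rule `"union"` (default) or `"max"`.
#' @return Tibble `organism`, `group`, `n_samples`, `n_detected`,
#'   `prevalence_pct`.
#' @export
signature_prevalence <- function(presence, annotation, metadata,
                                 groups = NULL, rule = c("union", "max")) {
  rule <- match.arg(rule)
  assert_df_cols(presence, c("probe_id", "sample_id", "detected"), "presence")
  metadata <- validate_metadata(metadata)
  if (is.null(groups)) groups <- unique(metadata$group)
  unmapped <- setdiff(unique(presence$probe_id), annotation$probe_id)
  if (length(unmapped) > 0) {
    abort(sprintf(
      "%d probe(s) in the presence matrix missing from the annotation (first: %s).",
      length(unmapped), unmapped[1]
    ))
  }
  x <- presence |>
    inner_join(annotation[, c("probe_id", "organism")], by = "probe_id") |>
    inner_join(metadata[, c("sample_id", "group")], by = "sample_id") |>
    filter(.data$group %in% groups)
  sizes <- metadata |>
    filter(.data$group %in% groups) |>
    dplyr::count(.data$group, name = "n_samples")
  if (any(!groups %in% sizes$group)) {
    abort(sprintf(
      "Group `%s` has no samples.", setdiff(groups, sizes$group)[1]
    ))
  }
  counts <- if (rule == "union") {
    x |>
      group_by(.data$organism, .data$group, .data$sample_id) |>
      summarise(hit = any(.data$detected), .groups = "drop") |>
      group_by(.data$organism, .data$group) |>
      summarise(n_detected = sum(.data$hit), .groups = "drop")
  } else {
    x |>
      group_by(.data$organism, .data$group, .data$probe_id) |>
      summarise(hits = sum(.data$detected), .groups = "drop") |>
      group_by(.data$organism, .data$group) |>
      summarise(n_detected = max(.data$hits), .groups = "drop")
  }
  counts |>
    left_join(sizes, by = "group") |>
    mutate(prevalence_pct = 100 * .data$n_detected / .data$n_samples) |>
    arrange(.data$organism, .data$group)
}

#' Joint significance thresholds for signature detection
#'
#' Defaults follow the screen's Methods thresholds: probe log2 fold change
#' >= 1 and BH-adjusted p <= 0.01, organism case prevalence >= 40% and
#' control prevalence <= 25%. A nominal-p variant (e.g. `max_adj_p = 0.05`
#' applied to unadjusted p) can be configured but is not the default.
#'
#' @param min_log2fc Minimum probe log2 fold change (case - control).
#' @param max_adj_p Maximum BH-adjusted one-sided p-value.
#' @param min_case_prev_pct Minimum case prevalence, percent.
#' @param max_control_prev_pct Maximum control prevalence, percent.
#' @param presence_delta Per-sample detection margin, log2 units (see
#'   [probe_presence()]).
#' @return A `pathosig_thresholds` list.
#' @export
detection_thresholds <- function(min_log2fc = 1, max_adj_p = 0.01,
                                 min_case_prev_pct = 40,
                                 max_control_prev_pct = 25,
                                 presence_delta = 1) {
  assert_scalar_number(min_log2fc, "min_log2fc")
  assert_scalar_number(max_adj_p, "max_adj_p", 0, 1)
  assert_scalar_number(min_case_prev_pct, "min_case_prev_pct", 0, 100)
  assert_scalar_number(max_control_prev_pct, "max_control_prev_pct", 0, 100)
  assert_scalar_number(presence_delta, "presence_delta")
  structure(
    list(
      min_log2fc = min_log2fc, max_adj_p = max_adj_p,
      min_case_prev_pct = min_case_prev_pct,
      max_control_prev_pct = max_control_prev_pct,
      presence_delta = presence_delta
    ),
    class = "pathosig_thresholds"
  )
}

#' Apply the joint probe and prevalence filters
#'
#' A probe is significant when `log2fc >= min_log2fc` and
#' `adj_p <= max_adj_p`. An organism is reported when it has at least one
#' significant probe, its case prevalence is at least `min_case_prev_pct`,
#' and its control prevalence is at most `max_control_prev_pct`.
#'
#' @param probe_stats Probe statistics with an `adj_p` column (from
#'   [test_probes()] + [bh_adjust()]).
#' @param prevalence Prevalence tibble from [signature_prevalence()] covering
#'   the case and control groups.
#' @param annotation Probe annotation tibble.
#' @param case_group,control_group Group labels used in `prevalence`.
#' @param thresholds A [detection_thresholds()] object.
#' @return Signature tibble: `organism`, `organism_class`,
#'   `n_significant_probes`, `significant_probe_ids` (comma-separated),
#'   `case_prevalence_pct`, `control_prevalence_pct`, `mean_case`,
#'   `mean_control` (means over significant probes of per-probe group means,
#'   log2 units).
#' @export
filter_signatures <- function(probe_stats, prevalence, annotation,
                              case_group, control_group = "control",
                              thresholds = detection_thresholds()) {
  assert_df_cols(probe_stats, c("probe_id", "adj_p", "log2fc", "mean_case", "mean_control"),
    what = "probe_stats"
  )
  stopifnot(inherits(thresholds, "pathosig_thresholds"))
  stats <- probe_stats |>
    inner_join(annotation[, c("probe_id", "organism", "organism_class")],
      by = "probe_id"
    ) |>
    mutate(significant = .data$log2fc >= thresholds$min_log2fc &
      .data$adj_p <= thresholds$max_adj_p)
  prev_wide <- prevalence |>
    filter(.data$group %in% c(case_group, control_group)) |>
    mutate(side = ifelse(.data$group == case_group, "case_prevalence_pct",
      "control_prevalence_pct"
    )) |>
    select("organism", "side", "prevalence_pct") |>
    tidyr::pivot_wider(names_from = "side", values_from = "prevalence_pct")
  for (col in c("case_prevalence_pct", "control_prevalence_pct")) {
    if (!col %in% names(prev_wide)) prev_wide[[col]] <- 0
  }
  stats |>
    filter(.data$significant) |>
    group_by(.data$organism, .data$organism_class) |>
    summarise(
      n_significant_probes = dplyr::n(),
      significant_probe_ids = paste(.data$probe_id, collapse = ","),
      mean_case = mean(.data$mean_case),
      mean_control = mean(.data$mean_control),
      .groups = "drop"
    ) |>
    inner_join(prev_wide, by = "organism") |>
    filter(
      .data$case_prevalence_pct >= thresholds$min_case_prev_pct,
      .data$control_prevalence_pct <= thresholds$max_control_prev_pct
    ) |>
    select(
      "organism", "organism_class", "n_significant_probes",
      "significant_probe_ids", "case_prevalence_pct",
      "control_prevalence_pct", "mean_case", "mean_control"
    ) |>
    arrange(.data$organism)
}

#' Detect microbial signatures in one case group versus controls
#'
#' The full probe-to-signature detection stage: one-sided probe tests
#' ([test_probes()]), BH adjustment across all microbial probes of this
#' comparison ([bh_adjust()]), per-sample presence calls
#' ([probe_presence()]), organism prevalence ([signature_prevalence()]), and
#' the joint filters ([filter_signatures()]).
#'
#' @inheritParams test_probes
#' @param thresholds A [detection_thresholds()] object.
#' @param prevalence_rule `"union"` (default) or `"max"`, see
#'   [signature_prevalence()].
#' @return A `pathosig_detection` object with elements `probe_stats` (all
#'   probes, with `adj_p` and `significant`), `signatures` (reported
#'   organisms), `prevalence`, `presence`, plus the thresholds and group
#'   labels. [tidy()] returns the probe statistics, [glance()] a one-row
#'   summary.
#' @export
detect_signatures <- function(normalized, metadata, case_group,
                              control_group = "control",
                              thresholds = detection_thresholds(),
                              alternative = "greater", var_equal = FALSE,
                              prevalence_rule = "union") {
  metadata <- validate_metadata(metadata)
  annotation <- if (inherits(normalized, "pathosig_normalized")) {
    normalized$annotation
  } else {
    abort("`normalized` must be a pathosig_normalized object.")
  }
  probe_stats <- test_probes(normalized, metadata, case_group, control_group,
    alternative = alternative, var_equal = var_equal
  ) |>
    mutate(adj_p = bh_adjust(.data$p))
  presence <- probe_presence(normalized, metadata, control_group,
    presence_delta = thresholds$presence_delta
  )
  prevalence <- signature_prevalence(presence, annotation, metadata,
    groups = c(case_group, control_group), rule = prevalence_rule
  )
  signatures <- filter_signatures(probe_stats, prevalence, annotation,
    case_group, control_group,
    thresholds = thresholds
  )
  probe_stats <- probe_stats |>
    mutate(significant = .data$log2fc >= thresholds$min_log2fc &
      .data$adj_p <= thresholds$max_adj_p)
  structure(
    list(
      probe_stats = probe_stats, signatures = signatures,
      prevalence = prevalence, presence = presence,
      thresholds = thresholds, case_group = case_group,
      control_group = control_group, prevalence_rule = prevalence_rule
    ),
    class = "pathosig_detection"
  )
}

#' @export
print.pathosig_detection <- function(x, ...) {
  cat(sprintf(
    "<pathosig detection: %s vs %s>\n", x$case_group, x$control_group
  ))
  cat(sprintf(
    "  %d probes tested, %d significant; %d signatures reported\n",
    nrow(x$probe_stats), sum(x$probe_stats$significant), nrow(x$signatures)
  ))
  invisible(x)
}
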