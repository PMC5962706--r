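#' Hierarchical clustering of samples on signature profiles
#'
#' Agglomerative clustering with Euclidean distance and complete linkage on
#' the unscaled signature-profile matrix (profiles are clustered as-is, no
#' standardization), plus Calinski-Harabasz selection of the cluster count
#' over `k_range`.
#'
#' @param profiles Data frame with a `sample_id` column followed by numeric
#'   feature columns (see [signature_profiles()]), or a plain numeric matrix
#'   with sample row names.
#' @param k_range Candidate cluster counts; default `2:min(10, n - 1)`.
#'   Use `NULL` to skip cluster-count selection (e.g. for n = 2).
#' @return A `pathosig_clusters` object: `hclust` (the merge tree), `labels`
#'   (tibble of cluster labels per candidate k), `ch_curve` (tibble `k`,
#'   `ch`), `selected_k` (argmax of the curve, smallest k on ties),
#'   `leaf_order` (sample ids in dendrogram order for heatmap export).
#' @export
#' @examples
#' set.seed(1)
#' pts <- tibble::tibble(
#'   sample_id = paste0("s", 1:20),
#'   x = c(rnorm(10, 0), rnorm(10, 10)),
#'   y = rnorm(20)
#' )
#' cl <- cluster_samples(pts, k_range = 2:5)
#' cl$selected_k
cluster_samples <- function(profiles, k_range = NULL) {
  m <- profile_matrix(profiles)
  n <- nrow(m)
  if (n < 2) abort("Clustering needs at least 2 samples.")
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Missing value in profiles at sample %s, feature %s.",
      rownames(m)[idx[1]], colnames(m)[idx[2]]
    ))
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  if (is.null(k_range) && n > 2) k_range <- 2:min(10, n - 1)
  labels <- NULL
  ch_curve <- NULL
  selected_k <- NA_integer_
  if (!is.null(k_range) && length(k_range) > 0) {
    if (any(k_range < 2) || any(k_range > n - 1)) {
      abort(sprintf("`k_range` must lie within [2, %d].", n - 1))
    }
    cuts <- cutree(hc, k = k_range)
    cuts <- matrix(cuts, nrow = n, dimnames = list(rownames(m), k_range))
    ch <- vapply(seq_along(k_range), function(j) {
      calinski_harabasz(m, cuts[, j])
    }, numeric(1))
    ch_curve <- tibble(k = as.integer(k_range), ch = ch)
    selected_k <- ch_curve$k[which.max(ch_curve$ch)]
    labels <- as_tibble(cuts, .name_repair = ~ paste0("k", k_range)) |>
      mutate(sample_id = rownames(m), .before = 1)
  }
  structure(
    list(
      hclust = hc, labels = labels, ch_curve = ch_curve,
      selected_k = selected_k, leaf_order = rownames(m)[hc$order]
    ),
    class = "pathosig_clusters"
  )
}

#' @export
print.pathosig_clusters <- function(x, ...) {
  cat("<pathosig clusters>\n")
  n <- length(x$hclust$order)
  if (!is.na(x$selected_k)) {
    cat(sprintf(
      "  %d samples; selected k = %d (CH = %.4g)\n", n, x$selected_k,
      x$ch_curve$ch[x$ch_curve$k == x$selected_k]
    ))
  } else {
    cat(sprintf("  %d samples; no cluster count selected\n", n))
  }
  invisible(x)
}

profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- sprintf("sample_%d", seq_len(nrow(profiles)))
    }
    return(profiles)
  }
  assert_df_cols(profiles, "sample_id", "profiles")
  feat <- setdiff(names(profiles), "sample_id")
  if (length(feat) == 0) abort("`profiles` has no feature columns.")
  m <- as.matrix(profiles[, feat, drop = FALSE])
  if (!is.numeric(m)) abort("Profile feature columns must be numeric.")
  rownames(m) <- profiles$sample_id
  m
}

#' Cut a cluster tree into k groups
#'
#' @param clusters A `pathosig_clusters` object or `hclust` tree.
#' @param k Number of groups, `1 <= k <= n`.
#' @return Named integer vector of cluster labels per sample.
#' @export
cut_clusters <- function(clusters, k) {
  tree <- if (inherits(clusters, "pathosig_clusters")) clusters$hclust else clusters
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    abort(sprintf("`k` must lie within [1, %d].", n))
  }
  cutree(tree, k = k)
}

#' Calinski-Harabasz index of a clustering
#'
#' `CH = (B / (k - 1)) / (W / (n - k))`, where `B` is the between-cluster
#' dispersion `sum_c n_c * ||mu_c - mu||^2` and `W` the within-cluster
#' dispersion `sum_c sum_i ||x_i - mu_c||^2`. Large values mean compact,
#' well-separated clusters; the index is maximized over k to choose the
#' cluster count. A perfect clustering of duplicated points (`W = 0`)
#' returns `Inf` with a warning.
#'
#' @param profiles Profile data frame or numeric matrix (samples in rows).
#' @param labels Cluster label per sample (any atomic type), with
#'   `2 <= k <= n - 1` distinct values and no empty cluster.
#' @return The CH value.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 10, 11), ncol = 1)
#' calinski_harabasz(m, c(1, 1, 2, 2)) # (100/1) / (1/2) = 200
calinski_harabasz <- function(profiles, labels) {
  m <- profile_matrix(profiles)
  n <- nrow(m)
  if (length(labels) != n) abort("`labels` must have one entry per sample.")
  labels <- as.factor(labels)
  k <- nlevels(droplevels(labels))
  if (k < 2 || k > n - 1) {
    abort(sprintf("CH needs 2 <= k <= n - 1 (got k = %d, n = %d).", k, n))
  }
  mu <- colMeans(m)
  b <- 0
  w <- 0
  for (lev in levels(labels)) {
    rows <- m[labels == lev, , drop = FALSE]
    mu_c <- colMeans(rows)
    b <- b + nrow(rows) * sum((mu_c - mu)^2)
    w <- w + sum(sweep(rows, 2, mu_c)^2)
  }
  if (w == 0) {
    warn("Within-cluster dispersion is zero; CH index is infinite.")
    return(Inf)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Select the cluster count by maximizing the CH index
#'
#' Cuts the complete-linkage tree at every k in `k_range`, computes the CH
#' index of each partition, and returns the maximizer (smallest k on ties).
#'
#' @inheritParams cluster_samples
#' @param k_range Candidate counts, a subset of `[2, n - 1]`.
#' @return List with `selected_k` and the `ch_curve` tibble.
#' @export
select_cluster_count <- function(profiles, k_range = NULL) {
  cl <- cluster_samples(profiles, k_range = k_range)
  if (is.null(cl$ch_curve)) abort("`k_range` is empty; nothing to select.")
  list(selected_k = cl$selected_k, ch_curve = cl$ch_curve)
}

#' Signature contrasts between two clusters
#'
#' Per-organism Welch t-test of aggregated signature signals between two
#' clusters of samples (two-sided by default), with
#' `logFC = mean(cluster a) - mean(cluster b)`. Swapping the clusters
#' negates both `t` and `logFC`.
#'
#' @param profiles Profile data frame (`sample_id` + organism columns) or
#'   matrix.
#' @param labels Cluster label per sample (named by sample id, or in row
#'   order of `profiles`).
#' @param cluster_a,cluster_b The two labels to contrast; both clusters need
#'   at least 2 samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Tibble `organism`, `t`, `df`, `p`, `logfc`.
#' @export
cluster_contrast <- function(profiles, labels, cluster_a, cluster_b,
                             alternative = "two.sided") {
  m <- profile_matrix(profiles)
  if (!is.null(names(labels))) {
    labels <- labels[rownames(m)]
  }
  if (length(labels) != nrow(m)) {
    abort("`labels` must cover every sample in `profiles`.")
  }
  ia <- which(labels == cluster_a)
  ib <- which(labels == cluster_b)
  res <- row_t_test(t(m), ia, ib, alternative = alternative)
  tibble(
    organism = colnames(m),
    t = res$t, df = res$df, p = res$p,
    logfc = res$mean_1 - res$mean_2
  ) |>
    arrange(.data$p)
}
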