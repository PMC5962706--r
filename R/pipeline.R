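# schema: known keys per config block
.config_schema <- list(
  top = c(
    "seed", "inputs", "simulation", "normalization", "detection",
    "clustering", "outcome", "control_group"
  ),
  inputs = c("signals", "annotation", "metadata"),
  simulation = c(
    "group_sizes", "n_human_probes", "signatures", "probes_per_signature",
    "n_decoy_organisms", "baseline_log2", "noise_sd_log2", "human_log2",
    "outcome_deceased_frac"
  ),
  signature = c(
    "organism", "organism_class", "target_groups", "effect_log2",
    "case_prevalence_frac", "control_prevalence_frac"
  ),
  normalization = c("mode", "signal_floor"),
  detection = c(
    "min_log2fc", "max_adj_p", "min_case_prev_pct", "max_control_prev_pct",
    "presence_delta", "alternative", "var_equal", "prevalence_rule"
  ),
  clustering = c("k_max", "contrast_alternative"),
  outcome = c("alpha")
)

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes an equivalent list), fills
#' defaults, and rejects unknown keys. Exactly one of an `inputs` block
#' (paths to the signal, annotation and metadata tables) or a `simulation`
#' block (arguments of [sim_config()]) must be present. All schema
#' violations are reported at once.
#'
#' @param config Path to a YAML/JSON file, or a list with the same
#'   structure.
#' @return A validated `pathosig_config` list with every default filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a path to a YAML/JSON file.")
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  unknown <- setdiff(names(config), .config_schema$top)
  if (length(unknown) > 0) {
    note(sprintf("Unknown top-level key(s): %s.", paste(unknown, collapse = ", ")))
  }
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulation)
  if (has_inputs == has_sim) {
    note("Exactly one of `inputs` and `simulation` must be present.")
  }
  check_block <- function(block, schema_name) {
    bad <- setdiff(names(block), .config_schema[[schema_name]])
    if (length(bad) > 0) {
      note(sprintf(
        "Unknown key(s) in `%s`: %s.", schema_name, paste(bad, collapse = ", ")
      ))
    }
  }
  if (has_inputs) {
    check_block(config$inputs, "inputs")
    for (f in .config_schema$inputs) {
      if (is.null(config$inputs[[f]])) {
        note(sprintf("`inputs` is missing the `%s` path.", f))
      }
    }
  }
  if (has_sim) {
    check_block(config$simulation, "simulation")
    for (s in config$simulation$signatures %||% list()) {
      check_block(s, "signature")
    }
  }
  for (nm in c("normalization", "detection", "clustering", "outcome")) {
    if (!is.null(config[[nm]])) check_block(config[[nm]], nm)
  }
  if (length(errs) > 0) {
    abort(paste(
      c("Invalid pipeline configuration:", paste("-", errs)),
      collapse = "\n"
    ))
  }

  seed <- as.integer(config$seed %||% 1L)
  out <- list(
    seed = seed,
    control_group = config$control_group %||% "control",
    inputs = config$inputs,
    simulation = NULL,
    normalization = list(
      mode = config$normalization$mode %||% "literal",
      signal_floor = config$normalization$signal_floor %||% 1
    ),
    detection = list(
      min_log2fc = config$detection$min_log2fc %||% 1,
      max_adj_p = config$detection$max_adj_p %||% 0.01,
      min_case_prev_pct = config$detection$min_case_prev_pct %||% 40,
      max_control_prev_pct = config$detection$max_control_prev_pct %||% 25,
      presence_delta = config$detection$presence_delta %||% 1,
      alternative = config$detection$alternative %||% "greater",
      var_equal = isTRUE(config$detection$var_equal),
      prevalence_rule = config$detection$prevalence_rule %||% "union"
    ),
    clustering = list(
      k_max = config$clustering$k_max %||% 10,
      contrast_alternative = config$clustering$contrast_alternative %||% "two.sided"
    ),
    outcome = list(alpha = config$outcome$alpha %||% 0.05)
  )
  if (has_sim) {
    sim <- config$simulation
    sigs <- purrr::map(sim$signatures %||% list(), function(s) {
      planted_signature(
        organism = s$organism,
        organism_class = s$organism_class,
        target_groups = unlist(s$target_groups),
        effect_log2 = s$effect_log2 %||% 2,
        case_prevalence_frac = s$case_prevalence_frac %||% 0.6,
        control_prevalence_frac = s$control_prevalence_frac %||% 0
      )
    })
    gs <- sim$group_sizes
    if (!is.null(gs)) gs <- unlist(gs)
    out$simulation <- sim_config(
      group_sizes = gs %||% .default_group_sizes,
      n_human_probes = sim$n_human_probes %||% 500,
      signatures = sigs,
      probes_per_signature = sim$probes_per_signature %||% 5,
      n_decoy_organisms = sim$n_decoy_organisms %||% 20,
      baseline_log2 = sim$baseline_log2 %||% 6,
      noise_sd_log2 = sim$noise_sd_log2 %||% 0.3,
      human_log2 = sim$human_log2 %||% 10,
      outcome_deceased_frac = sim$outcome_deceased_frac %||% 0.3,
      seed = seed
    )
  }
  structure(out, class = "pathosig_config")
}

log_line <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (!is.null(con)) writeLines(line, con)
  inform(msg)
}

#' Run the full signature-detection pipeline
#'
#' Executes every stage end-to-end: load or simulate the experiment,
#' normalize, detect signatures per case group versus controls, aggregate
#' organism-level signals and percent shares, partition signatures across
#' case groups, cluster each case group and the pooled cases on their
#' signature profiles (with CH cluster-count selection, pairwise cluster
#' contrasts and Newick dendrogram export), and associate signatures and
#' clusters with outcomes. All result tables are written under `out_dir`
#' together with a `manifest.json` (configuration hash, seed, versions,
#' per-stage row counts). A fixed seed gives byte-identical output tables;
#' timestamps appear only in `run.log`.
#'
#' @param config A `pathosig_config` from [validate_config()] (or a path /
#'   list accepted by it).
#' @param out_dir Output directory, created if absent.
#' @param quiet Suppress progress messages. Default TRUE.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = TRUE) {
  if (!inherits(config, "pathosig_config")) config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(msg) {
    if (quiet) writeLines(
      sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg), log_con
    ) else log_line(log_con, msg)
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_effective.yaml"))

  if (!is.null(config$simulation)) {
    say(sprintf("simulate: seed %d", config$simulation$seed))
    experiment <- simulate_experiment(config$simulation)
  } else {
    say("load: reading input tables")
    experiment <- structure(
      list(
        signals = read_signal_table(
          config$inputs$signals, config$normalization$signal_floor
        ),
        annotation = read_probe_annotations(config$inputs$annotation),
        metadata = read_sample_metadata(config$inputs$metadata),
        truth = NULL, config = NULL
      ),
      class = "pathosig_experiment"
    )
  }
  metadata <- experiment$metadata
  ctrl <- config$control_group
  if (!ctrl %in% metadata$group) {
    abort(sprintf("Stage detect: control group `%s` absent from metadata.", ctrl))
  }

  say("normalize: computing scale factors and normalized signals")
  norm <- normalize_signals(
    experiment$signals, experiment$annotation,
    mode = config$normalization$mode,
    signal_floor = config$normalization$signal_floor
  )
  tables <- list(scale_factors = norm$scale_factors)

  thresholds <- detection_thresholds(
    min_log2fc = config$detection$min_log2fc,
    max_adj_p = config$detection$max_adj_p,
    min_case_prev_pct = config$detection$min_case_prev_pct,
    max_control_prev_pct = config$detection$max_control_prev_pct,
    presence_delta = config$detection$presence_delta
  )
  case_groups <- setdiff(unique(metadata$group), ctrl)
  detections <- list()
  signature_sets <- list()
  for (g in case_groups) {
    say(sprintf("detect: %s vs %s", g, ctrl))
    det <- detect_signatures(norm, metadata, g, ctrl,
      thresholds = thresholds,
      alternative = config$detection$alternative,
      var_equal = config$detection$var_equal,
      prevalence_rule = config$detection$prevalence_rule
    )
    detections[[g]] <- det
    signature_sets[[g]] <- det$signatures$organism
    tables[[paste0("probe_stats_", g)]] <- det$probe_stats
    tables[[paste0("signatures_", g)]] <- det$signatures
    tables[[paste0("prevalence_", g)]] <- det$prevalence
  }

  say("signatures: aggregating signals, shares and the Venn partition")
  shares <- purrr::map(case_groups, function(g) {
    sig <- detections[[g]]$signatures
    if (nrow(sig) == 0) {
      return(NULL)
    }
    aggregate_signatures(norm, sig, metadata, groups = g) |>
      percent_signal_share()
  })
  shares <- bind_rows(shares)
  tables$signal_shares <- shares
  partition <- partition_signatures(signature_sets)
  tables$venn_partition <- partition
  venn_json(partition, file.path(out_dir, "venn_partition.json"))

  cluster_scope <- c(
    stats::setNames(as.list(case_groups), case_groups),
    list(pooled = case_groups)
  )
  cluster_results <- list()
  contrast_rows <- list()
  outcome_rows <- list()
  cluster_outcome_rows <- list()
  for (scope in names(cluster_scope)) {
    grps <- cluster_scope[[scope]]
    orgs <- unique(unlist(signature_sets[grps], use.names = FALSE))
    ids <- metadata$sample_id[metadata$group %in% grps]
    if (length(orgs) == 0 || length(ids) < 4) {
      say(sprintf("cluster: %s skipped (%d signatures, %d samples)", scope,
        length(orgs), length(ids)))
      next
    }
    sig_union <- bind_rows(purrr::map(detections[grps], "signatures")) |>
      distinct(.data$organism, .keep_all = TRUE)
    profiles <- signature_profiles(norm, sig_union, sample_ids = ids)
    say(sprintf("cluster: %s (%d samples x %d signatures)", scope,
      length(ids), length(orgs)))
    kr <- 2:min(config$clustering$k_max, length(ids) - 1)
    cl <- cluster_samples(profiles, k_range = kr)
    cluster_results[[scope]] <- cl
    tables[[paste0("cluster_labels_", scope)]] <- cl$labels
    tables[[paste0("ch_curve_", scope)]] <- cl$ch_curve
    export_newick(cl, file.path(out_dir, paste0("dendrogram_", scope, ".nwk")))

    labels <- cut_clusters(cl, cl$selected_k)
    big <- names(table(labels))[table(labels) >= 2]
    if (length(big) >= 2) {
      pairs <- utils::combn(big, 2, simplify = FALSE)
      con <- purrr::map(pairs, function(pr) {
        cluster_contrast(profiles, labels, pr[1], pr[2],
          alternative = config$clustering$contrast_alternative
        ) |>
          mutate(scope = scope, cluster_a = pr[1], cluster_b = pr[2], .before = 1)
      })
      contrast_rows[[scope]] <- bind_rows(con)
    }
    cluster_outcome_rows[[scope]] <-
      cluster_outcome_summary(labels, metadata) |>
      mutate(scope = scope, .before = 1)

    if (scope != "pooled") {
      known <- metadata[metadata$sample_id %in% ids & !is.na(metadata$outcome), ]
      if (sum(known$outcome == "deceased") >= 2 && sum(known$outcome == "alive") >= 2) {
        say(sprintf("outcome: %s deceased vs alive", scope))
        outcome_rows[[scope]] <- bind_rows(
          outcome_association(profiles, metadata, "deceased_greater",
            alpha = config$outcome$alpha
          ),
          outcome_association(profiles, metadata, "alive_greater",
            alpha = config$outcome$alpha
          )
        ) |>
          mutate(group = scope, .before = 1)
      } else {
        say(sprintf("outcome: %s skipped (too few known outcomes)", scope))
      }
    }
  }
  if (length(contrast_rows) > 0) {
    tables$cluster_contrasts <- bind_rows(contrast_rows)
  }
  if (length(cluster_outcome_rows) > 0) {
    tables$cluster_outcomes <- bind_rows(cluster_outcome_rows)
  }
  if (length(outcome_rows) > 0) {
    tables$outcome_associations <- bind_rows(outcome_rows)
  }

  say("write: emitting result tables and manifest")
  paths <- write_tables(tables, out_dir)
  manifest <- list(
    package = "pathosig",
    version = as.character(utils::packageVersion("pathosig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_probes = nrow(experiment$annotation),
    n_samples = nrow(metadata),
    case_groups = as.list(stats::setNames(
      vapply(case_groups, function(g) sum(metadata$group == g), integer(1)),
      case_groups
    )),
    reported_signatures = as.list(stats::setNames(
      vapply(case_groups, function(g) length(signature_sets[[g]]), integer(1)),
      case_groups
    )),
    selected_k = as.list(purrr::map(cluster_results, "selected_k")),
    tables = as.list(stats::setNames(
      vapply(tables, nrow, integer(1)), names(tables)
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(manifest, list(
    detections = detections, clusters = cluster_results, files = paths
  )))
}
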