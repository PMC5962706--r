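#' Build the probe library of a synthetic experiment
#'
#' Lays out the annotation table of a simulated array: `n_human_probes` human
#' reference probes, `probes_per_signature` probes for every planted organism,
#' and the same number for every decoy organism (present on the array, no
#' planted effect). Mirrors the structure of a pan-pathogen chip where each
#' organism is targeted by several probes against different genomic regions.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `probe_id`, `organism`, `organism_class`,
#'   `is_human` (0/1); one row per probe, probe ids unique.
#' @export
#' @examples
#' lib <- build_probe_library(sim_config(n_human_probes = 10))
#' table(lib$organism_class)
build_probe_library <- function(config) {
  stopifnot(inherits(config, "pathosig_sim_config"))
  planted <- vapply(config$signatures, `[[`, character(1), "organism")
  decoys <- if (config$n_decoy_organisms > 0) {
    sprintf("Decoy_%02d", seq_len(config$n_decoy_organisms))
  } else {
    character()
  }
  dup <- intersect(planted, decoys)
  if (length(dup) > 0) {
    abort(sprintf(
      "Organism name%s duplicated between planted signatures and decoys: %s.",
      if (length(dup) > 1) "s" else "", paste(dup, collapse = ", ")
    ))
  }

  human <- tibble(
    probe_id = sprintf("HUM_%05d", seq_len(config$n_human_probes)),
    organism = "Homo sapiens",
    organism_class = "human",
    is_human = 1L
  )
  planted_classes <- vapply(config$signatures, `[[`, character(1), "organism_class")
  # decoys cycle through the microbial classes so every class has a null set
  decoy_classes <- rep_len(.organism_classes, length(decoys))
  org <- c(planted, decoys)
  cls <- c(planted_classes, decoy_classes)
  microbial <- tibble(
    organism = rep(org, each = config$probes_per_signature),
    organism_class = rep(cls, each = config$probes_per_signature),
    probe_id = sprintf(
      "%s|%02d", rep(org, each = config$probes_per_signature),
      rep(seq_len(config$probes_per_signature), times = length(org))
    ),
    is_human = 0L
  )
  out <- bind_rows(human, microbial[, names(human)])
  stopifnot(!anyDuplicated(out$probe_id))
  out
}

# deterministic carrier choice: exactly round(frac * n) carriers per group,
# picked by a seeded permutation (not Bernoulli), so prevalence filters are
# exactly testable
assign_carriers <- function(config, metadata) {
  carriers <- character()
  for (sig in config$signatures) {
    groups <- c(sig$target_groups, if (sig$control_prevalence_frac > 0) "control")
    for (g in groups) {
      ids <- metadata$sample_id[metadata$group == g]
      frac <- if (g == "control") sig$control_prevalence_frac else sig$case_prevalence_frac
      k <- round(frac * length(ids))
      if (k > 0) {
        chosen <- sample(ids)[seq_len(k)]
        carriers <- c(carriers, paste(sig$organism, chosen, sep = "\r"))
      }
    }
  }
  carriers
}

#' Simulate a two-channel pan-pathogen microarray experiment
#'
#' Draws raw green (sample channel) and red (human reference channel) signals
#' for every probe and sample: `raw = 2^(mean_log2 + Normal(0, noise_sd_log2))`
#' per channel, independently across probes, samples and channels. Human
#' probes are centred at `human_log2` in both channels; microbial probes at
#' `baseline_log2` in both channels (background cross-hybridization); samples
#' carrying a planted signature get `effect_log2` added to the green-channel
#' log2 mean of that signature's probes. Carrier status per signature and
#' sample is recorded as ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A `pathosig_experiment` list with elements
#'   \describe{
#'     \item{signals}{long tibble: `probe_id`, `sample_id`, `green_signal`,
#'       `red_signal` (raw fluorescence, strictly positive)}
#'     \item{annotation}{probe annotation tibble, see [build_probe_library()]}
#'     \item{metadata}{tibble: `sample_id`, `group`, `outcome`}
#'     \item{truth}{tibble: `organism`, `sample_id`, `carrier` (0/1), one row
#'       per planted signature and sample}
#'     \item{config}{the configuration used}
#'   }
#' @export
#' @examples
#' exp <- simulate_experiment(sim_config(
#'   group_sizes = c(BRER = 4, control = 3), n_human_probes = 5,
#'   n_decoy_organisms = 2, seed = 7
#' ))
#' exp$signals
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "pathosig_sim_config"))
  annotation <- build_probe_library(config)

  metadata <- tibble(
    group = rep(names(config$group_sizes), times = config$group_sizes)
  ) |>
    group_by(.data$group) |>
    mutate(sample_id = sprintf("%s_%03d", .data$group, dplyr::row_number())) |>
    ungroup() |>
    select("sample_id", "group")
  # keep samples in the declared group order
  metadata <- metadata[order(match(metadata$group, names(config$group_sizes))), ]

  withr::with_seed(config$seed, {
    carrier_keys <- assign_carriers(config, metadata)

    n_probe <- nrow(annotation)
    n_sample <- nrow(metadata)
    mu <- matrix(
      ifelse(annotation$is_human == 1L, config$human_log2, config$baseline_log2),
      nrow = n_probe, ncol = n_sample,
      dimnames = list(annotation$probe_id, metadata$sample_id)
    )
    mu_green <- mu
    for (sig in config$signatures) {
      rows <- which(annotation$organism == sig$organism)
      carr <- metadata$sample_id[
        paste(sig$organism, metadata$sample_id, sep = "\r") %in% carrier_keys
      ]
      if (length(carr) > 0) {
        mu_green[rows, carr] <- mu_green[rows, carr] + sig$effect_log2
      }
    }
    noise <- function() {
      matrix(rnorm(n_probe * n_sample, sd = config$noise_sd_log2),
        nrow = n_probe
      )
    }
    green <- 2^(mu_green + noise())
    red <- 2^(mu + noise())

    # outcomes: seeded random split of each case group; controls unknown
    metadata$outcome <- NA_character_
    for (g in setdiff(names(config$group_sizes), "control")) {
      ids <- metadata$sample_id[metadata$group == g]
      k <- round(config$outcome_deceased_frac * length(ids))
      dead <- sample(ids)[seq_len(k)]
      metadata$outcome[metadata$sample_id %in% ids] <- "alive"
      metadata$outcome[metadata$sample_id %in% dead] <- "deceased"
    }
  })

  signals <- tibble(
    probe_id = rep(annotation$probe_id, times = n_sample),
    sample_id = rep(metadata$sample_id, each = n_probe),
    green_signal = as.vector(green),
    red_signal = as.vector(red)
  )

  truth <- tidyr::expand_grid(
    organism = vapply(config$signatures, `[[`, character(1), "organism"),
    sample_id = metadata$sample_id
  )
  if (nrow(truth) > 0) {
    truth$carrier <- as.integer(
      paste(truth$organism, truth$sample_id, sep = "\r") %in% carrier_keys
    )
  } else {
    truth$carrier <- integer()
  }

  structure(
    list(
      signals = signals, annotation = annotation, metadata = metadata,
      truth = truth, config = config
    ),
    class = "pathosig_experiment"
  )
}

#' @export
print.pathosig_experiment <- function(x, ...) {
  cat("<pathosig experiment>\n")
  cat(sprintf(
    "  %d probes x %d samples; %d planted signatures, seed %d\n",
    nrow(x$annotation), nrow(x$metadata), length(x$config$signatures),
    x$config$seed
  ))
  invisible(x)
}

#' Write a simulated experiment to tab-delimited fixture files
#'
#' Emits the four tables of a [simulate_experiment()] result in the package's
#' external formats (`signals.tsv`, `annotation.tsv`, `metadata.tsv`,
#' `truth.tsv`). Re-reading through [read_experiment()] reproduces the
#' experiment losslessly; identical configuration and seed give byte-identical
#' files.
#'
#' @param experiment A `pathosig_experiment`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the file paths written, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "pathosig_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    signals = file.path(dir, "signals.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(experiment$signals, paths[["signals"]])
  readr::write_tsv(experiment$annotation, paths[["annotation"]])
  readr::write_tsv(experiment$metadata, paths[["metadata"]])
  readr::write_tsv(experiment$truth, paths[["truth"]])
  invisible(paths)
}
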