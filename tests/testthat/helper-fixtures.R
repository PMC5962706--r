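# small experiment builders used across test files

tiny_config <- function(..., seed = 1) {
  defaults <- list(
    group_sizes = c(BRER = 6, BRTN = 5, control = 4),
    n_human_probes = 8,
    n_decoy_organisms = 2,
    probes_per_signature = 3,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# hand-built long signal table from g and r matrices
signals_from_matrices <- function(g, r) {
  tibble::tibble(
    probe_id = rep(rownames(g), times = ncol(g)),
    sample_id = rep(colnames(g), each = nrow(g)),
    green_signal = as.vector(g),
    red_signal = as.vector(r)
  )
}

# annotation for a mix of human and one-organism-per-probe microbial probes
annotation_for <- function(human_ids, microbial) {
  # microbial: named character vector probe_id -> organism
  tibble::tibble(
    probe_id = c(human_ids, names(microbial)),
    organism = c(rep("Homo sapiens", length(human_ids)), unname(microbial)),
    organism_class = c(
      rep("human", length(human_ids)),
      rep("bacterium", length(microbial))
    ),
    is_human = c(rep(1L, length(human_ids)), rep(0L, length(microbial)))
  )
}

# normalized object built directly from a probe x sample matrix
normalized_from_matrix <- function(m, organisms = NULL) {
  if (is.null(organisms)) {
    organisms <- stats::setNames(rownames(m), rownames(m))
  }
  structure(
    list(
      normalized = tibble::tibble(
        probe_id = rep(rownames(m), times = ncol(m)),
        sample_id = rep(colnames(m), each = nrow(m)),
        normalized = as.vector(m)
      ),
      scale_factors = tibble::tibble(
        sample_id = colnames(m), scale_factor = 1
      ),
      annotation = tibble::tibble(
        probe_id = rownames(m),
        organism = unname(organisms[rownames(m)]),
        organism_class = "bacterium",
        is_human = 0L
      ),
      mode = "literal"
    ),
    class = "pathosig_normalized"
  )
}

simple_metadata <- function(groups, outcomes = NULL) {
  # groups: named character vector sample_id -> group
  md <- tibble::tibble(sample_id = names(groups), group = unname(groups))
  md$outcome <- if (is.null(outcomes)) NA_character_ else unname(outcomes[md$sample_id])
  md
}
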