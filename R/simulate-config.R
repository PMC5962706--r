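#' Describe a planted microbial signature
#'
#' A planted signature is an organism whose probes receive an elevated
#' green-channel (sample-channel) signal in a configurable fraction of the
#' samples of its target groups. The red channel carries the common human
#' reference hybridization and never receives planted effects.
#'
#' @param organism Organism name (genus or viral family level), a single string.
#' @param organism_class One of `"virus"`, `"bacterium"`, `"fungus"`,
#'   `"parasite"`.
#' @param target_groups Character vector of case-group labels whose samples can
#'   carry the signature.
#' @param effect_log2 Planted green-channel elevation in log2 units; must be
#'   positive. Default 2.
#' @param case_prevalence_frac Fraction of each target group's samples that
#'   carry the elevation, in (0, 1].
#' @param control_prevalence_frac Fraction of control samples that carry it,
#'   in \[0, 1\]. Default 0.
#'
#' @return A `pathosig_signature` list, usable in [sim_config()].
#' @seealso [sim_config()], [simulate_experiment()]
#' @export
#' @examples
#' planted_signature("Polyomaviridae", "virus", c("BRER", "BRHR"),
#'   effect_log2 = 2, case_prevalence_frac = 0.6
#' )
planted_signature <- function(organism, organism_class, target_groups,
                              effect_log2 = 2, case_prevalence_frac = 0.6,
                              control_prevalence_frac = 0) {
  if (!is.character(organism) || length(organism) != 1 || !nzchar(organism)) {
    abort("`organism` must be a single non-empty string.")
  }
  organism_class <- match.arg(organism_class, .organism_classes)
  if (!is.character(target_groups) || length(target_groups) < 1) {
    abort("`target_groups` must name at least one group.")
  }
  assert_scalar_number(effect_log2, "effect_log2")
  if (effect_log2 <= 0) abort("`effect_log2` must be > 0.")
  assert_scalar_number(case_prevalence_frac, "case_prevalence_frac")
  if (case_prevalence_frac <= 0 || case_prevalence_frac > 1) {
    abort("`case_prevalence_frac` must be in (0, 1].")
  }
  assert_scalar_number(control_prevalence_frac, "control_prevalence_frac", 0, 1)
  structure(
    list(
      organism = organism, organism_class = organism_class,
      target_groups = unique(target_groups), effect_log2 = effect_log2,
      case_prevalence_frac = case_prevalence_frac,
      control_prevalence_frac = control_prevalence_frac
    ),
    class = "pathosig_signature"
  )
}

#' Configure a synthetic pan-pathogen microarray experiment
#'
#' Builds the configuration object consumed by [build_probe_library()] and
#' [simulate_experiment()]. Defaults emulate a PathoChip-like breast-cancer
#' screen: four case groups of 50/34/24/40 samples plus 20 controls, human
#' reference probes bright in both channels, microbial probes at a common
#' cross-hybridization background, and planted signatures elevated in the
#' green channel of carrier samples.
#'
#' @param group_sizes Named integer vector of samples per group; must include
#'   a `control` entry with at least 2 samples, all other groups at least 1.
#' @param n_human_probes Number of human reference probes (used for the
#'   per-array scale factor). Default 500.
#' @param signatures List of [planted_signature()] objects. Default none.
#' @param probes_per_signature Probes representing each planted or decoy
#'   organism. Default 5.
#' @param n_decoy_organisms Organisms with probes on the array but no planted
#'   effect, so specificity is measurable. Default 20.
#' @param baseline_log2 Background microbial log2 signal mean (both channels).
#'   Default 6.
#' @param noise_sd_log2 Per-channel Gaussian noise SD on the log2 scale
#'   (log-normal raw signals). Default 0.3, approximately a 23% coefficient of
#'   variation — typical probe-level replicate noise for glass-slide arrays.
#' @param human_log2 Human-probe log2 signal mean, both channels. Default 10.
#' @param outcome_deceased_frac Fraction of case samples assigned the
#'   `deceased` outcome (at random, seeded); controls get `NA`. Default 0.3.
#' @param seed Integer seed; the same configuration and seed give
#'   byte-identical simulated tables.
#'
#' @return A validated `pathosig_sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(
#'   signatures = list(
#'     planted_signature("Mycoplasma", "bacterium", "BRTN",
#'       case_prevalence_frac = 0.6
#'     )
#'   ),
#'   seed = 1
#' )
#' cfg$group_sizes
sim_config <- function(group_sizes = c(
                         BRER = 50, BRHR = 34, BRTP = 24, BRTN = 40,
                         control = 20
                       ),
                       n_human_probes = 500,
                       signatures = list(),
                       probes_per_signature = 5,
                       n_decoy_organisms = 20,
                       baseline_log2 = 6,
                       noise_sd_log2 = 0.3,
                       human_log2 = 10,
                       outcome_deceased_frac = 0.3,
                       seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    abort("`group_sizes` must be a fully named vector.")
  }
  if (anyDuplicated(names(group_sizes))) {
    abort("`group_sizes` has duplicated group labels.")
  }
  if (!"control" %in% names(group_sizes)) {
    abort("`group_sizes` must include a `control` group.")
  }
  group_sizes <- vapply(group_sizes, as.integer, integer(1))
  if (group_sizes[["control"]] < 2) {
    abort("The control group needs at least 2 samples.")
  }
  if (any(group_sizes < 1)) abort("All group sizes must be >= 1.")
  assert_scalar_number(n_human_probes, "n_human_probes", lower = 1)
  assert_scalar_number(probes_per_signature, "probes_per_signature", lower = 1)
  assert_scalar_number(n_decoy_organisms, "n_decoy_organisms", lower = 0)
  assert_scalar_number(baseline_log2, "baseline_log2")
  assert_scalar_number(noise_sd_log2, "noise_sd_log2", lower = 0)
  assert_scalar_number(human_log2, "human_log2")
  assert_scalar_number(outcome_deceased_frac, "outcome_deceased_frac", 0, 1)
  if (!is.list(signatures) ||
    !all(vapply(signatures, inherits, logical(1), "pathosig_signature"))) {
    abort("`signatures` must be a list of planted_signature() objects.")
  }
  orgs <- vapply(signatures, `[[`, character(1), "organism")
  if (anyDuplicated(orgs)) {
    abort(sprintf(
      "Duplicate organism name in `signatures`: %s.",
      paste(unique(orgs[duplicated(orgs)]), collapse = ", ")
    ))
  }
  case_groups <- setdiff(names(group_sizes), "control")
  for (sig in signatures) {
    bad <- setdiff(sig$target_groups, case_groups)
    if (length(bad) > 0) {
      abort(sprintf(
        "Signature %s targets unknown group%s: %s.",
        sig$organism, if (length(bad) > 1) "s" else "",
        paste(bad, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      group_sizes = group_sizes,
      n_human_probes = as.integer(n_human_probes),
      signatures = signatures,
      probes_per_signature = as.integer(probes_per_signature),
      n_decoy_organisms = as.integer(n_decoy_organisms),
      baseline_log2 = baseline_log2,
      noise_sd_log2 = noise_sd_log2,
      human_log2 = human_log2,
      outcome_deceased_frac = outcome_deceased_frac,
      seed = as.integer(seed)
    ),
    class = "pathosig_sim_config"
  )
}

#' @export
print.pathosig_sim_config <- function(x, ...) {
  cat("<pathosig simulation config>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
    collapse = ", "
  ), "\n")
  cat(sprintf(
    "  probes: %d human, %d planted organisms x %d, %d decoys x %d\n",
    x$n_human_probes, length(x$signatures), x$probes_per_signature,
    x$n_decoy_organisms, x$probes_per_signature
  ))
  cat(sprintf(
    "  signal: baseline %.3g, human %.3g, noise sd %.3g (log2); seed %d\n",
    x$baseline_log2, x$human_log2, x$noise_sd_log2, x$seed
  ))
  invisible(x)
}
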