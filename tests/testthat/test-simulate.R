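test_that("probe library has the configured composition", {
  cfg <- sim_config(
    n_human_probes = 100, probes_per_signature = 5, n_decoy_organisms = 0,
    signatures = list(
      planted_signature("OrgA", "virus", "BRER"),
      planted_signature("OrgB", "bacterium", "BRTN")
    )
  )
  lib <- build_probe_library(cfg)
  expect_equal(nrow(lib), 110)
  expect_equal(sum(lib$is_human), 100)
  expect_equal(sum(lib$organism == "OrgA"), 5)
  expect_false(anyDuplicated(lib$probe_id) > 0)

  # no signatures, decoys only
  lib2 <- build_probe_library(sim_config(
    n_human_probes = 10, n_decoy_organisms = 3, probes_per_signature = 5
  ))
  expect_equal(nrow(lib2), 25)
  expect_equal(sum(lib2$is_human == 0), 15)
})

test_that("duplicate organism names are rejected with the duplicate named", {
  expect_error(
    sim_config(signatures = list(
      planted_signature("Same", "virus", "BRER"),
      planted_signature("Same", "fungus", "BRTN")
    )),
    "Same"
  )
  # planted name clashing with a decoy name
  cfg <- sim_config(
    signatures = list(planted_signature("Decoy_01", "virus", "BRER")),
    n_decoy_organisms = 2
  )
  expect_error(build_probe_library(cfg), "Decoy_01")
})

test_that("signature targeting an unknown group errors naming the label", {
  expect_error(
    sim_config(signatures = list(
      planted_signature("OrgA", "virus", "NOPE")
    )),
    "NOPE"
  )
})

test_that("config invariants are enforced", {
  expect_error(sim_config(group_sizes = c(BRER = 5)), "control")
  expect_error(sim_config(group_sizes = c(BRER = 5, control = 1)), "at least 2")
  expect_error(sim_config(noise_sd_log2 = -0.1), "noise_sd_log2")
  expect_error(planted_signature("A", "virus", "BRER", effect_log2 = 0), "> 0")
  expect_error(
    planted_signature("A", "virus", "BRER", case_prevalence_frac = 0),
    "case_prevalence_frac"
  )
})

test_that("noiseless null experiment normalizes to exactly zero", {
  cfg <- tiny_config(noise_sd_log2 = 0)
  e <- simulate_experiment(cfg)
  n <- normalize_signals(e$signals, e$annotation)
  expect_equal(n$scale_factors$scale_factor, rep(1, nrow(e$metadata)))
  expect_equal(n$normalized$normalized, rep(0, nrow(n$normalized)))
})

test_that("noiseless planted effect appears as an exact green/red log2 gap", {
  cfg <- tiny_config(
    noise_sd_log2 = 0,
    signatures = list(planted_signature("OrgA", "virus", "BRER",
      effect_log2 = 2, case_prevalence_frac = 1
    ))
  )
  e <- simulate_experiment(cfg)
  carriers <- e$truth$sample_id[e$truth$carrier == 1]
  expect_setequal(carriers, e$metadata$sample_id[e$metadata$group == "BRER"])
  sig <- e$signals |>
    dplyr::inner_join(e$annotation, by = "probe_id") |>
    dplyr::filter(.data$organism == "OrgA")
  gap <- log2(sig$green_signal) - log2(sig$red_signal)
  expect_equal(gap[sig$sample_id %in% carriers],
    rep(2, sum(sig$sample_id %in% carriers)),
    tolerance = 1e-12
  )
  expect_equal(gap[!sig$sample_id %in% carriers],
    rep(0, sum(!sig$sample_id %in% carriers)),
    tolerance = 1e-12
  )
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  cfg <- tiny_config(noise_sd_log2 = 0.5, seed = 1)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$signals, e2$signals)
  expect_identical(e1$metadata, e2$metadata)
  e3 <- simulate_experiment(tiny_config(noise_sd_log2 = 0.5, seed = 2))
  expect_false(identical(e1$signals$green_signal, e3$signals$green_signal))
})

test_that("carrier counts are exactly round(prevalence * group size)", {
  for (frac in c(0.25, 0.5, 0.6, 1)) {
    cfg <- tiny_config(
      signatures = list(
        planted_signature("OrgA", "virus", c("BRER", "BRTN"),
          case_prevalence_frac = frac, control_prevalence_frac = 0.5
        )
      ),
      seed = 42
    )
    e <- simulate_experiment(cfg)
    carr <- e$truth |>
      dplyr::inner_join(e$metadata, by = "sample_id") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = sum(.data$carrier))
    expect_equal(carr$n[carr$group == "BRER"], round(frac * 6))
    expect_equal(carr$n[carr$group == "BRTN"], round(frac * 5))
    expect_equal(carr$n[carr$group == "control"], round(0.5 * 4))
  }
})

test_that("null green-red log2 differences are centred at zero (3 SE at n = 200)", {
  cfg <- sim_config(
    group_sizes = c(BRER = 100, control = 100),
    n_human_probes = 10, n_decoy_organisms = 4, probes_per_signature = 5,
    noise_sd_log2 = 0.4, seed = 99
  )
  e <- simulate_experiment(cfg)
  diffs <- e$signals |>
    dplyr::inner_join(e$annotation, by = "probe_id") |>
    dplyr::filter(.data$is_human == 0L) |>
    dplyr::mutate(d = log2(.data$green_signal) - log2(.data$red_signal)) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(m = mean(.data$d), se = stats::sd(.data$d) / sqrt(dplyr::n()))
  expect_true(all(abs(diffs$m) <= 3 * diffs$se))
})
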