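test_that("probe test reproduces the Welch t-test", {
  m <- rbind(
    P1 = c(5, 6, 7, 1, 2, 3),
    P2 = c(1, 2, 3, 1, 2, 3)
  )
  colnames(m) <- c(paste0("c", 1:3), paste0("n", 1:3))
  norm <- normalized_from_matrix(m)
  md <- simple_metadata(setNames(
    c(rep("case", 3), rep("control", 3)), colnames(m)
  ))
  out <- test_probes(norm, md, "case")
  # case [5,6,7] vs control [1,2,3]: se = sqrt(2/3), t = 4/sqrt(2/3)
  expect_equal(out$t[1], 4 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(out$df[1], 4, tolerance = 1e-10)
  orc <- oracle_t(c(5, 6, 7), c(1, 2, 3), "greater")
  expect_equal(out$p[1], orc$p, tolerance = 1e-10)
  expect_lt(abs(out$p[1] - 0.004), 5e-4)
  # identical groups: t = 0, one-sided p = 0.5
  expect_equal(out$t[2], 0)
  expect_equal(out$p[2], 0.5)
  expect_equal(out$log2fc, c(4, 0))
})

test_that("control-exceeding probes get t < 0 and p > 0.5", {
  m <- rbind(P1 = c(1, 2, 3, 5, 6, 7))
  colnames(m) <- c(paste0("c", 1:3), paste0("n", 1:3))
  out <- test_probes(
    normalized_from_matrix(m),
    simple_metadata(setNames(c(rep("case", 3), rep("control", 3)), colnames(m))),
    "case"
  )
  expect_lt(out$t, 0)
  expect_gt(out$p, 0.5)
})

test_that("row t-tests agree with stats::t.test on random inputs", {
  set.seed(123)
  for (rep in 1:100) {
    n1 <- sample(2:12, 1)
    n2 <- sample(2:12, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, sd = runif(1, 0.3, 3))
    m <- matrix(c(x, y), 1, dimnames = list("P1", paste0("s", seq_len(n1 + n2))))
    md <- simple_metadata(setNames(
      c(rep("case", n1), rep("control", n2)), colnames(m)
    ))
    norm <- normalized_from_matrix(m)
    for (alt in c("greater", "less", "two.sided")) {
      for (ve in c(FALSE, TRUE)) {
        got <- test_probes(norm, md, "case", alternative = alt, var_equal = ve)
        orc <- oracle_t(x, y, alt, var_equal = ve)
        expect_equal(got$t, orc$t, tolerance = 1e-10)
        expect_equal(got$df, orc$df, tolerance = 1e-10)
        expect_equal(got$p, orc$p, tolerance = 1e-10)
      }
    }
  }
})

test_that("degenerate constant probes follow the stated conventions", {
  m <- rbind(
    flat = c(2, 2, 2, 2, 2, 2), # constant, equal means
    apart = c(3, 3, 3, 1, 1, 1) # constant, different means
  )
  colnames(m) <- paste0("s", 1:6)
  md <- simple_metadata(setNames(c(rep("case", 3), rep("control", 3)), colnames(m)))
  expect_warning(
    out <- test_probes(normalized_from_matrix(m), md, "case"),
    "constant within both groups"
  )
  expect_equal(out$t[1], 0)
  expect_equal(out$p[1], 0.5)
  expect_equal(out$t[2], Inf)
  expect_equal(out$p[2], 0)
})

test_that("groups of fewer than 2 samples are rejected", {
  m <- matrix(1:4, 1, dimnames = list("P1", paste0("s", 1:4)))
  md <- simple_metadata(setNames(c("case", rep("control", 3)), colnames(m)))
  expect_error(
    test_probes(normalized_from_matrix(m), md, "case"),
    ">= 2 samples"
  )
})

test_that("BH adjustment matches hand step-up computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("BH adjustment agrees with the brute-force step-up oracle", {
  set.seed(11)
  for (rep in 1:50) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("presence calls use the control-mean baseline and delta margin", {
  m <- rbind(P1 = c(2.0, 0.9, 1.0, 0, 0)) # controls mean 1/3
  colnames(m) <- c("a", "b", "c", "d", "e")
  md <- simple_metadata(setNames(c("case", "case", rep("control", 3)), colnames(m)))
  norm <- normalized_from_matrix(m)
  pres <- probe_presence(norm, md, presence_delta = 1)
  det <- setNames(pres$detected, pres$sample_id)
  expect_true(det[["a"]]) # 2 - 1/3 >= 1
  expect_false(det[["b"]]) # 0.9 - 1/3 < 1
  expect_false(det[["c"]]) # control called against the same baseline
  # boundary: delta = 0 means detected iff N >= control mean
  pres0 <- probe_presence(norm, md, presence_delta = 0)
  det0 <- setNames(pres0$detected, pres0$sample_id)
  expect_equal(unname(det0[c("a", "b", "c", "d", "e")]),
    c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("prevalence rules implement union and max-over-probes", {
  # probe A detected in {s1, s2}, probe B in {s2, s3}, group of 4
  pres <- tibble::tibble(
    probe_id = rep(c("A", "B"), each = 4),
    sample_id = rep(paste0("s", 1:4), 2),
    detected = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  ann <- annotation_for(character(), c(A = "Org1", B = "Org1"))
  md <- simple_metadata(setNames(rep("case", 4), paste0("s", 1:4)))
  u <- signature_prevalence(pres, ann, md, rule = "union")
  expect_equal(u$prevalence_pct, 75) # |{s1,s2,s3}| / 4
  mx <- signature_prevalence(pres, ann, md, rule = "max")
  expect_equal(mx$prevalence_pct, 50) # max(2, 2) / 4

  # no detections at all -> 0% under both rules
  pres$detected <- FALSE
  expect_equal(signature_prevalence(pres, ann, md, rule = "union")$prevalence_pct, 0)
  expect_equal(signature_prevalence(pres, ann, md, rule = "max")$prevalence_pct, 0)
})

test_that("prevalence agrees with the set-operation oracle on random matrices", {
  set.seed(21)
  for (rep in 1:40) {
    n_probe <- sample(2:10, 1)
    n_sample <- sample(2:12, 1)
    det <- matrix(runif(n_probe * n_sample) < 0.4, n_probe, n_sample,
      dimnames = list(paste0("P", 1:n_probe), paste0("s", 1:n_sample))
    )
    orgs <- sample(paste0("Org", 1:3), n_probe, replace = TRUE)
    pres <- tibble::tibble(
      probe_id = rep(rownames(det), times = n_sample),
      sample_id = rep(colnames(det), each = n_probe),
      detected = as.vector(det)
    )
    ann <- annotation_for(character(), setNames(orgs, rownames(det)))
    md <- simple_metadata(setNames(rep("g", n_sample), colnames(det)))
    for (rule in c("union", "max")) {
      got <- signature_prevalence(pres, ann, md, rule = rule)
      orc <- oracle_prevalence(det, orgs, rule)
      for (o in names(orc)) {
        expect_equal(got$prevalence_pct[got$organism == o], orc[[o]])
      }
    }
  }
})

test_that("joint filters apply fold change, adjusted p and prevalence bounds", {
  ann <- annotation_for(character(), c(A1 = "OrgA", B1 = "OrgB", C1 = "OrgC"))
  stats <- tibble::tibble(
    probe_id = c("A1", "B1", "C1"),
    adj_p = c(0.005, 0.001, 0.004),
    log2fc = c(1.2, 0.9, 1.5),
    mean_case = c(2, 1, 2), mean_control = c(0.8, 0.1, 0.5)
  )
  prev <- tibble::tibble(
    organism = rep(c("OrgA", "OrgB", "OrgC"), each = 2),
    group = rep(c("case", "control"), 3),
    n_detected = c(9, 2, 9, 2, 9, 3),
    n_samples = c(20, 10, 20, 10, 20, 10),
    prevalence_pct = c(45, 20, 45, 20, 45, 30)
  )
  out <- filter_signatures(stats, prev, ann, "case", "control")
  # OrgA passes everything; OrgB fails probe fold change; OrgC fails control prevalence
  expect_equal(out$organism, "OrgA")
  expect_equal(out$case_prevalence_pct, 45)
  expect_equal(out$significant_probe_ids, "A1")
})

test_that("relaxing thresholds never shrinks the reported set", {
  cfg <- tiny_config(
    group_sizes = c(BRER = 12, control = 8),
    signatures = list(
      planted_signature("OrgA", "virus", "BRER", effect_log2 = 1.5),
      planted_signature("OrgB", "bacterium", "BRER", effect_log2 = 0.8)
    ),
    n_decoy_organisms = 5, noise_sd_log2 = 0.4, seed = 17
  )
  e <- simulate_experiment(cfg)
  n <- normalize_signals(e$signals, e$annotation)
  strict <- detect_signatures(n, e$metadata, "BRER",
    thresholds = detection_thresholds(min_log2fc = 1, max_adj_p = 0.01)
  )
  relaxed_p <- detect_signatures(n, e$metadata, "BRER",
    thresholds = detection_thresholds(min_log2fc = 1, max_adj_p = 0.05)
  )
  relaxed_fc <- detect_signatures(n, e$metadata, "BRER",
    thresholds = detection_thresholds(min_log2fc = 0.5, max_adj_p = 0.01)
  )
  expect_true(all(strict$signatures$organism %in% relaxed_p$signatures$organism))
  expect_true(all(strict$signatures$organism %in% relaxed_fc$signatures$organism))
})

test_that("a noiseless null experiment reports no signatures", {
  cfg <- tiny_config(noise_sd_log2 = 0, n_decoy_organisms = 6)
  e <- simulate_experiment(cfg)
  n <- normalize_signals(e$signals, e$annotation)
  for (g in c("BRER", "BRTN")) {
    det <- detect_signatures(n, e$metadata, g)
    expect_equal(nrow(det$signatures), 0)
  }
})

test_that("detection recovers a strongly planted signature end to end", {
  cfg <- tiny_config(
    group_sizes = c(BRER = 24, control = 12),
    n_human_probes = 200, probes_per_signature = 5,
    signatures = list(planted_signature("OrgA", "virus", "BRER",
      effect_log2 = 3, case_prevalence_frac = 0.8
    )),
    n_decoy_organisms = 10, seed = 4
  )
  e <- simulate_experiment(cfg)
  n <- normalize_signals(e$signals, e$annotation)
  det <- detect_signatures(n, e$metadata, "BRER")
  expect_true("OrgA" %in% det$signatures$organism)
  g <- glance(det)
  expect_equal(g$n_signatures, nrow(det$signatures))
  expect_equal(nrow(tidy(det)), nrow(det$probe_stats))
})
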