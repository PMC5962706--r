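test_that("scale factor is the ratio of summed human-probe signals", {
  g <- matrix(c(100, 300, 7), 3, 1, dimnames = list(c("H1", "H2", "M1"), "s1"))
  r <- matrix(c(200, 200, 7), 3, 1, dimnames = list(c("H1", "H2", "M1"), "s1"))
  ann <- annotation_for(c("H1", "H2"), c(M1 = "OrgA"))
  sf <- scale_factors(signals_from_matrices(g, r), ann)
  expect_equal(sf$scale_factor, 1.0) # 400 / 400

  g2 <- matrix(c(10, 20, 30, 5), 4, 1,
    dimnames = list(c("H1", "H2", "H3", "M1"), "s1")
  )
  r2 <- matrix(c(10, 10, 10, 5), 4, 1,
    dimnames = list(c("H1", "H2", "H3", "M1"), "s1")
  )
  ann2 <- annotation_for(c("H1", "H2", "H3"), c(M1 = "OrgA"))
  expect_equal(
    scale_factors(signals_from_matrices(g2, r2), ann2)$scale_factor,
    2.0 # 60 / 30
  )
})

test_that("scale factor requires human probes", {
  g <- matrix(4, 1, 1, dimnames = list("M1", "s1"))
  ann <- annotation_for(character(), c(M1 = "OrgA"))
  expect_error(
    scale_factors(signals_from_matrices(g, g), ann),
    "No human probes"
  )
})

test_that("literal normalization applies log2 g - sf * log2 r", {
  # one human probe pins the scale factor; sf = 1 here
  g <- matrix(c(16, 4), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
  r <- matrix(c(16, 2), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
  ann <- annotation_for("H1", c(M1 = "OrgA"))
  n <- normalize_signals(signals_from_matrices(g, r), ann)
  expect_equal(n$normalized$normalized, 1.0) # 2 - 1*1

  # sf = 2: human g = 32, r = 16; microbial g = 8, r = 4 -> 3 - 2*2 = -1
  g2 <- matrix(c(32, 8), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
  r2 <- matrix(c(16, 4), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
  n2 <- normalize_signals(signals_from_matrices(g2, r2), ann)
  expect_equal(n2$scale_factors$scale_factor, 2.0)
  expect_equal(n2$normalized$normalized, -1.0)
  # ratio mode on the same input: log2(8 / (2*4)) = 0
  n2r <- normalize_signals(signals_from_matrices(g2, r2), ann, mode = "ratio")
  expect_equal(n2r$normalized$normalized, 0.0)

  # g = r = 1 gives N = 0 under any sf
  g3 <- matrix(c(32, 1), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
  r3 <- matrix(c(16, 1), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
  expect_equal(
    normalize_signals(signals_from_matrices(g3, r3), ann)$normalized$normalized,
    0.0
  )
})

test_that("both modes agree exactly when sf = 1", {
  set.seed(31)
  probes <- c("H1", "H2", paste0("M", 1:10))
  samples <- paste0("s", 1:6)
  g <- matrix(2^runif(length(probes) * length(samples), 2, 10),
    length(probes), length(samples), dimnames = list(probes, samples)
  )
  r <- g
  r[3:12, ] <- 2^runif(10 * length(samples), 2, 10)
  # human probes identical in both channels -> sf exactly 1 per sample
  ann <- annotation_for(c("H1", "H2"), setNames(paste0("Org", 1:10), paste0("M", 1:10)))
  sig <- signals_from_matrices(g, r)
  lit <- normalize_signals(sig, ann, mode = "literal")
  rat <- normalize_signals(sig, ann, mode = "ratio")
  expect_equal(lit$scale_factors$scale_factor, rep(1, 6))
  expect_equal(lit$normalized$normalized, rat$normalized$normalized,
    tolerance = 1e-12
  )
})

test_that("normalized signal is monotone: increasing in g, decreasing in r", {
  ann <- annotation_for("H1", c(M1 = "OrgA"))
  base <- function(g, r) {
    gm <- matrix(c(16, g), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
    rm_ <- matrix(c(8, r), 2, 1, dimnames = list(c("H1", "M1"), "s1"))
    normalize_signals(signals_from_matrices(gm, rm_), ann)$normalized$normalized
  }
  gs <- c(2, 4, 8, 16, 64)
  expect_true(all(diff(vapply(gs, base, numeric(1), r = 4)) > 0))
  expect_true(all(diff(vapply(gs, function(r) base(8, r), numeric(1))) < 0))
})

test_that("doubling a sample's human green signals doubles its scale factor", {
  cfg <- tiny_config(noise_sd_log2 = 0.2, seed = 8)
  e <- simulate_experiment(cfg)
  sf1 <- scale_factors(e$signals, e$annotation)
  boosted <- e$signals
  s <- e$metadata$sample_id[1]
  human <- e$annotation$probe_id[e$annotation$is_human == 1L]
  idx <- boosted$sample_id == s & boosted$probe_id %in% human
  boosted$green_signal[idx] <- boosted$green_signal[idx] * 2
  sf2 <- scale_factors(boosted, e$annotation)
  expect_equal(
    sf2$scale_factor[sf2$sample_id == s],
    2 * sf1$scale_factor[sf1$sample_id == s],
    tolerance = 1e-12
  )
  expect_equal(
    sf2$scale_factor[sf2$sample_id != s],
    sf1$scale_factor[sf1$sample_id != s]
  )
})

test_that("normalization matches an element-wise reimplementation on random data", {
  set.seed(77)
  for (rep in 1:20) {
    n_h <- sample(2:5, 1)
    n_m <- sample(3:8, 1)
    n_s <- sample(2:5, 1)
    probes <- c(paste0("H", seq_len(n_h)), paste0("M", seq_len(n_m)))
    samples <- paste0("s", seq_len(n_s))
    g <- matrix(runif(length(probes) * n_s, 1, 1000), length(probes), n_s,
      dimnames = list(probes, samples)
    )
    r <- matrix(runif(length(probes) * n_s, 1, 1000), length(probes), n_s,
      dimnames = list(probes, samples)
    )
    ann <- annotation_for(
      paste0("H", seq_len(n_h)),
      setNames(paste0("Org", seq_len(n_m)), paste0("M", seq_len(n_m)))
    )
    out <- normalize_signals(signals_from_matrices(g, r), ann)
    for (s in samples) {
      sf <- sum(g[seq_len(n_h), s]) / sum(r[seq_len(n_h), s])
      for (p in paste0("M", seq_len(n_m))) {
        expected <- log2(g[p, s]) - sf * log2(r[p, s])
        got <- out$normalized$normalized[
          out$normalized$probe_id == p & out$normalized$sample_id == s
        ]
        expect_equal(got, expected, tolerance = 1e-10)
      }
    }
  }
})
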