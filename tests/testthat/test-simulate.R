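test_that("zero-intensity and zero-rate simulations are all-zero", {
  tr <- simulate_dl_trace(A = 0, B = 10, C = 0.5, background_rate = 0,
                          duration = 50, seed = 1)
  expect_true(all(tr$counts == 0))
  sp <- simulate_spe_trace(rate = 0, background_rate = 0, n_bins = 100,
                           seed = 1)
  expect_true(all(sp$counts == 0))
})

test_that("DL bin-0 counts average to the closed-form bin integral", {
  # oracle: quadrature of the intensity over [0, 1)
  expected <- oracle_bin_count(0, 1, 100, 10, 0.5)
  n_seeds <- 10000
  first_bins <- vapply(seq_len(n_seeds), function(s)
    simulate_dl_trace(100, 10, 0.5, background_rate = 0, duration = 1,
                      seed = s)$counts[1], numeric(1))
  mc_se <- stats::sd(first_bins) / sqrt(n_seeds)
  expect_lt(abs(mean(first_bins) - expected), 3 * mc_se)
})

test_that("SPE traces have the protocol length and Poisson moments", {
  sp <- simulate_spe_trace(rate = 100, background_rate = 30, seed = 3)
  expect_length(sp$counts, 600)           # ten minutes of 1-s bins
  expect_equal(sp$duration, 600)
  expect_lt(abs(mean(sp$counts) - 130), 3 * sqrt(130 / 600))
  # mean and variance agree (Poisson) within Monte-Carlo error at 10,000 bins
  big <- simulate_spe_trace(rate = 50, background_rate = 0, n_bins = 10000,
                            seed = 4)
  m <- mean(big$counts); v <- stats::var(big$counts)
  sd_diff <- sqrt(2 * 50^2 / 10000 + 50 / 10000)  # sd of (var - mean), approx
  expect_lt(abs(v - m), 4 * sd_diff)
})

test_that("summed DL counts converge to the closed-form total intensity", {
  A <- 200; B <- 8; C <- 0.6; n_seeds <- 200
  expected_total <- A * B * (1 / tanh(C) - 1 / tanh(300 / B + C))
  totals <- vapply(seq_len(n_seeds), function(s)
    sum(simulate_dl_trace(A, B, C, 0, duration = 300, seed = s)$counts),
    numeric(1))
  expect_lt(abs(mean(totals) - expected_total),
            3 * stats::sd(totals) / sqrt(n_seeds))
})

test_that("simulation is bit-identical under a fixed seed", {
  t1 <- simulate_dl_trace(100, 10, 0.5, 30, seed = 11, sample_id = "s")
  t2 <- simulate_dl_trace(100, 10, 0.5, 30, seed = 11, sample_id = "s")
  expect_identical(t1, t2)
  cfg <- sim_config(n_per_group = 2, groups = c("control", "drought"))
  a1 <- simulate_assay_tables(cfg, seed = 5)
  a2 <- simulate_assay_tables(cfg, seed = 5)
  expect_identical(a1, a2)
  s1 <- simulate_study(cfg, seed = 5)
  s2 <- simulate_study(cfg, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(simulate_dl_trace(100, 10, 0.5, 30, seed = 12),
                         t1))
})

test_that("parameter domains are enforced by the simulators", {
  expect_error(simulate_dl_trace(100, -1, 0.5), "characteristic time")
  expect_error(simulate_dl_trace(100, 10, 0), "phase factor")
  expect_error(simulate_dl_trace(100, 10, 0.5, background_rate = -1))
  expect_error(simulate_spe_trace(rate = -5), ">= 0")
  expect_error(simulate_spe_trace(rate = 1, n_bins = 0), "n_bins")
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  et <- default_effect_table(c("control", "drought"))
  expect_error(sim_config(groups = c("control", "salt_low"),
                          effect_table = et), "do not match")
})

test_that("assay tables carry the configured group effects", {
  cfg <- sim_config()
  at <- simulate_assay_tables(cfg, seed = 2)
  # high-salinity indirubin multiplier 0.18 on a 0.1% control content
  ind <- tapply(at$compounds$indirubin, at$compounds$group, mean)
  expect_equal(unname(ind["control"]), 0.1, tolerance = 0.1)
  expect_equal(unname(ind["salt_high"]), 0.018, tolerance = 0.15)
  expect_lt(ind["salt_high"], 0.02)   # below the pharmacopoeial standard
  # conductivities are ordered E1 <= E2 <= E3
  expect_true(all(at$conductivity$E1 <= at$conductivity$E2))
  expect_true(all(at$conductivity$E2 <= at$conductivity$E3))
  # MIC plates live on the printed 1024..8 ladder
  p <- at$mic_plates[[1]]
  expect_identical(p$concentrations, c(1024, 512, 256, 128, 64, 32, 16, 8))
})

test_that("a two-step MIC ladder shift moves 128 to 512", {
  et <- default_effect_table()
  expect_identical(128 * 2^et$mic_shift_ecoli[et$group == "salt_high"], 512)
  # and the simulated plates for that group are predominantly called at 512
  cfg <- sim_config()
  at <- simulate_assay_tables(cfg, seed = 3)
  keys <- grep("^salt_high_ecoli_", names(at$mic_plates), value = TRUE)
  mics <- vapply(at$mic_plates[keys], function(p) call_mic(p)$mic, numeric(1))
  expect_identical(summarize_mic(mics)$consensus, 512)
})

test_that("feature-table generator plants effects only through I0 and CPS", {
  ft <- simulate_feature_table(n_per_group = 200,
                               groups = c("control", "stress"), seed = 9)
  by_group <- function(col) tapply(ft[[col]], ft$group, mean)
  for (col in c("A", "B", "C", "Iw", "T")) {
    m <- by_group(col)
    expect_equal(unname(m["stress"] / m["control"]), 1, tolerance = 0.05)
  }
  for (col in c("I0", "CPS")) {
    m <- by_group(col)
    expect_equal(unname(m["stress"] / m["control"]), 0.5, tolerance = 0.05)
  }
})
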