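mpc_matrix_of <- function(record, n_samples = 4096) {
  win <- segment_windows(record, n_samples)
  lapply(win$data, function(x) sync_matrix(instantaneous_phase(x)))
}

test_that("identical config and seed reproduce the recording bit for bit", {
  cfg <- oscillator_config(n_channels = 4, duration = 60, seed = 123)
  r1 <- generate_record(cfg)
  r2 <- generate_record(cfg)
  expect_identical(r1$record$samples, r2$record$samples)
  expect_identical(r1$record$segments, r2$record$segments)
  expect_identical(r1$truth$expected_assortativity_day,
                   r2$truth$expected_assortativity_day)
})

test_that("uncoupled noiseless oscillators at distinct frequencies stay incoherent", {
  zero <- matrix(0, 4, 4)
  expect_warning(
    cfg <- oscillator_config(
      n_channels = 4, duration = 2 * 4096 / 200, seed = 5,
      base_frequency = c(8, 12), noise_sd = 0,
      coupling_strength_high = 0, coupling_strength_low = 0,
      day_graph = zero, night_graph = zero
    ),
    "no links"
  )
  sim <- generate_record(cfg)
  for (R in mpc_matrix_of(sim$record)) {
    off <- R[lower.tri(R)]
    expect_true(all(off < 0.2))
  }
  # channels are pure sinusoids: unwrapped phase advances at the base rate
  x <- sim$record$samples[1:4096, 1]
  ph <- instantaneous_phase(x)
  slope <- mean(diff(ph[500:3500]) %% (2 * pi))
  expect_equal(slope, 2 * pi * 8 / 200, tolerance = 0.01)
})

test_that("block-coupled oscillators are more coherent within than between blocks", {
  blocks <- coupling_topology("modular", 9, block_sizes = c(3, 3, 3))
  cfg <- oscillator_config(
    n_channels = 9, duration = 5 * 4096 / 200, seed = 11,
    base_frequency = c(9, 11), noise_sd = 0,
    coupling_strength_high = 30, coupling_strength_low = 30,
    day_graph = blocks, night_graph = blocks
  )
  sim <- generate_record(cfg)
  within <- blocks[lower.tri(blocks)] == 1
  for (R in mpc_matrix_of(sim$record)) {
    vals <- R[lower.tri(R)]
    expect_gt(min(vals[within]), max(vals[!within]))
  }
})

test_that("pairwise coherence is non-decreasing in coupling strength", {
  pair <- matrix(0, 3, 3)
  pair[1, 2] <- pair[2, 1] <- 1
  avg_mpc <- sapply(c(0, 3, 10, 30), function(K) {
    cfg <- oscillator_config(
      n_channels = 3, duration = 6 * 4096 / 200, seed = 21,
      base_frequency = c(9, 10, 11), noise_sd = 0.1,
      coupling_strength_high = K, coupling_strength_low = K,
      day_graph = pair, night_graph = pair
    )
    mean(sapply(mpc_matrix_of(generate_record(cfg)$record),
                function(R) R[1, 2]))
  })
  expect_true(all(diff(avg_mpc) >= 0))
  expect_gt(avg_mpc[4], avg_mpc[1] + 0.3) # strong coupling actually locks
})

test_that("gaps delete samples and are recorded; annotations propagate", {
  cfg <- oscillator_config(
    n_channels = 4, duration = 120, seed = 2,
    gap_intervals = data.frame(onset = 40, end = 50),
    seizure_events = data.frame(onset = 70, end = 75)
  )
  rec <- generate_record(cfg)$record
  expect_equal(nrow(rec$samples), (120 - 10) * 200)
  expect_equal(nrow(rec$segments), 2)
  expect_equal(rec$segments$onset, c(0, 50))
  expect_equal(rec$gaps$onset, 40)
  expect_equal(rec$annotations$end, 75)
})

test_that("configuration invariants are enforced", {
  expect_error(oscillator_config(n_channels = 2, duration = 60), "at least 3")
  expect_error(oscillator_config(n_channels = 4, duration = 10),
               "shorter than one")
  expect_error(
    oscillator_config(
      n_channels = 4, duration = 60,
      seizure_events = data.frame(onset = c(10, 15), end = c(20, 25))
    ),
    "non-overlapping"
  )
  expect_error(
    oscillator_config(n_channels = 4, duration = 60,
                      gap_intervals = data.frame(onset = 50, end = 70)),
    "within"
  )
})

test_that("coupling cross-fade is periodic with the modulation period", {
  sim <- small_sim()
  truth <- sim$truth
  t <- c(0, 3600, 7200)
  expect_equal(truth$coupling_graph_at(t[1]),
               truth$coupling_graph_at(t[1] + 24 * 3600))
  expect_equal(truth$day_weight_at(t), truth$day_weight_at(t + 24 * 3600))
  # start 21:00, peak 14:00: day weight must decrease into the night
  expect_lt(truth$day_weight_at(3 * 3600), truth$day_weight_at(0))
})
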