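make_record <- function(samples, fs = 200, gaps = NULL,
                        start = "2024-01-01 00:00:00") {
  multichannel_record(samples, fs, start, gaps = gaps)
}

test_that("bandpass keeps the passband and attenuates the stopband", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  inner <- (fs + 1):(9 * fs) # discard 1 s at each edge
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(make_record(cbind(x10)))$samples[, 1]
  expect_equal(sqrt(mean(y10[inner]^2)), sqrt(mean(x10[inner]^2)),
               tolerance = 0.01)

  # steady-state stopband attenuation, away from the filtfilt edge transient
  x60 <- sin(2 * pi * 60 * t)
  y60 <- bandpass_filter(make_record(cbind(x60)))$samples[, 1]
  expect_lt(sqrt(mean(y60[inner]^2)), 0.05 * sqrt(mean(x60[inner]^2)))

  zero <- bandpass_filter(make_record(cbind(rep(0, 2000))))$samples
  expect_equal(zero, cbind(rep(0, 2000)))

  expect_error(bandpass_filter(make_record(cbind(x10)), 1, 120), "Nyquist|band")
})

test_that("filtering is per-segment and length-preserving", {
  set.seed(1)
  x <- matrix(rnorm(4000 * 2), ncol = 2)
  rec <- make_record(x, gaps = data.frame(onset = 8, end = 10))
  out <- bandpass_filter(rec)
  expect_equal(dim(out$samples), dim(rec$samples))
  # second segment result must not depend on first-segment data
  rec2 <- rec
  rec2$samples[1:100, ] <- 0
  out2 <- bandpass_filter(rec2)
  seg2 <- rec$segments$first_row[2]:nrow(rec$samples)
  expect_identical(out$samples[seg2, ], out2$samples[seg2, ])
})

test_that("windows are consecutive, gap-aware, remainder-discarding", {
  rec <- make_record(matrix(rnorm(81920), ncol = 1))
  win <- segment_windows(rec)
  expect_equal(nrow(win), 20)
  expect_equal(diff(win$onset), rep(20.48, 19)) # 4096 samples at 200 Hz

  # one gap splitting the record into 6000 + 6000 samples: 1 + 1 windows
  rec2 <- make_record(matrix(rnorm(13000), ncol = 1),
                      gaps = data.frame(onset = 30, end = 35))
  expect_equal(rec2$segments$n, c(6000, 6000))
  win2 <- segment_windows(rec2)
  expect_equal(nrow(win2), 2)
  expect_equal(win2$onset, c(0, 35))

  short <- make_record(matrix(rnorm(1000), ncol = 1))
  expect_warning(w <- segment_windows(short), "shorter than one window")
  expect_equal(nrow(w), 0)
})

test_that("instantaneous phase matches the analytic phase of sinusoids", {
  fs <- 200
  n <- 4096
  j <- 0:(n - 1)
  x <- cos(2 * pi * 8 * j / fs)
  ph <- instantaneous_phase(x)
  interior <- 200:3900
  slopes <- diff(ph)[interior] %% (2 * pi)
  expect_equal(mean(slopes), 2 * pi * 8 / fs, tolerance = 0.01)

  expect_identical(instantaneous_phase(x), ph) # deterministic

  # quadrature pair: sin lags cos by pi/2
  ph_s <- instantaneous_phase(sin(2 * pi * 8 * j / fs))
  d <- (ph[interior] - ph_s[interior]) %% (2 * pi)
  expect_equal(median(d), pi / 2, tolerance = 0.02)

  expect_warning(ph0 <- instantaneous_phase(cbind(x, 0 * x)),
                 "phase undefined")
  expect_true(all(is.na(ph0[, 2])))
})

test_that("mean phase coherence matches hand-computed phasor averages", {
  ph <- runif(100, -pi, pi)
  expect_equal(mean_phase_coherence(ph, ph), 1)
  expect_equal(mean_phase_coherence(ph, ph + 1.3), 1)
  expect_equal(mean_phase_coherence(c(0, 0, 0, 0), c(0, pi, 0, pi)), 0)
  expect_error(mean_phase_coherence(1:3, 1:4), "equal length")
})

test_that("coherence agrees with a brute-force complex sum on random phases", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(512, -pi, pi)
    b <- runif(512, -pi, pi)
    brute <- Mod(sum(complex(argument = a - b))) / 512
    expect_equal(mean_phase_coherence(a, b), brute, tolerance = 1e-12)
  }
})

test_that("sync matrices are symmetric, bounded, phase-shift invariant", {
  set.seed(3)
  phases <- apply(matrix(rnorm(4096 * 5, sd = 0.5), ncol = 5), 2, cumsum)
  R <- sync_matrix(phases)
  expect_identical(R, t(R))
  expect_true(all(diag(R) == 0))
  off <- R[lower.tri(R)]
  expect_true(all(off >= 0 & off <= 1))
  expect_true(all(off < 0.2)) # independent random walks decohere

  shifted <- phases
  shifted[, 2] <- shifted[, 2] + 2.2 # global phase shift of one channel
  expect_equal(sync_matrix(shifted), R, tolerance = 1e-12)

  dup <- cbind(phases[, 1], phases[, 1], phases[, 2])
  expect_equal(sync_matrix(dup)[1, 2], 1)

  expect_error(sync_matrix(phases[, 1, drop = FALSE]), "at least 2")
})

test_that("the windowed pipeline is deterministic for a fixed record", {
  rec <- small_sim()$record
  tc1 <- sync_timecourse(bandpass_filter(rec))
  tc2 <- sync_timecourse(bandpass_filter(rec))
  expect_identical(tc1, tc2)
  expect_equal(nrow(tc1), sum(rec$segments$n %/% 4096))
})
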