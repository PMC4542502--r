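make_tc <- function(onset, a, start = "2024-01-01 00:00:00", C = NULL) {
  tibble::tibble(
    window_index = seq_along(onset),
    start_time = as.POSIXct(start, tz = "UTC") + onset,
    onset = onset,
    a = a,
    C = if (is.null(C)) a else C,
    a_defined = !is.na(a)
  )
}

test_that("moving average is centered, gap-aware and partial at edges", {
  # constant series unchanged
  tc <- make_tc(20.48 * (0:9), rep(0.4, 10))
  expect_equal(moving_average(tc, "a", span = 5)$a_smooth, rep(0.4, 10))

  # 10-point toy with a gap after the 4th window: runs of 4 and 6, span 3
  onset <- c(20.48 * (0:3), 1000 + 20.48 * (0:5))
  tc <- make_tc(onset, c(1:4, 5:10))
  sm <- moving_average(tc, "a", span = 3)$a_smooth
  expect_equal(sm, c(1.5, 2, 3, 3.5, 5.5, 6, 7, 8, 9, 9.5))

  # no value mixes pre- and post-gap samples even at span 30
  sm30 <- moving_average(tc, "a", span = 30)$a_smooth
  expect_equal(sm30[1:4], rep(mean(1:4), 4))
  expect_equal(sm30[5:10], rep(mean(5:10), 6))

  # 30 windows of 20.48 s cover 10.24 min (display span)
  expect_equal(30 * 4096 / 200 / 60, 10.24)
})

test_that("periodogram recovers a 24 h rhythm through 20% gaps", {
  set.seed(14)
  onset <- seq(0, 5 * 24 * 3600, by = 20.48 * 30)
  onset <- sort(sample(onset, round(0.8 * length(onset))))
  y <- sin(2 * pi * onset / (24 * 3600))
  pg <- periodogram(make_tc(onset, y))
  peak <- pg$frequency[which.max(pg$power)]
  expect_lt(abs(peak - 1 / 24), attr(pg, "grid_step"))
})

test_that("periodogram separates a 24 h fundamental from an 8 h component", {
  set.seed(15)
  onset <- seq(0, 4 * 24 * 3600, by = 15 * 60)
  y <- 3 * sin(2 * pi * onset / (24 * 3600)) +
    1 * sin(2 * pi * onset / (8 * 3600)) + rnorm(length(onset), sd = 0.2)
  pg <- periodogram(make_tc(onset, y))
  step <- attr(pg, "grid_step")
  p24 <- max(pg$power[abs(pg$frequency - 1 / 24) <= step])
  p8 <- max(pg$power[abs(pg$frequency - 1 / 8) <= step])
  background <- median(pg$power)
  expect_gt(p24, p8) # fundamental dominates
  expect_gt(p8, 10 * background) # but the 8 h peak is present
})

test_that("periodogram equals the least-squares oracle and ignores offsets", {
  set.seed(16)
  onset <- sort(runif(80, 0, 40 * 3600))
  y <- sin(2 * pi * onset / (24 * 3600)) + rnorm(80, sd = 0.3)
  t_h <- onset / 3600
  freqs <- runif(10, 1 / 40, 0.4)
  p <- lomb_scargle(t_h, y, freqs)
  for (i in seq_along(freqs)) {
    expect_equal(p[i], oracle_lomb(t_h, y, freqs[i]), tolerance = 1e-6)
  }
  expect_equal(lomb_scargle(t_h, y + 5, freqs), p, tolerance = 1e-9)
  expect_true(all(p >= 0))

  expect_warning(pg <- periodogram(make_tc(onset, rep(1, 80))), "constant")
  expect_true(all(pg$power == 0))
  expect_error(periodogram(make_tc(1:5, 1:5)), "at least 16")
})

test_that("day/night labels follow the 06:00/22:00 wall-clock boundaries", {
  tc <- make_tc(c(0, 1, 2, 3), rep(0.5, 4), start = "2024-01-01 00:00:00")
  tc$start_time <- as.POSIXct(
    c(
      "2024-01-01 05:59:59", "2024-01-01 06:00:00",
      "2024-01-01 21:59:59", "2024-01-01 22:00:00"
    ),
    tz = "UTC"
  )
  lab <- label_daynight(tc)
  expect_equal(as.character(lab$daynight), c("night", "day", "day", "night"))
})

test_that("seizure-state labels follow the interval and precedence rules", {
  # 10 h record, windows starting every 6 min, one seizure 6.0-6.1 h
  onset <- seq(0, 10 * 3600 - 360, by = 360)
  tc <- make_tc(onset, runif(length(onset)))
  sz <- data.frame(onset = 6 * 3600, end = 6.1 * 3600)
  lab <- label_states(tc, sz, window_s = 360)
  st <- function(h) as.character(lab$state[which.min(abs(onset - h * 3600))])
  expect_equal(st(1), "inter-ictal")
  expect_equal(st(3), "pre-ictal")
  expect_equal(st(6.05), "ictal")
  expect_equal(st(6.3), "post-exclusion")
  expect_equal(st(8), "inter-ictal")
  # every window gets exactly one label; counts partition the record
  expect_equal(sum(table(lab$state)), nrow(tc))

  # no seizures: everything inter-ictal
  lab0 <- label_states(tc, NULL)
  expect_true(all(lab0$state == "inter-ictal"))

  # two seizures 1 h apart: the whole between-seizure span is pre-ictal of
  # the second (pre-ictal precedence over post-exclusion)
  sz2 <- data.frame(onset = c(2, 3) * 3600, end = c(2, 3) * 3600 + 60)
  lab2 <- label_states(tc, sz2, window_s = 360)
  between <- onset > 2 * 3600 + 60 & onset < 3 * 3600
  expect_true(all(lab2$state[between] == "pre-ictal"))

  expect_warning(
    label_states(tc, data.frame(onset = 20 * 3600, end = 20.1 * 3600),
                 window_s = 360),
    "outside the recording"
  )
})

test_that("group comparisons compute medians and relative change", {
  onset <- seq(0, 24 * 3600 - 1, by = 1200)
  tc <- make_tc(onset, rep(0.5, length(onset)))
  tc <- label_daynight(tc)
  tc$a[tc$daynight == "night"] <- 0.4
  cmp <- compare_groups(tc, "daynight")
  expect_equal(cmp$median1, 0.5)
  expect_equal(cmp$median2, 0.4)
  expect_equal(cmp$relative_change, -0.2)

  tc$a <- 0.7 # identical groups
  expect_equal(compare_groups(tc, "daynight")$relative_change, 0)

  tc$state <- factor("inter-ictal",
                     levels = c("ictal", "pre-ictal", "post-exclusion",
                                "inter-ictal"))
  expect_warning(out <- compare_groups(tc, "state"), "empty group")
  expect_null(out)
})

test_that("metric correlation and joint histogram follow their contracts", {
  onset <- 20.48 * (0:99)
  a <- runif(100, -0.2, 0.6)
  tc <- make_tc(onset, a, C = a)
  expect_equal(correlate_metrics(tc)$pearson, 1)
  tc$C <- -a + 1
  mc <- correlate_metrics(tc)
  expect_equal(mc$pearson, -1)
  expect_equal(max(mc$histogram$density), 1) # normalized to max bin count
  expect_equal(sum(mc$histogram$count), 100)

  tc$C <- rep(0.5, 100)
  expect_warning(flat <- correlate_metrics(tc), "zero variance")
  expect_true(is.na(flat$pearson))
})
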