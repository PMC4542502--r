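# Shared simulation fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Reduced-scale multi-day world: 16 channels over 3 simulated days with a
# ~3.6% recording duty cycle (128 s kept per hour), day-modular/night-hub
# coupling (the lower-night-assortativity regime of the generator), two
# seizures. Heavy (~1.5 min); built lazily and reused by the acceptance suite.
longrun_fixture <- function() {
  fixture("longrun", function() {
    keep_s <- 128
    dur <- 3 * 24 * 3600
    hour0 <- seq(0, dur - 3600, 3600)
    # one kept segment per hour at an irregular offset: strictly periodic
    # sampling would alias a 24 h rhythm onto 1/h +/- 1/24 h harmonics
    offset <- withr::with_seed(99, runif(length(hour0), 0, 3600 - keep_s))
    keep_on <- hour0 + offset
    gaps <- data.frame(
      onset = c(0, keep_on + keep_s),
      end = c(keep_on[1], keep_on[-1], dur)
    )
    gaps <- gaps[gaps$end > gaps$onset, ]
    cfg <- oscillator_config(
      n_channels = 16, duration = dur, seed = 42,
      day_graph = "modular", night_graph = "hub",
      coupling_strength_high = 20, coupling_strength_low = 20,
      gap_intervals = gaps,
      seizure_events = data.frame(
        onset = c(30 * 3600, 55 * 3600),
        end = c(30 * 3600 + 90, 55 * 3600 + 120)
      )
    )
    sim <- generate_record(cfg, truth_windows = 20)
    tc <- sim$record |>
      bandpass_filter() |>
      sync_timecourse() |>
      threshold_networks(rho = 0.1) |>
      network_metrics() |>
      label_daynight() |>
      label_states(sim$record$annotations)
    list(config = cfg, truth = sim$truth, annotations = sim$record$annotations,
         tc = tc)
  })
}

# small record crossing the 22:00 day/night boundary, with one seizure
small_sim <- function() {
  fixture("small_sim", function() {
    cfg <- oscillator_config(
      n_channels = 6, duration = 5400, seed = 7,
      start_time = "2024-03-01 21:00:00",
      gap_intervals = data.frame(onset = 2000, end = 2400),
      seizure_events = data.frame(onset = 3000, end = 3060)
    )
    generate_record(cfg)
  })
}
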