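test_that("degenerate (zero-dispersion) configs give deterministic trains", {
  cfg <- generator_config(amplitude_mean = 2, amplitude_sd = 0,
                          period_mean = 100, period_sd = 0,
                          duration = 1000, spike_width = 15, noise_sd = 0)
  tr <- sample_event_train(cfg)
  expect_equal(tr$event_times, seq(100, 900, by = 100))
  expect_equal(tr$event_amplitudes, rep(2, 9))

  # duration shorter than the first interval: empty train
  short <- generator_config(2, 0, period_mean = 100, period_sd = 0,
                            duration = 50, spike_width = 15, noise_sd = 0)
  expect_length(sample_event_train(short)$event_times, 0L)
})

test_that("event moments match the configured profile moments (letter A)", {
  tab <- load_profile_table(check = "none")
  cfg <- config_from_profile(tab, "A", n_events = 10000L, seed = 5L)
  tr <- sample_event_train(cfg)
  expect_length(tr$event_times, 10000L)
  expect_lt(abs(mean(tr$event_amplitudes) - 2.65) / 2.65, 0.02)
  expect_lt(abs(mean(diff(tr$event_times)) - 2034.88) / 2034.88, 0.1)
  expect_true(all(diff(tr$event_times) > 0))
  expect_true(all(tr$event_amplitudes > 0))
})

test_that("generator config validation rejects impossible settings", {
  expect_error(generator_config(2, -1, 100, 0, duration = 10,
                                spike_width = 1),
               "dispersions")
  expect_error(generator_config(2, 0, 100, 0, duration = -5,
                                spike_width = 1),
               "duration")
  expect_error(generator_config(2, 0, 100, 0, duration = 10,
                                spike_width = 30),
               "spike_width")
  expect_error(generator_config(2, 0, 100, 0, spike_width = 1),
               "duration.*n_events")
})

test_that("rendered signals honour baseline, spike shape and noise", {
  cfg <- generator_config(5, 0, 100, 0, duration = 400, spike_width = 10,
                          noise_sd = 0,
                          baseline = list(offset = 3))
  empty <- structure(list(event_times = numeric(0),
                          event_amplitudes = numeric(0), label = NULL),
                     class = "event_train")
  flat <- render_signal(empty, cfg)
  expect_equal(flat$values, rep(3, length(flat$values)))

  one <- structure(list(event_times = 200, event_amplitudes = 5,
                        label = NULL), class = "event_train")
  cfg0 <- generator_config(5, 0, 100, 0, duration = 400, spike_width = 10,
                           noise_sd = 0)
  sig <- render_signal(one, cfg0)
  expect_lt(abs(max(sig$values) - 5) / 5, 0.001)
  expect_equal(sig$times[which.max(sig$values)], 200)

  beyond <- structure(list(event_times = 500, event_amplitudes = 1,
                           label = NULL), class = "event_train")
  expect_error(render_signal(beyond, cfg0), "beyond")
})

test_that("detection recovers a zero-noise train exactly", {
  sim <- quick_sim(n_events = 50L, noise_sd = 0, amplitude_sd = 0.5,
                   period_sd = 15, seed = 3L)
  peaks <- detect_spikes(sim$recording, min_prominence = 0.5)
  expect_length(peaks$times, 50L)
  expect_true(all(abs(peaks$times - sim$events$event_times) <= 5 / 2))
})

test_that("diameter sampling is truncated-normal, seeded and reproducible", {
  expect_equal(sample_diameters(5, 1600, 0), rep(1600, 5))
  expect_error(sample_diameters(0, 1600, 200), "n must be")

  x <- sample_diameters(100000L, 1600, 200, seed = 9L)
  expect_lt(abs(mean(x) - 1600) / 1600, 0.01)
  expect_true(all(x > 0))
  expect_identical(x, sample_diameters(100000L, 1600, 200, seed = 9L))

  # truncation keeps draws positive even when the mean is near zero
  y <- sample_diameters(5000L, 10, 40, seed = 2L)
  expect_true(all(y > 0))
})

test_that("same seed gives identical trains and signals", {
  cfg <- generator_config(3, 1, 120, 40, duration = 4000, spike_width = 8,
                          noise_sd = 0.05, seed = 77L)
  a <- simulate_recording(cfg, label = "K")
  b <- simulate_recording(cfg, label = "K")
  expect_identical(a$events, b$events)
  expect_identical(a$recording$values, b$recording$values)
})

test_that("pipeline closure: profiling a rendered train recovers the moments", {
  # parameter-recovery across seeds: estimates stay within 3 standard
  # errors of the configured amplitude/period means
  amp_m <- 3; per_m <- 100; amp_sd <- 0.5; per_sd <- 10
  n <- 400L
  for (seed in c(2L, 12L, 22L)) {
    sim <- quick_sim(n_events = n, period_mean = per_m, period_sd = per_sd,
                     amplitude_mean = amp_m, amplitude_sd = amp_sd,
                     noise_sd = 0.02, seed = seed)
    prof <- profile_character(sim$recording, baseline_window = 60)
    expect_lt(abs(prof$amplitude$mean - amp_m),
              3 * amp_sd / sqrt(n) + 0.02 * amp_m)
    expect_lt(abs(prof$period$mean - per_m), 3 * per_sd / sqrt(n) + 1)
  }
})
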