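test_that("baseline removal maps constants and linear drift to zero", {
  t <- 0:499
  const <- recording(t, rep(7, 500), "potential_mV")
  expect_equal(remove_baseline(const, "linear_fit")$values, rep(0, 500))
  expect_equal(remove_baseline(const, "prestim_mean",
                               prestim = c(0, 100))$values,
               rep(0, 500))

  sim <- quick_sim(n_events = 30L, noise_sd = 0, seed = 4L)
  drifted <- recording(sim$recording$times,
                       sim$recording$values + 0.01 * sim$recording$times,
                       "potential_mV")
  det <- remove_baseline(drifted, "linear_fit")
  slope <- coef(lm(det$values ~ det$times))[2L]
  expect_lt(abs(slope), 1e-6 * 0.01)
})

test_that("moving-median baseline preserves isolated spike heights", {
  # duration padded past the last event so no spike sits inside the
  # running median's shrinking edge windows
  sim <- quick_sim(n_events = 40L, period_mean = 200, period_sd = 0,
                   amplitude_sd = 0.5, noise_sd = 0, seed = 6L,
                   duration = 8200)
  det <- remove_baseline(sim$recording, "moving_median", window = 80)
  peaks <- detect_spikes(det, min_prominence = 0.5)
  expect_length(peaks$heights, 40L)
  matched <- sim$events$event_amplitudes[
    findInterval(peaks$times, sim$events$event_times - 100) ]
  expect_true(all(abs(peaks$heights - matched) / matched < 0.01))

  expect_error(remove_baseline(sim$recording, "moving_median", window = 2),
               "3 samples")
})

test_that("reference subtraction is exact element-wise", {
  t <- 0:99
  x <- recording(t, sin(t / 7) + 2, "temperature_C")
  expect_equal(subtract_reference(x, x)$values, rep(0, 100))

  shifted <- recording(t, x$values + 1.5, "temperature_C")
  expect_equal(subtract_reference(shifted, x)$values, rep(1.5, 100))

  short <- recording(0:49, rep(1, 50), "temperature_C")
  expect_error(subtract_reference(x, short), "length mismatch")

  # synthetic temperature trace minus its drift-only twin leaves the spikes
  cfg <- generator_config(0.3, 0, 120, 0, duration = 1200, spike_width = 10,
                          noise_sd = 0,
                          baseline = list(offset = 21, drift = 1e-4))
  tr <- sample_event_train(cfg)
  with_drift <- render_signal(tr, cfg, "temperature_C")
  cfg0 <- generator_config(0.3, 0, 120, 0, duration = 1200, spike_width = 10,
                           noise_sd = 0,
                           baseline = list(offset = 21, drift = 1e-4))
  empty <- structure(list(event_times = numeric(0),
                          event_amplitudes = numeric(0), label = NULL),
                     class = "event_train")
  drift_only <- render_signal(empty, cfg0, "temperature_C")
  resid <- subtract_reference(with_drift, drift_only)
  expect_lt(abs(max(resid$values) - 0.3) / 0.3, 0.001)
})

test_that("monotone signals contain no peaks and short records error", {
  r <- recording(0:49, seq(0, 5, length.out = 50), "potential_mV")
  expect_length(detect_spikes(r, min_prominence = 0)$indices, 0L)
  expect_error(detect_spikes(recording(0:1, c(1, 2), "potential_mV"),
                             min_prominence = 0, min_separation = 1),
               "3 samples")
  expect_error(detect_spikes(r, min_separation = 0.5), "sampling interval")
})

test_that("two isolated bumps are located to within half a sample", {
  t <- 0:399
  v <- exp(-(t - 100)^2 / (2 * 8^2)) + exp(-(t - 300)^2 / (2 * 8^2))
  r <- recording(t, v, "potential_mV")
  peaks <- detect_spikes(r, min_prominence = 0.5)
  expect_equal(peaks$times, c(100, 300))
  expect_equal(peaks$heights, c(1, 1), tolerance = 1e-6)
})

test_that("detection matches the brute-force oracle on random signals", {
  set.seed(301)
  for (k in 1:60) {
    n <- sample(10:500, 1L)
    v <- switch(sample(3L, 1L),
                rnorm(n),
                cumsum(rnorm(n)),
                round(rnorm(n), 1))  # many plateau ties
    t <- seq_len(n) - 1
    mp <- runif(1, 0, 1.5)
    ms <- sample(c(1, 3, 10), 1L)
    mh <- sample(c(-Inf, 0, 0.5), 1L)
    rec <- recording(t, v, "potential_mV")
    got <- detect_spikes(rec, min_prominence = mp, min_separation = ms,
                         min_height = mh)
    want <- oracle_detect(v, t, min_prominence = mp, min_height = mh,
                          min_separation = ms)
    expect_identical(got$indices, sort(want$indices))
    expect_equal(got$prominences,
                 want$prominences[order(want$indices)])
  }
})

test_that("peak periods are successive time differences", {
  mk <- function(times) {
    structure(list(indices = seq_along(times), times = times,
                   heights = rep(1, length(times)),
                   prominences = rep(1, length(times)),
                   params = list()), class = "peak_set")
  }
  expect_equal(peak_periods(mk(c(0, 100, 250))), c(100, 150))
  expect_length(peak_periods(mk(42)), 0L)
  expect_length(peak_periods(mk(numeric(0))), 0L)

  sim <- quick_sim(n_events = 20L, period_sd = 0, noise_sd = 0, seed = 8L)
  peaks <- detect_spikes(sim$recording, min_prominence = 0.5)
  expect_true(all(abs(peak_periods(peaks) - 100) <= 1))
})

test_that("summaries follow the type-7 quartile convention", {
  s <- summarize_stats(rep(5, 10))
  expect_equal(c(s$q1, s$q2, s$q3, s$mean, s$max, s$min, s$sd),
               c(5, 5, 5, 5, 5, 5, 0))

  s <- summarize_stats(c(1, 2, 3, 4))
  expect_equal(c(s$q1, s$q2, s$q3), c(1.75, 2.5, 3.25))

  # midpoint-style convention stays configurable
  s2 <- summarize_stats(c(1, 2, 3, 4), type = 2)
  expect_equal(s2$q2, 2.5)

  expect_error(summarize_stats(numeric(0)), "empty")
})

test_that("summaries are permutation-invariant and affine-equivariant", {
  set.seed(17)
  for (k in 1:20) {
    x <- rnorm(sample(5:200, 1L), sd = 3)
    a <- runif(1, -5, 5)
    b <- runif(1, 0.1, 4) * sample(c(-1, 1), 1L)
    s <- summarize_stats(x)
    sp <- summarize_stats(sample(x))
    expect_equal(unclass(s), unclass(sp))
    st <- summarize_stats(a + b * x)
    expect_equal(st$mean, a + b * s$mean)
    expect_equal(st$sd, abs(b) * s$sd)
    expect_equal(st$q2, a + b * s$q2)
    expect_equal(sort(c(st$min, st$max)),
                 sort(a + b * c(s$min, s$max)))
    qs <- sort(a + b * c(s$q1, s$q3))
    expect_equal(c(st$q1, st$q3), qs)
  }
})

test_that("profiling requires at least two detected spikes", {
  sim <- quick_sim(n_events = 1L, noise_sd = 0, seed = 10L)
  expect_error(profile_character(sim$recording, baseline_window = 60),
               "insufficient spikes")

  unlabelled <- quick_sim(n_events = 10L, seed = 10L)$recording
  unlabelled$label <- NULL
  expect_error(profile_character(unlabelled), "label")
})

test_that("zero-noise periodic trains profile with near-zero period spread", {
  sim <- quick_sim(n_events = 30L, period_sd = 0, amplitude_sd = 0,
                   noise_sd = 0, seed = 12L, duration = 3200)
  prof <- profile_character(sim$recording, baseline_window = 250)
  expect_lte(prof$period$sd, 1)  # at most the sampling interval
  expect_equal(prof$amplitude$mean, 3, tolerance = 0.01)
})
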