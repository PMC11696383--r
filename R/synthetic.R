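#' Configuration for the synthetic spiking-recording generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: spike events whose amplitudes (mV) and inter-event intervals (s)
#' are i.i.d. log-normal, moment-matched to a target mean and standard
#' deviation — the published per-character period tables are strongly
#' right-skewed (means far above medians), which the log-normal reproduces
#' while staying positive.  Events are rendered as unit-peak Gaussian bumps
#' on a configurable baseline (offset + linear drift + sinusoid) with
#' additive white Gaussian noise.
#'
#' @param amplitude_mean,amplitude_sd Target moments of spike amplitudes, mV.
#' @param period_mean,period_sd Target moments of inter-event intervals, s.
#' @param duration Recording duration, s.  Events are laid down at
#'   cumulative interval sums and kept while strictly before `duration`.
#' @param spike_width Gaussian bump scale parameter, s; must be below
#'   `period_mean / 5` so spikes stay resolvable.
#' @param noise_sd Additive white-noise standard deviation, channel units.
#' @param baseline Named list `offset` (channel units), `drift`
#'   (units/s), `sin_amplitude` (units), `sin_period` (s).  Defaults to a
#'   flat zero baseline.
#' @param sampling_interval Render grid spacing, s (default 1).
#' @param n_events Optional event count: when given, exactly `n_events`
#'   intervals are drawn and `duration` is taken just past the last event.
#' @param seed Optional integer seed fixing the pseudo-random stream
#'   (R's default Mersenne-Twister generator).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(amplitude_mean, amplitude_sd,
                             period_mean, period_sd,
                             duration = NULL, spike_width = 20,
                             noise_sd = 0.05,
                             baseline = list(offset = 0, drift = 0,
                                             sin_amplitude = 0,
                                             sin_period = 1000),
                             sampling_interval = 1,
                             n_events = NULL, seed = NULL) {
  base_default <- list(offset = 0, drift = 0, sin_amplitude = 0,
                      sin_period = 1000)
  baseline <- utils::modifyList(base_default, as.list(baseline))
  if (is.null(duration) && is.null(n_events)) {
    stop("one of `duration` or `n_events` is required")
  }
  cfg <- structure(
    list(amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
         period_mean = period_mean, period_sd = period_sd,
         duration = duration, spike_width = spike_width,
         noise_sd = noise_sd, baseline = baseline,
         sampling_interval = sampling_interval,
         n_events = n_events, seed = seed),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$amplitude_mean <= 0 || cfg$period_mean <= 0) {
    stop("amplitude_mean and period_mean must be positive")
  }
  if (cfg$amplitude_sd < 0 || cfg$period_sd < 0 || cfg$noise_sd < 0) {
    stop("dispersions (amplitude_sd, period_sd, noise_sd) must be >= 0")
  }
  if (!is.null(cfg$duration) && cfg$duration <= 0) stop("duration must be > 0")
  if (cfg$spike_width <= 0) stop("spike_width must be > 0")
  if (cfg$spike_width >= cfg$period_mean / 5) {
    stop("spike_width must be below period_mean / 5 (got ", cfg$spike_width,
         " vs period_mean ", cfg$period_mean, ")")
  }
  if (cfg$sampling_interval <= 0) stop("sampling_interval must be > 0")
  if (!is.null(cfg$n_events) && cfg$n_events < 0) stop("n_events must be >= 0")
  invisible(cfg)
}

#' Generator configuration from a profile-table row
#'
#' @param profiles A `profile_table` (default: the packaged table).
#' @param label Letter selecting the row.
#' @param ... Overrides passed on to [generator_config()] (`duration`,
#'   `n_events`, `noise_sd`, ...).
#' @return A `generator_config` with amplitude/period moments taken from the
#'   selected row's mean and sd columns.
#' @export
config_from_profile <- function(profiles = load_profile_table(check = "none"),
                                label, ...) {
  row <- profiles[profiles$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("no profile row for label '", label, "'")
  generator_config(amplitude_mean = row$amp_mean, amplitude_sd = row$amp_sd,
                   period_mean = row$per_mean, period_sd = row$per_sd, ...)
}

# moment-matched log-normal parameters: mu = ln(m^2/sqrt(v+m^2)),
# sigma^2 = ln(1 + v/m^2)
lognormal_params <- function(m, s) {
  v <- s^2
  list(mu = log(m^2 / sqrt(v + m^2)), sigma = sqrt(log(1 + v / m^2)))
}

rlnorm_matched <- function(n, m, s) {
  if (s == 0) return(rep(m, n))  # point mass
  p <- lognormal_params(m, s)
  stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
}

#' Sample a latent spike-event train
#'
#' Draws i.i.d. log-normal inter-event intervals and amplitudes
#' moment-matched to the configured means and standard deviations; the first
#' event falls one interval after `t = 0` and events are kept while strictly
#' before `duration` (or, with `n_events` set, exactly that many are drawn).
#' A zero dispersion degenerates to a point mass at the mean.
#'
#' @param config A [generator_config()].
#' @param label Optional stimulus label carried on the train.
#' @return An `event_train`: list with strictly increasing `event_times`
#'   (s), positive `event_amplitudes` (mV) and `label`.
#' @export
sample_event_train <- function(config, label = NULL) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.null(config$n_events)) {
    n <- config$n_events
    intervals <- rlnorm_matched(n, config$period_mean, config$period_sd)
    times <- cumsum(intervals)
  } else {
    # draw in blocks until the duration is exceeded
    times <- numeric(0)
    total <- 0
    block <- max(16L, ceiling(config$duration / config$period_mean * 1.2))
    while (total < config$duration) {
      intervals <- rlnorm_matched(block, config$period_mean, config$period_sd)
      times <- c(times, total + cumsum(intervals))
      total <- times[length(times)]
    }
    times <- times[times < config$duration]
  }
  amplitudes <- rlnorm_matched(length(times), config$amplitude_mean,
                               config$amplitude_sd)
  structure(list(event_times = times, event_amplitudes = amplitudes,
                 label = if (is.null(label)) NULL else validate_label(label)),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events", length(x$event_times)))
  if (!is.null(x$label)) cat(sprintf(", stimulus '%s'", x$label))
  if (length(x$event_times) > 0L) {
    cat(sprintf("; t in [%.4g, %.4g] s, amplitude mean %.4g mV",
                x$event_times[1L], x$event_times[length(x$event_times)],
                mean(x$event_amplitudes)))
  }
  cat("\n")
  invisible(x)
}

baseline_values <- function(baseline, t) {
  b <- baseline$offset + baseline$drift * t
  if (baseline$sin_amplitude != 0) {
    b <- b + baseline$sin_amplitude * sin(2 * pi * t / baseline$sin_period)
  }
  b
}

#' Render an event train as a sampled recording
#'
#' The signal is `baseline(t) + sum_k a_k * exp(-((t - t_k)^2) /
#' (2 * spike_width^2)) + N(0, noise_sd)` sampled on a uniform grid, so the
#' local maximum of an isolated noiseless spike equals baseline plus its
#' amplitude (to within the sampling offset of the bump top, under 0.1%
#' for the default grid).
#'
#' @param events An [sample_event_train()] result.
#' @param config The [generator_config()] used to draw it.
#' @param channel_kind Channel of the rendered recording.
#' @return A [recording()] spanning `[0, duration]`.
#' @export
render_signal <- function(events, config,
                          channel_kind = c("potential_mV", "temperature_C")) {
  channel_kind <- match.arg(channel_kind)
  validate_generator_config(config)
  duration <- config$duration
  if (is.null(duration)) {
    last <- if (length(events$event_times)) max(events$event_times) else 0
    duration <- last + 5 * config$spike_width
  }
  if (length(events$event_times) && max(events$event_times) > duration) {
    stop("event at t = ", max(events$event_times),
         " s extends beyond duration ", duration, " s")
  }
  dt <- config$sampling_interval
  t <- seq(0, duration, by = dt)
  v <- baseline_values(config$baseline, t)
  w <- config$spike_width
  half <- ceiling(5 * w / dt)  # bump support truncated at +-5 widths
  for (k in seq_along(events$event_times)) {
    tk <- events$event_times[k]
    centre <- round(tk / dt)
    idx <- max(0L, centre - half):min(length(t) - 1L, centre + half)
    v[idx + 1L] <- v[idx + 1L] +
      events$event_amplitudes[k] * exp(-((t[idx + 1L] - tk)^2) / (2 * w^2))
  }
  if (config$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, config$noise_sd)
  recording(t, v, channel_kind, label = events$label,
            sampling_interval = dt)
}

#' Simulate one labelled recording in a single call
#'
#' Convenience wrapper: [sample_event_train()] then [render_signal()],
#' returning both the recording and its ground-truth events.
#'
#' @inheritParams sample_event_train
#' @inheritParams render_signal
#' @return List with elements `recording` and `events`.
#' @export
simulate_recording <- function(config, label = NULL,
                               channel_kind = c("potential_mV",
                                                "temperature_C")) {
  channel_kind <- match.arg(channel_kind)
  events <- sample_event_train(config, label = label)
  list(recording = render_signal(events, config, channel_kind),
       events = events)
}

#' Sample microsphere diameters
#'
#' I.i.d. normal draws truncated at zero (negative draws are rejected and
#' redrawn), emulating a measured diameter sample.
#'
#' @param n Sample size, `>= 1`.
#' @param mean,sd Normal parameters in nm; `sd = 0` gives a point mass.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positive diameters.
#' @export
sample_diameters <- function(n, mean = 1600, sd = 200, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  }
  x
}
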