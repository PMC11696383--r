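#' Remove the slow baseline from a recording
#'
#' Three estimators of the non-spiking baseline, subtracted sample-wise:
#' \describe{
#'   \item{`prestim_mean`}{mean over a supplied pre-stimulus interval;
#'     appropriate when stimulation starts at a known time.}
#'   \item{`linear_fit`}{least-squares line in time; removes offset and
#'     constant drift exactly.}
#'   \item{`moving_median`}{running median over a window much wider than a
#'     spike; tracks slow nonlinear drift while ignoring sparse spikes.}
#' }
#'
#' @param rec A [recording()].
#' @param method Baseline estimator.
#' @param window Window length in seconds for `moving_median`; must cover at
#'   least 3 samples.
#' @param prestim Length-2 numeric `c(t0, t1)`, the pre-stimulus interval in
#'   seconds, for `prestim_mean`.
#' @return The detrended [recording()] (same times, channel and label).
#' @export
remove_baseline <- function(rec,
                            method = c("moving_median", "linear_fit",
                                       "prestim_mean"),
                            window = 500, prestim = NULL) {
  stopifnot(inherits(rec, "recording"))
  method <- match.arg(method)
  v <- rec$values
  base <- switch(method,
    prestim_mean = {
      if (is.null(prestim) || length(prestim) != 2L) {
        stop("`prestim_mean` needs a pre-stimulus interval `prestim = c(t0, t1)`")
      }
      sel <- rec$times >= prestim[1L] & rec$times <= prestim[2L]
      if (!any(sel)) stop("pre-stimulus interval contains no samples")
      rep(mean(v[sel]), length(v))
    },
    linear_fit = {
      fit <- stats::lm.fit(cbind(1, rec$times), v)
      drop(cbind(1, rec$times) %*% fit$coefficients)
    },
    moving_median = {
      if (window <= 0) stop("window must be > 0")
      k <- floor(window / rec$sampling_interval)
      if (k < 3L) stop("moving-median window shorter than 3 samples")
      if (k %% 2L == 0L) k <- k + 1L  # runmed needs odd width
      k <- min(k, if (length(v) %% 2L == 1L) length(v) else length(v) - 1L)
      as.numeric(stats::runmed(v, k, endrule = "median"))
    })
  recording(rec$times, v - base, rec$channel_kind, label = rec$label,
            sampling_interval = rec$sampling_interval)
}

#' Subtract a reference trace
#'
#' Element-wise difference of two recordings on the same time grid, e.g.
#' removing the background temperature from a co-recorded temperature trace.
#'
#' @param rec,reference [recording()]s of equal length whose times agree
#'   within `tol` seconds.
#' @param tol Time-agreement tolerance in seconds.
#' @return A [recording()] with `rec$values - reference$values`; channel and
#'   label are taken from `rec`.
#' @export
subtract_reference <- function(rec, reference, tol = 1e-6) {
  stopifnot(inherits(rec, "recording"), inherits(reference, "recording"))
  if (length(rec$times) != length(reference$times)) {
    stop("length mismatch: ", length(rec$times), " vs ",
         length(reference$times), " samples")
  }
  if (any(abs(rec$times - reference$times) > tol)) {
    stop("time grids differ by more than ", tol, " s")
  }
  recording(rec$times, rec$values - reference$values, rec$channel_kind,
            label = rec$label, sampling_interval = rec$sampling_interval)
}

#' Robust noise-floor estimate
#'
#' Standard deviation of the additive noise estimated as the median absolute
#' deviation of the first difference divided by sqrt(2); insensitive to
#' sparse spikes and slow drift.
#'
#' @param rec A [recording()] (or numeric vector).
#' @return Estimated noise sd in channel units.
#' @export
estimate_noise_sd <- function(rec) {
  v <- if (inherits(rec, "recording")) rec$values else as.numeric(rec)
  stats::mad(diff(v)) / sqrt(2)
}

#' Detect spikes as prominent local maxima
#'
#' A sample is a peak candidate when it exceeds its left neighbour and is at
#' least its right neighbour (the leftmost sample of a flat plateau);
#' candidates are filtered by height and by topographic prominence (height
#' minus the higher of the two minima separating the peak from higher
#' terrain or the record edge), and peaks closer together than
#' `min_separation` are resolved in favour of the taller one (ties: the
#' earlier).  Run on a detrended recording; heights are read off the
#' detrended signal.
#'
#' @param rec A [recording()] with at least 3 samples, normally already
#'   baseline-removed.
#' @param min_prominence Minimum topographic prominence, channel units.
#'   `NULL` (default) uses a length-adaptive noise floor,
#'   `max(5, 2 * sqrt(2 * log(n))) * sigma` with `sigma` from
#'   [estimate_noise_sd()]: the topographic prominence that pure noise can
#'   reach grows with the record length (extreme-value scaling), so a fixed
#'   multiple of the noise sd admits spurious peaks on long records; the
#'   `2 * sqrt(2 * log(n))` term is the universal-threshold rate for the
#'   running extremes of `n` Gaussian samples, doubled because a prominence
#'   spans a noise maximum and a noise minimum.
#' @param min_separation Minimum spacing between reported peaks, s; must be
#'   at least the sampling interval.
#' @param min_height Minimum peak height, channel units.
#' @return A `peak_set`: list with `indices` (1-based sample positions),
#'   `times` (s), `heights` (channel units), `prominences`, and the
#'   detection parameters used.
#' @export
detect_spikes <- function(rec, min_prominence = NULL, min_separation = 10,
                          min_height = 0) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$values) < 3L) stop("recording shorter than 3 samples")
  if (min_separation < rec$sampling_interval) {
    stop("min_separation (", min_separation,
         " s) below the sampling interval (", rec$sampling_interval, " s)")
  }
  if (is.null(min_prominence)) {
    n <- length(rec$values)
    min_prominence <- max(5, 2 * sqrt(2 * log(n))) * estimate_noise_sd(rec)
  }
  sep_samples <- max(1L, ceiling(min_separation / rec$sampling_interval))
  res <- detect_peaks_cpp(rec$values, min_prominence, min_height,
                          as.integer(sep_samples))
  idx <- res$indices
  structure(
    list(indices = idx, times = rec$times[idx], heights = rec$values[idx],
         prominences = res$prominences,
         params = list(min_prominence = min_prominence,
                       min_separation = min_separation,
                       min_height = min_height)),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (min prominence %.4g, min separation %g s)\n",
              length(x$indices), x$params$min_prominence,
              x$params$min_separation))
  invisible(x)
}

#' Inter-peak periods
#'
#' Successive differences of peak times; the quantity summarized as the
#' "period" of the spiking response.
#'
#' @param peaks A `peak_set` from [detect_spikes()].
#' @return Numeric vector of length `n_peaks - 1` in seconds (empty for 0 or
#'   1 peaks).
#' @export
peak_periods <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$times) < 2L) return(numeric(0))
  diff(peaks$times)
}

#' Seven-number summary of a sample
#'
#' Quartiles by linear interpolation of order statistics
#' ([stats::quantile()] type 7 by default, configurable), arithmetic mean,
#' extremes and the n-1 standard deviation.
#'
#' @param values Non-empty numeric vector.
#' @param type Quantile convention passed to [stats::quantile()].
#' @return A [stats_summary()] with `n = length(values)`.
#' @export
summarize_stats <- function(values, type = 7) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("cannot summarize an empty sample")
  if (any(!is.finite(values))) stop("non-finite values in sample")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = type))
  stats_summary(q1 = q[1L], q2 = q[2L], q3 = q[3L], mean = mean(values),
                max = max(values), min = min(values),
                sd = if (length(values) > 1L) stats::sd(values) else 0,
                n = length(values))
}

#' Profile a labelled recording
#'
#' The stage that turns one stimulus recording into a per-character profile
#' row: baseline removal, spike detection, then summary statistics of the
#' detected peak heights and of the inter-peak periods.
#'
#' @param rec A [recording()].
#' @param label Stimulus label; defaults to the recording's own.
#' @param baseline_method,baseline_window Passed to [remove_baseline()].
#' @param prestim Pre-stimulus interval for `baseline_method =
#'   "prestim_mean"`.
#' @param min_prominence,min_separation,min_height Passed to
#'   [detect_spikes()].
#' @param type Quartile convention for [summarize_stats()].
#' @return A [character_profile()] (requires at least 2 detected peaks).
#' @export
profile_character <- function(rec, label = rec$label,
                              baseline_method = "moving_median",
                              baseline_window = 500, prestim = NULL,
                              min_prominence = NULL, min_separation = 10,
                              min_height = 0, type = 7) {
  if (is.null(label)) stop("recording carries no stimulus label")
  detrended <- remove_baseline(rec, method = baseline_method,
                               window = baseline_window, prestim = prestim)
  peaks <- detect_spikes(detrended, min_prominence = min_prominence,
                         min_separation = min_separation,
                         min_height = min_height)
  if (length(peaks$indices) < 2L) {
    stop("insufficient spikes for period statistics (",
         length(peaks$indices), " peak(s) detected)")
  }
  character_profile(label,
                    amplitude = summarize_stats(peaks$heights, type = type),
                    period = summarize_stats(peak_periods(peaks), type = type))
}
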