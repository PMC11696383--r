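# steady-state filter state for a unit-amplitude step input, solved from the
# direct-form II transposed recursion (z = A z + B per unit input), so a
# constant signal passes through the filter without an edge transient
filter_zi <- function(b, a) {
  n <- length(b)
  if (n < 2L) return(numeric(0))
  ord <- n - 1L
  A <- matrix(0, ord, ord)
  if (ord > 1L) A[cbind(seq_len(ord - 1L), seq_len(ord - 1L) + 1L)] <- 1
  A[, 1L] <- A[, 1L] - a[-1L]
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(ord) - A, B)
}

apply_filtfilt <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * max(length(a), length(b)) * 10L)
  if (pad < 1L) stop("signal too short to filter")
  # odd extension about both endpoints suppresses edge transients
  pre <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  ext <- c(pre, x, post)
  zi <- filter_zi(b, a)
  y <- iir_df2t_cpp(b, a, ext, zi * ext[1L])
  y <- rev(iir_df2t_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

butter_design <- function(order, cutoff, fs, type) {
  nyquist <- fs / 2
  if (cutoff <= 0 || cutoff >= nyquist) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency ",
         format(nyquist), " Hz")
  }
  if (order < 1L) stop("order must be >= 1")
  signal::butter(order, cutoff / nyquist, type = type)
}

zero_phase_filter <- function(rec, cutoff, order, type) {
  stopifnot(inherits(rec, "recording"))
  fs <- 1 / rec$sampling_interval
  bf <- butter_design(order, cutoff, fs, type)
  recording(rec$times, apply_filtfilt(bf$b, bf$a, rec$values),
            rec$channel_kind, label = rec$label,
            sampling_interval = rec$sampling_interval)
}

#' Zero-phase Butterworth filtering
#'
#' Forward-backward application of a Butterworth filter designed with
#' [signal::butter()]: no phase distortion (spike timing preserved), DC gain
#' 1 for the low-pass and 0 for the high-pass, and the usual -3 dB
#' single-pass attenuation at the cutoff becoming -6 dB after the two
#' passes.  Edge transients are suppressed by odd-extension padding plus a
#' steady-state initial filter state.
#'
#' @param rec A [recording()].
#' @param cutoff Cutoff frequency in Hz, strictly inside (0, Nyquist).
#' @param order Butterworth order per pass (default 4).
#' @return The filtered [recording()].
#' @export
lowpass <- function(rec, cutoff, order = 4L) {
  zero_phase_filter(rec, cutoff, order, "low")
}

#' @rdname lowpass
#' @export
highpass <- function(rec, cutoff, order = 4L) {
  zero_phase_filter(rec, cutoff, order, "high")
}

spectral_windows <- c("rectangular", "hann", "hamming")

#' Power spectrum in decibels
#'
#' Periodogram of the recording: power `|X_k|^2 / n` from the discrete
#' Fourier transform (so the two-sided power sums to the signal energy,
#' Parseval), reported as `10 log10(power)` at the positive frequencies.
#'
#' @param rec A [recording()] with at least 8 samples.
#' @param window Taper applied before the transform: `"rectangular"`
#'   (default), `"hann"` or `"hamming"`.
#' @param onesided Report positive frequencies only (default); `FALSE`
#'   returns the full two-sided spectrum (frequencies above Nyquist folded
#'   as sampled).
#' @return A `spectrum_estimate`: list with `frequencies` (Hz), `power`
#'   (linear), `power_db`, `n`, `window`.
#' @export
power_spectrum_db <- function(rec, window = spectral_windows,
                              onesided = TRUE) {
  stopifnot(inherits(rec, "recording"))
  window <- match.arg(window)
  x <- rec$values
  n <- length(x)
  if (n < 8L) stop("recording too short for a spectrum (need >= 8 samples)")
  w <- switch(window,
              rectangular = rep(1, n),
              hann = 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))),
              hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  X <- stats::fft(x * w)
  power <- Mod(X)^2 / n
  freqs <- (seq_len(n) - 1L) / (n * rec$sampling_interval)
  if (onesided) {
    keep <- 2:(floor(n / 2) + 1L)  # positive frequencies up to Nyquist
    power <- power[keep]
    freqs <- freqs[keep]
  }
  structure(list(frequencies = freqs, power = power,
                 power_db = 10 * log10(power), n = n, window = window),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> n = %d, %s window, %d bins up to %.4g Hz\n",
              x$n, x$window, length(x$frequencies), max(x$frequencies)))
  invisible(x)
}
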