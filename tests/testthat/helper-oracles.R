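# Brute-force peak-detection oracle: same contract as detect_spikes but
# written as direct O(n^2) scans over the definition, independent of the
# package's compiled path.
oracle_detect <- function(v, times, min_prominence = 0, min_height = 0,
                          min_separation = 0) {
  n <- length(v)
  cand <- integer(0)
  for (i in seq(2L, n - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) cand <- c(cand, i)
  }
  kept <- integer(0)
  prom <- numeric(0)
  for (i in cand) {
    h <- v[i]
    if (h < min_height) next
    higher_left <- which(v[seq_len(i - 1L)] > h)
    lseg <- if (length(higher_left)) seq(max(higher_left) + 1L, i - 1L) else
      seq_len(i - 1L)
    lmin <- min(v[lseg])
    right <- seq(i + 1L, n)
    higher_right <- right[v[right] > h]
    rseg <- if (length(higher_right)) seq(i + 1L, min(higher_right) - 1L) else
      right
    rmin <- min(v[rseg])
    p <- h - max(lmin, rmin)
    if (p < min_prominence) next
    kept <- c(kept, i)
    prom <- c(prom, p)
  }
  # taller first, earlier on ties; drop peaks within min_separation of a keeper
  ord <- order(-v[kept], kept)
  sel <- logical(length(kept))
  for (k in ord) {
    if (!any(sel & abs(times[kept] - times[kept[k]]) < min_separation)) {
      sel[k] <- TRUE
    }
  }
  list(indices = kept[sel], prominences = prom[sel])
}

# counting oracle for confusion matrices
oracle_confusion <- function(true, pred) {
  counts <- matrix(0L, 26L, 26L, dimnames = list(LETTERS, LETTERS))
  rejected <- stats::setNames(integer(26L), LETTERS)
  for (k in seq_along(true)) {
    if (pred[k] == "REJECT") {
      rejected[true[k]] <- rejected[true[k]] + 1L
    } else {
      counts[true[k], pred[k]] <- counts[true[k], pred[k]] + 1L
    }
  }
  list(counts = counts, rejected = rejected)
}

# quick labelled synthetic recording with desk-scale parameters
quick_sim <- function(label = "A", n_events = 50L, period_mean = 100,
                      period_sd = 10, amplitude_mean = 3,
                      amplitude_sd = 0.5, noise_sd = 0.02, spike_width = 5,
                      seed = 1L, ...) {
  cfg <- generator_config(amplitude_mean, amplitude_sd, period_mean,
                          period_sd, n_events = n_events,
                          spike_width = spike_width, noise_sd = noise_sd,
                          seed = seed, ...)
  simulate_recording(cfg, label = label)
}

# simulate one recording per letter from the packaged table (optionally with
# all per-character separation collapsed to the grand mean), profile each and
# classify against the references; returns the 26 predicted labels
simulate_and_classify <- function(seed, references, collapse = FALSE,
                                  events_per_character = 60L,
                                  sampling_interval = 5) {
  vapply(seq_len(26L), function(i) {
    lab <- LETTERS[i]
    if (collapse) {
      cfg <- generator_config(
        amplitude_mean = mean(references$amp_mean),
        amplitude_sd = mean(references$amp_sd),
        period_mean = mean(references$per_mean),
        period_sd = mean(references$per_sd),
        n_events = events_per_character,
        sampling_interval = sampling_interval,
        seed = seed * 1000L + i)
    } else {
      cfg <- config_from_profile(references, lab,
                                 n_events = events_per_character,
                                 sampling_interval = sampling_interval,
                                 seed = seed * 1000L + i)
    }
    sim <- simulate_recording(cfg, label = lab)
    prof <- profile_character(sim$recording)
    nearest_profile_classify(prof, references)
  }, "")
}
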