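#' Configuration for the end-to-end analysis pipeline
#'
#' Collects every tunable of the full workflow: simulation scale, detection
#' parameters, recognition thresholds (mV / s), Boolean-gate thresholds
#' (normalized units), diameter-sample parameters, filter settings and the
#' quartile convention.  Identical configuration and seed give identical
#' outputs.
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param events_per_character Events simulated per alphabet character.
#' @param sampling_interval Render grid spacing, s.
#' @param noise_sd Additive noise sd, mV.
#' @param spike_width Spike bump scale, s.
#' @param baseline Baseline description passed to [generator_config()].
#' @param min_prominence,min_separation,min_height Detection parameters
#'   (see [detect_spikes()]).
#' @param baseline_method,baseline_window Passed to [remove_baseline()].
#' @param A_th,P_th Recognition thresholds (mV, s) for
#'   [threshold_classify()].
#' @param T_A,T_P Boolean-gate thresholds on the normalized scale.
#' @param diameter_n,diameter_mean,diameter_sd Microsphere diameter sample.
#' @param filter_cutoff,filter_order Spectral-stage filter settings (Hz,
#'   Butterworth order).
#' @param quartile_type Quantile convention.
#' @param out_dir Output directory for [run_full_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            events_per_character = 60L,
                            sampling_interval = 5,
                            noise_sd = 0.05,
                            spike_width = 20,
                            baseline = list(offset = 0, drift = 0,
                                            sin_amplitude = 0,
                                            sin_period = 1000),
                            min_prominence = NULL,
                            min_separation = 10,
                            min_height = 0,
                            baseline_method = "moving_median",
                            baseline_window = 500,
                            A_th = 10, P_th = 8000,
                            T_A = 1, T_P = 1,
                            diameter_n = 500L,
                            diameter_mean = 1600,
                            diameter_sd = 200,
                            filter_cutoff = 0.01,
                            filter_order = 4L,
                            quartile_type = 7,
                            out_dir = "results") {
  structure(as.list(environment()), class = "pipeline_config")
}

# hash of the scientific parameters only: where outputs land does not change
# what is computed
config_hash <- function(config) {
  cfg <- unclass(config)
  rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
}

write_output_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Mirrors the study workflow end to end on synthetic data: simulate one
#' recording per alphabet character from the packaged profile table, profile
#' each (baseline removal, spike detection, summary statistics), classify
#' the estimated profiles against the references (nearest-profile) and the
#' reference table against the thresholds (threshold rule + confusion
#' matrix), evaluate the Boolean-gate table, and run the morphology (KDE +
#' box statistics) and spectral (filtering + dB spectrum) summaries.
#' Writes CSVs plus a plain-text report, each stamped with the
#' configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param profiles Reference `profile_table` (default: packaged table).
#' @return Invisibly, a list with the estimated profile table, confusion
#'   matrices, metrics, gate table, morphology and spectral summaries, and
#'   the paths written.
#' @export
run_full_pipeline <- function(config = pipeline_config(),
                              profiles = load_profile_table(check = "none")) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  # --- simulate + profile all 26 characters -------------------------------
  estimated <- vector("list", 26L)
  predicted <- character(26L)
  for (i in seq_len(26L)) {
    lab <- LETTERS[i]
    cfg <- config_from_profile(
      profiles, lab,
      n_events = config$events_per_character,
      noise_sd = config$noise_sd,
      spike_width = config$spike_width,
      baseline = config$baseline,
      sampling_interval = config$sampling_interval,
      seed = config$seed * 1000L + i)
    sim <- simulate_recording(cfg, label = lab)
    prof <- profile_character(
      sim$recording,
      baseline_method = config$baseline_method,
      baseline_window = config$baseline_window,
      min_prominence = config$min_prominence,
      min_separation = config$min_separation,
      min_height = config$min_height,
      type = config$quartile_type)
    estimated[[i]] <- prof
    predicted[i] <- nearest_profile_classify(prof, profiles)
  }
  est_table <- profile_table(estimated)
  paths <- c(paths, write_output_csv(as.data.frame(est_table),
                                     out("estimated_profiles.csv"), hash))

  # --- recognition --------------------------------------------------------
  cm_sim <- build_confusion_matrix(LETTERS, predicted)
  thr_pred <- threshold_classify(profiles, config$A_th, config$P_th)
  cm_thr <- build_confusion_matrix(LETTERS, unname(thr_pred))
  metrics <- data.frame(
    quantity = c("nearest_profile_accuracy", "threshold_accuracy"),
    value = c(accuracy(cm_sim), accuracy(cm_thr)))
  cm_df <- as.data.frame(cm_thr$counts[, , drop = FALSE])
  cm_df$REJECT <- as.integer(cm_thr$rejected)
  cm_df <- cbind(true = LETTERS, cm_df)
  paths <- c(paths, write_output_csv(cm_df, out("confusion_threshold.csv"),
                                     hash))
  paths <- c(paths, write_output_csv(precision_recall(cm_sim),
                                     out("precision_recall_simulated.csv"),
                                     hash))
  paths <- c(paths, write_output_csv(metrics, out("metrics.csv"), hash))

  # --- Boolean gates ------------------------------------------------------
  gate_tab <- gates_from_profiles(profiles, T_A = config$T_A,
                                  T_P = config$T_P)
  paths <- c(paths, write_output_csv(gate_tab$table, out("gate_table.csv"),
                                     hash))

  # --- morphology ---------------------------------------------------------
  diam <- sample_diameters(config$diameter_n, config$diameter_mean,
                           config$diameter_sd,
                           seed = config$seed * 1000L + 27L)
  kde_est <- kde(diam)
  box <- box_stats(diam, type = config$quartile_type)
  paths <- c(paths, write_output_csv(
    data.frame(diameter_nm = kde_est$grid, density = kde_est$density),
    out("diameter_kde.csv"), hash))
  paths <- c(paths, write_output_csv(
    data.frame(statistic = c("q1", "q2", "q3", "mean", "lower_fence",
                             "upper_fence", "n_outliers"),
               value = c(box$q1, box$q2, box$q3, box$mean, box$lower_fence,
                         box$upper_fence, length(box$outliers))),
    out("diameter_boxstats.csv"), hash))

  # --- spectral summary on a spontaneous-spiking style trace --------------
  spont_cfg <- generator_config(
    amplitude_mean = 3.56, amplitude_sd = 3.23,
    period_mean = 188.39, period_sd = 60.77,
    duration = 7200, spike_width = 10,
    noise_sd = config$noise_sd, sampling_interval = 1,
    seed = config$seed * 1000L + 28L)
  spont <- simulate_recording(spont_cfg)$recording
  lp <- lowpass(spont, config$filter_cutoff, config$filter_order)
  hp <- highpass(spont, config$filter_cutoff, config$filter_order)
  spec <- power_spectrum_db(lp)
  paths <- c(paths, write_output_csv(
    data.frame(frequency_hz = spec$frequencies, power_db = spec$power_db),
    out("lowpass_spectrum_db.csv"), hash))

  # --- report -------------------------------------------------------------
  report <- c(
    paste0("protospike pipeline report (config ", hash, ")"),
    sprintf("seed: %d; events per character: %d; sampling interval: %g s",
            config$seed, config$events_per_character,
            config$sampling_interval),
    sprintf("nearest-profile recognition accuracy: %.4f",
            accuracy(cm_sim)),
    sprintf("threshold rule (A_th = %g mV, P_th = %g s): %d assigned, %d rejected",
            config$A_th, config$P_th, sum(thr_pred != "REJECT"),
            sum(thr_pred == "REJECT")),
    sprintf("gate counts (AND, OR, NOT, NAND, NOR): %s",
            paste(gate_tab$table$count, collapse = ", ")),
    sprintf("diameters: n = %d, mean %.2f nm, fences [%.2f, %.2f] nm, %d outlier(s)",
            box$n, box$mean, box$lower_fence, box$upper_fence,
            length(box$outliers)),
    sprintf("low/high-pass at %g Hz: lowpass sd %.4g mV, highpass sd %.4g mV",
            config$filter_cutoff, stats::sd(lp$values), stats::sd(hp$values)))
  report_path <- out("report.txt")
  writeLines(report, report_path)
  paths <- c(paths, report_path)

  invisible(list(estimated_profiles = est_table,
                 predicted = predicted,
                 confusion_simulated = cm_sim,
                 confusion_threshold = cm_thr,
                 metrics = metrics,
                 gate_table = gate_tab,
                 diameter_kde = kde_est,
                 diameter_box = box,
                 lowpass = lp, highpass = hp, spectrum = spec,
                 config_hash = hash,
                 paths = paths))
}
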