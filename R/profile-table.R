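#' Summary statistics for one spike quantity
#'
#' Seven-number summary used throughout the per-character response tables:
#' quartiles, mean, extremes and standard deviation of detected-peak
#' amplitudes (mV) or inter-peak periods (s), plus the sample count when
#' known.
#'
#' @param q1,q2,q3 Quartiles (same units as the summarized quantity).
#' @param mean Arithmetic mean.
#' @param max,min Extremes.
#' @param sd Standard deviation (n-1 denominator), `>= 0`.
#' @param n Sample count, or `NA` when unknown (published tables do not
#'   report it).
#' @param check `"error"`, `"warn"` or `"none"`: how to handle violations of
#'   the ordering invariants `min <= q1 <= q2 <= q3 <= max`,
#'   `min <= mean <= max`, `sd >= 0`.
#' @return A `stats_summary` object.
#' @export
stats_summary <- function(q1, q2, q3, mean, max, min, sd, n = NA_integer_,
                          check = c("error", "warn", "none")) {
  check <- match.arg(check)
  out <- structure(
    list(q1 = q1, q2 = q2, q3 = q3, mean = mean, max = max, min = min,
         sd = sd, n = n),
    class = "stats_summary"
  )
  msg <- summary_violations(out)
  if (length(msg) > 0L && check != "none") {
    msg <- paste(msg, collapse = "; ")
    if (check == "error") stop("invalid summary: ", msg) else
      warning("summary invariant violated: ", msg)
  }
  out
}

summary_violations <- function(s) {
  msg <- character(0)
  if (!(s$min <= s$q1 && s$q1 <= s$q2 && s$q2 <= s$q3 && s$q3 <= s$max)) {
    msg <- c(msg, sprintf(
      "quartile ordering min <= q1 <= q2 <= q3 <= max fails (%g, %g, %g, %g, %g)",
      s$min, s$q1, s$q2, s$q3, s$max))
  }
  if (!(s$min <= s$mean && s$mean <= s$max)) {
    msg <- c(msg, sprintf("mean %g outside [min, max] = [%g, %g]",
                          s$mean, s$min, s$max))
  }
  if (s$sd < 0) msg <- c(msg, sprintf("sd %g < 0", s$sd))
  if (!is.na(s$n) && s$n < 1) msg <- c(msg, "n < 1")
  msg
}

#' @export
print.stats_summary <- function(x, ...) {
  cat(sprintf(
    "<stats_summary> q1 %.4g | q2 %.4g | q3 %.4g | mean %.4g | sd %.4g | range [%.4g, %.4g]%s\n",
    x$q1, x$q2, x$q3, x$mean, x$sd, x$min, x$max,
    if (is.na(x$n)) "" else sprintf(" | n = %d", x$n)))
  invisible(x)
}

#' Per-character response profile
#'
#' Couples the amplitude summary (mV) and inter-peak period summary (s) of
#' the spiking response evoked by one projected alphabet character.  The
#' amplitude and period means are the two features the recognition and
#' Boolean-gate stages operate on.
#'
#' @param label Single character `A`-`Z`.
#' @param amplitude,period [stats_summary()] objects in mV and s.
#' @return A `character_profile` object.
#' @export
character_profile <- function(label, amplitude, period) {
  label <- validate_label(label)
  stopifnot(inherits(amplitude, "stats_summary"),
            inherits(period, "stats_summary"))
  structure(list(label = label, amplitude = amplitude, period = period),
            class = "character_profile")
}

#' @export
print.character_profile <- function(x, ...) {
  cat(sprintf("<character_profile> '%s'\n  amplitude (mV): ", x$label))
  print(x$amplitude)
  cat("  period (s):     ")
  print(x$period)
  invisible(x)
}

profile_columns <- c(
  "label",
  paste0("amp_", c("q1", "q2", "q3", "mean", "max", "min", "sd")),
  paste0("per_", c("q1", "q2", "q3", "mean", "max", "min", "sd"))
)

#' Assemble a 26-row profile table
#'
#' @param profiles List of 26 [character_profile()] objects, one per letter
#'   `A`-`Z` (any order; stored alphabetically).
#' @return A `profile_table`: a data frame with one row per letter and
#'   columns `label`, `amp_q1` .. `amp_sd`, `per_q1` .. `per_sd`.
#' @export
profile_table <- function(profiles) {
  labels <- vapply(profiles, function(p) p$label, "")
  missing <- setdiff(LETTERS, labels)
  if (length(missing) > 0L) {
    stop("missing profile: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate profile: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  profiles <- profiles[order(labels)]
  row <- function(p) {
    c(unlist(p$amplitude[c("q1", "q2", "q3", "mean", "max", "min", "sd")]),
      unlist(p$period[c("q1", "q2", "q3", "mean", "max", "min", "sd")]))
  }
  tab <- as.data.frame(do.call(rbind, lapply(profiles, row)))
  names(tab) <- profile_columns[-1L]
  tab <- cbind(data.frame(label = LETTERS, stringsAsFactors = FALSE), tab)
  rownames(tab) <- LETTERS
  class(tab) <- c("profile_table", "data.frame")
  tab
}

#' Load a per-character profile table
#'
#' With no `path`, loads the packaged transcription of the published
#' amplitude and period statistics tables for optical stimulation of the 26
#' alphabet characters.  Custom tables must be CSV with the 15 documented
#' columns (`label` plus 7 amplitude and 7 period statistics, units mV / s).
#'
#' One published row (letter `H`) has a period Q2 exceeding its printed Q3;
#' the packaged table transcribes the publication verbatim, so the default
#' `check = "warn"` reports that row without rejecting the table.
#'
#' @param path CSV path, or `NULL` for the packaged table.
#' @param check Passed to the per-row invariant check: `"warn"` (default),
#'   `"error"` or `"none"`.
#' @return A `profile_table` data frame (26 rows, alphabetical).
#' @export
load_profile_table <- function(path = NULL, check = c("warn", "error", "none")) {
  check <- match.arg(check)
  if (is.null(path)) {
    path <- system.file("extdata", "character_profiles.csv",
                        package = "protospike", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(profile_columns, names(tab))
  if (length(missing_cols) > 0L) {
    stop("profile table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, profile_columns]
  missing <- setdiff(LETTERS, tab$label)
  if (length(missing) > 0L) {
    stop("missing profile: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$label)) {
    stop("duplicate profile: ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  }
  tab <- tab[order(tab$label), ]
  rownames(tab) <- tab$label
  if (check != "none") {
    for (i in seq_len(nrow(tab))) {
      p <- as_character_profile(tab[i, ], check = "none")
      msg <- c(summary_violations(p$amplitude), summary_violations(p$period))
      if (length(msg) > 0L) {
        msg <- paste0("profile table row '", tab$label[i], "': ",
                      paste(msg, collapse = "; "))
        if (check == "error") stop(msg) else warning(msg)
      }
    }
  }
  class(tab) <- c("profile_table", "data.frame")
  tab
}

#' Extract one row of a profile table as a character profile
#'
#' @param row One-row slice of a `profile_table` (or a `profile_table` plus
#'   a `label` to select).
#' @param label Optional letter selecting the row when `row` has several.
#' @param check Invariant handling for the embedded summaries.
#' @return A [character_profile()].
#' @export
as_character_profile <- function(row, label = NULL,
                                 check = c("none", "warn", "error")) {
  check <- match.arg(check)
  if (!is.null(label)) row <- row[row$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("expected exactly one profile row, got ", nrow(row))
  grab <- function(prefix) {
    stats_summary(q1 = row[[paste0(prefix, "_q1")]],
                  q2 = row[[paste0(prefix, "_q2")]],
                  q3 = row[[paste0(prefix, "_q3")]],
                  mean = row[[paste0(prefix, "_mean")]],
                  max = row[[paste0(prefix, "_max")]],
                  min = row[[paste0(prefix, "_min")]],
                  sd = row[[paste0(prefix, "_sd")]],
                  check = check)
  }
  character_profile(row$label, grab("amp"), grab("per"))
}

#' Published microsphere-diameter box statistics
#'
#' Returns the packaged transcription of the published box-plot summary of
#' proteinoid microsphere diameters (nm): quartiles, mean, whisker
#' endpoints and the single flagged outlier.
#'
#' @return Named numeric vector with elements `q1`, `q2`, `q3`, `mean`,
#'   `lower_whisker`, `upper_whisker`, `outlier`.
#' @export
microsphere_boxstats_reference <- function() {
  path <- system.file("extdata", "microsphere_boxstats.csv",
                      package = "protospike", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$value_nm, tab$statistic)
}
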