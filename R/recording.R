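#' Construct a single-channel recording
#'
#' A `recording` is one uniformly sampled channel — electrical potential (mV)
#' or temperature (degrees C) — with an optional stimulus label naming the
#' projected alphabet character.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param values Numeric vector of channel values (mV or degrees C), same
#'   length as `times`, all finite.
#' @param channel_kind `"potential_mV"` or `"temperature_C"`.
#' @param label Optional single character `A`-`Z`, the stimulus identity.
#' @param sampling_interval Sampling interval in seconds; inferred as the
#'   median spacing of `times` when `NULL`.
#'
#' @return An object of class `recording`: a list with fields `times`,
#'   `values`, `channel_kind`, `label` and `sampling_interval`.
#' @export
recording <- function(times, values,
                      channel_kind = c("potential_mV", "temperature_C"),
                      label = NULL, sampling_interval = NULL) {
  channel_kind <- match.arg(channel_kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length (", length(times),
         " vs ", length(values), ")")
  }
  if (any(!is.finite(values))) {
    stop("non-finite value at data row ", which(!is.finite(values))[1L])
  }
  if (length(times) >= 2L) {
    dt <- diff(times)
    bad <- which(dt <= 0)
    if (length(bad) > 0L) {
      stop("non-monotone time at data row ", bad[1L] + 1L)
    }
    if (is.null(sampling_interval)) sampling_interval <- stats::median(dt)
    if (any(abs(dt - sampling_interval) > 1e-6 * abs(sampling_interval))) {
      stop("non-uniform sampling: spacing deviates from sampling interval ",
           format(sampling_interval), " s by more than 1e-6 relative")
    }
  } else if (is.null(sampling_interval)) {
    sampling_interval <- NA_real_
  }
  if (!is.null(label)) {
    label <- validate_label(label)
  }
  structure(
    list(times = times, values = values, channel_kind = channel_kind,
         label = label, sampling_interval = sampling_interval),
    class = "recording"
  )
}

validate_label <- function(label) {
  label <- as.character(label)
  if (length(label) != 1L || !label %in% LETTERS) {
    stop("`label` must be a single character A-Z, got ",
         deparse(substitute(label)), " = ", paste(label, collapse = ","))
  }
  label
}

#' @export
print.recording <- function(x, ...) {
  unit <- if (x$channel_kind == "potential_mV") "mV" else "°C"
  cat(sprintf("<recording> %d samples, %s", length(x$times), x$channel_kind))
  if (!is.null(x$label)) cat(sprintf(", stimulus '%s'", x$label))
  cat("\n")
  if (length(x$times) > 0L) {
    cat(sprintf("  t: %g .. %g s (dt = %g s)\n  v: %g .. %g %s\n",
                x$times[1L], x$times[length(x$times)], x$sampling_interval,
                min(x$values), max(x$values), unit))
  }
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$times)

value_column <- function(channel_kind) {
  switch(channel_kind,
         potential_mV = "potential_mV",
         temperature_C = "temperature_C")
}

#' Read a recording from CSV
#'
#' The dialect is two numeric columns (time in seconds, channel value),
#' comma-separated with dot decimals, an optional single header row, and
#' optional leading `# key: value` metadata lines.  A `# label: X` metadata
#' line supplies the stimulus label unless overridden by the `label`
#' argument.
#'
#' @param path Path to a CSV file.
#' @inheritParams recording
#' @param label Optional stimulus label; overrides any label stored in the
#'   file's metadata lines.
#' @return A validated [recording()].
#' @export
read_recording <- function(path,
                           channel_kind = c("potential_mV", "temperature_C"),
                           label = NULL) {
  channel_kind <- match.arg(channel_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^\\s*#", lines)
  meta <- lines[meta_idx]
  if (is.null(label)) {
    lab_line <- grep("^\\s*#\\s*label\\s*:", meta, value = TRUE)
    if (length(lab_line) > 0L) {
      label <- trimws(sub("^\\s*#\\s*label\\s*:", "", lab_line[1L]))
    }
  }
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("empty recording file: ", path)
  first <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  has_header <- suppressWarnings(is.na(as.numeric(first[1L])))
  data_lines <- if (has_header) body[-1L] else body
  if (length(data_lines) == 0L) {
    return(recording(numeric(0), numeric(0), channel_kind, label = label))
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 2L)) {
    stop("expected two columns (time, value); data row ",
         which(ncol < 2L)[1L], " has ", ncol[which(ncol < 2L)[1L]])
  }
  tt <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  vv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(tt)) stop("non-numeric time at data row ", which(is.na(tt))[1L])
  if (anyNA(vv)) stop("non-numeric value at data row ", which(is.na(vv))[1L])
  recording(tt, vv, channel_kind, label = label)
}

#' Write a recording to CSV
#'
#' Writes the documented dialect: optional `# label: X` metadata line, a
#' header `time_s,<value column>`, then full-precision (17 significant
#' digits) numeric rows, so that a write/read round trip reproduces the
#' recording exactly.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  lines <- character(0)
  if (!is.null(rec$label)) lines <- c(lines, paste0("# label: ", rec$label))
  lines <- c(lines, paste0("time_s,", value_column(rec$channel_kind)))
  if (length(rec$times) > 0L) {
    lines <- c(lines, paste0(sprintf("%.17g", rec$times), ",",
                             sprintf("%.17g", rec$values)))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
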