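# Reading, validation and minute-level aggregation of activity-count
# recordings.
#
# Two plain-CSV schemas are supported:
#   * epoch-level triaxial: subject_id,timestamp,axis1,axis2,axis3
#   * minute-level single axis: subject_id,timestamp,counts
# Timestamps are ISO 8601 and must be strictly regular; vendor multi-line
# metadata headers are not parsed (export/convert to plain CSV first).

#' Construct an activity recording
#'
#' An `activity_recording` holds one subject's regularly sampled triaxial
#' activity counts. Axis 1 is the vertical axis, the only axis used by the
#' downstream scoring; axes 2 and 3 are carried for completeness. Epochs must
#' be contiguous (no gaps) and `epoch_seconds` must divide 60 so that counts
#' can be aggregated into whole minutes.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param start_time `POSIXct` timestamp of the first epoch (UTC assumed).
#' @param epoch_seconds Epoch length in seconds; must divide 60.
#' @param axis_counts Integer matrix with one row per epoch and three columns
#'   (axis1 = vertical, axis2, axis3); all counts must be non-negative.
#' @return An object of class `activity_recording`.
#' @export
activity_recording <- function(subject_id, start_time, epoch_seconds, axis_counts) {
  if (is.character(start_time)) start_time <- parse_iso_time(start_time)
  axis_counts <- as.matrix(axis_counts)
  if (ncol(axis_counts) != 3L) stop("'axis_counts' must have 3 columns (axis1, axis2, axis3)")
  if (nrow(axis_counts) < 1L) stop("recording must contain at least one epoch")
  if (anyNA(axis_counts) || any(axis_counts < 0)) stop("activity counts must be non-negative and non-missing")
  epoch_seconds <- as.integer(epoch_seconds)
  if (epoch_seconds <= 0L || 60L %% epoch_seconds != 0L) {
    stop("'epoch_seconds' must be a positive divisor of 60")
  }
  structure(
    list(subject_id = as.character(subject_id), start_time = start_time,
         epoch_seconds = epoch_seconds,
         axis_counts = matrix(as.numeric(axis_counts), ncol = 3L,
                              dimnames = list(NULL, c("axis1", "axis2", "axis3")))),
    class = "activity_recording")
}

#' Construct a minute-resolution activity series
#'
#' A `minute_series` is the scoring substrate: one non-negative vertical-axis
#' count per minute, contiguous from `start_time`.
#'
#' @param subject_id Character scalar.
#' @param start_time `POSIXct` (or ISO 8601 string) of the first minute.
#' @param counts Numeric vector of non-negative per-minute counts.
#' @return An object of class `minute_series`.
#' @export
minute_series <- function(subject_id, start_time, counts) {
  if (is.character(start_time)) start_time <- parse_iso_time(start_time)
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("series must contain at least one minute")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative and non-missing")
  structure(list(subject_id = as.character(subject_id), start_time = start_time,
                 counts = counts),
            class = "minute_series")
}

#' @export
print.minute_series <- function(x, ...) {
  cat(sprintf("<minute_series> subject %s, %d minutes from %s\n",
              x$subject_id, length(x$counts),
              minutes_to_iso(x$start_time, 0L)))
  invisible(x)
}

#' @export
length.minute_series <- function(x) length(x$counts)

parse_iso_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(out)) stop("unparseable ISO 8601 timestamp: ", x[which(is.na(out))[1]])
  out
}

#' Read an epoch-level triaxial CSV
#'
#' Expects header `subject_id,timestamp,axis1,axis2,axis3`, one row per epoch,
#' ISO 8601 timestamps at a strictly regular interval that divides 60 s.
#' Malformed rows, gapped or irregular timestamps and negative counts are
#' errors, not warnings: scoring assumes contiguity.
#'
#' @param path Path to the CSV file.
#' @return An [activity_recording()].
#' @export
read_epoch_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject_id", "timestamp", "axis1", "axis2", "axis3")
  if (!identical(names(df), required)) {
    stop("expected header ", paste(required, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  }
  counts <- suppressWarnings(vapply(df[c("axis1", "axis2", "axis3")],
                                    as.numeric, numeric(nrow(df))))
  counts <- matrix(counts, ncol = 3L)
  bad <- which(apply(counts, 1L, anyNA))
  if (length(bad)) {
    stop(sprintf("malformed count at line %d of %s", bad[1] + 1L, path))
  }
  if (any(counts < 0)) {
    stop(sprintf("negative count at line %d of %s",
                 which(apply(counts < 0, 1L, any))[1] + 1L, path))
  }
  ts <- parse_iso_time(df$timestamp)
  if (nrow(df) > 1L) {
    deltas <- as.numeric(diff(ts), units = "secs")
    epoch_seconds <- deltas[1]
    if (any(deltas != epoch_seconds)) {
      stop(sprintf("irregular or gapped timestamps near line %d of %s",
                   which(deltas != epoch_seconds)[1] + 2L, path))
    }
  } else {
    epoch_seconds <- 60
  }
  if (epoch_seconds <= 0 || 60 %% epoch_seconds != 0) {
    stop("sampling interval of ", epoch_seconds, " s does not divide 60 s")
  }
  activity_recording(df$subject_id[1], ts[1], epoch_seconds, counts)
}

#' Extract the vertical axis from a recording
#'
#' Wrist-worn devices are most informative about gross physical activity on
#' the vertical axis; scoring uses it exclusively.
#'
#' @param rec An [activity_recording()].
#' @return Numeric vector of per-epoch vertical (axis 1) counts.
#' @export
extract_vertical_axis <- function(rec) {
  stopifnot(inherits(rec, "activity_recording"))
  unname(rec$axis_counts[, 1L])
}

#' Aggregate an epoch recording to minute resolution
#'
#' Sums vertical-axis counts of the sub-minute epochs within each minute. A
#' trailing partial minute is dropped with a warning rather than padded, so
#' the output covers exactly `floor(duration / 60 s)` minutes.
#'
#' @param rec An [activity_recording()].
#' @return A [minute_series()].
#' @export
aggregate_to_minutes <- function(rec) {
  stopifnot(inherits(rec, "activity_recording"))
  v <- extract_vertical_axis(rec)
  per_min <- 60L %/% rec$epoch_seconds
  n_min <- length(v) %/% per_min
  if (n_min < 1L) stop("recording shorter than one full minute")
  dropped <- length(v) - n_min * per_min
  if (dropped > 0L) {
    warning(sprintf("dropping trailing partial minute (%d epoch(s), %d s)",
                    dropped, dropped * rec$epoch_seconds))
  }
  v <- v[seq_len(n_min * per_min)]
  counts <- as.numeric(rowsum(v, rep(seq_len(n_min), each = per_min)))
  minute_series(rec$subject_id, rec$start_time, counts)
}

#' Read a minute-resolution single-axis CSV
#'
#' Expects header `subject_id,timestamp,counts`, one row per minute,
#' contiguous ISO 8601 timestamps.
#'
#' @param path Path to the CSV file.
#' @return A [minute_series()].
#' @export
read_minute_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject_id", "timestamp", "counts")
  if (!identical(names(df), required)) {
    stop("expected header ", paste(required, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  }
  counts <- suppressWarnings(as.numeric(df$counts))
  if (anyNA(counts)) {
    stop(sprintf("malformed count at line %d of %s", which(is.na(counts))[1] + 1L, path))
  }
  ts <- parse_iso_time(df$timestamp)
  if (nrow(df) > 1L && any(as.numeric(diff(ts), units = "secs") != 60)) {
    stop("timestamps are not contiguous minutes in ", path)
  }
  minute_series(df$subject_id[1], ts[1], counts)
}

#' Write a minute series as single-axis CSV
#'
#' @param series A [minute_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(series, path) {
  stopifnot(inherits(series, "minute_series"))
  n <- length(series$counts)
  df <- data.frame(
    subject_id = series$subject_id,
    timestamp = minutes_to_iso(series$start_time, seq_len(n) - 1L),
    counts = series$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
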