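# Rule-based sleep scoring of minute-epoch activity counts.
#
# Definitions implemented here:
#   * candidate row: a minute whose vertical count is at or below the
#     movement threshold, i.e. potentially asleep pending confirmation;
#   * sleep onset: the first minute of a candidate run at least
#     `onset_run_min` minutes long;
#   * sleep awakening: the end of the last candidate run of at least
#     `awakening_run_min` minutes that is followed by `close_movement_min`
#     minutes of movement (or end of recording, flagged as truncated);
#   * bedtime/latency: the maximal sedentary run immediately preceding onset;
#   * WASO: total minutes of within-sleep wake bouts strictly longer than
#     `waso_bout_exclusive_min` minutes;
#   * sleep efficiency: (duration - WASO) / (latency + duration), with >= 85%
#     labelled good-quality sleep.
#
# All indices are 0-based minutes; intervals are half-open [start, end).

#' Scoring configuration
#'
#' Thresholds and run lengths controlling sleep scoring. The defaults encode
#' the standard actigraphy conventions: a 15-minute movement-free run opens a
#' sleep period, a 30-minute movement run closes it, wake bouts strictly
#' longer than 5 minutes count towards WASO, and 85% sleep efficiency
#' separates good from poor sleep.
#'
#' The movement threshold (candidate-row cut-off) is deliberately above zero:
#' sleepers produce micro-movements, and exact-zero runs indicate device
#' removal, not deep sleep. The sedentary threshold used for bedtime
#' inference sits above the movement threshold so that quiet pre-bed
#' wakefulness (reading, screen use) is distinguishable from sleep-level
#' stillness; if the two thresholds coincide, every pre-bed sedentary minute
#' is also a sleep candidate and inferred latency collapses to zero.
#'
#' @param movement_threshold Counts/min at or below which a minute is a sleep
#'   candidate. Default 100.
#' @param sedentary_threshold Counts/min at or below which a pre-bed minute
#'   counts as sedentary for bedtime inference. Default 250.
#' @param onset_run_min Candidate-run length (minutes) opening a sleep
#'   period. Default 15.
#' @param awakening_run_min Candidate-run length (minutes) that can anchor
#'   the awakening time. Default 15.
#' @param close_movement_min Movement-run length (minutes) that closes an
#'   open sleep period. Default 30.
#' @param waso_bout_exclusive_min Wake bouts must be strictly longer than
#'   this many minutes to count towards WASO. Default 5.
#' @param efficiency_good_threshold Sleep-efficiency fraction at or above
#'   which a period is labelled good. Default 0.85.
#' @param nonwear_mode `"naive"` scores nonwear zero-blocks as sleep (they
#'   come out with perfect efficiency); `"exclude"` flags periods overlapping
#'   detected nonwear so downstream dataset construction can drop them.
#' @param nonwear_zero_run_min Minimum run of exact-zero minutes flagged as
#'   nonwear. Default 90.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(movement_threshold = 100,
                           sedentary_threshold = 250,
                           onset_run_min = 15L,
                           awakening_run_min = 15L,
                           close_movement_min = 30L,
                           waso_bout_exclusive_min = 5L,
                           efficiency_good_threshold = 0.85,
                           nonwear_mode = c("naive", "exclude"),
                           nonwear_zero_run_min = 90L) {
  nonwear_mode <- match.arg(nonwear_mode)
  for (nm in c("movement_threshold", "sedentary_threshold", "onset_run_min",
               "awakening_run_min", "close_movement_min",
               "waso_bout_exclusive_min", "nonwear_zero_run_min")) {
    assert_positive_scalar(get(nm), nm)
  }
  if (!(efficiency_good_threshold > 0 && efficiency_good_threshold < 1)) {
    stop("'efficiency_good_threshold' must lie strictly between 0 and 1")
  }
  structure(list(
    movement_threshold = movement_threshold,
    sedentary_threshold = sedentary_threshold,
    onset_run_min = as.integer(onset_run_min),
    awakening_run_min = as.integer(awakening_run_min),
    close_movement_min = as.integer(close_movement_min),
    waso_bout_exclusive_min = as.integer(waso_bout_exclusive_min),
    efficiency_good_threshold = efficiency_good_threshold,
    nonwear_mode = nonwear_mode,
    nonwear_zero_run_min = as.integer(nonwear_zero_run_min)),
    class = "scoring_config")
}

#' Classify candidate (potentially asleep) minutes
#'
#' @param series A [minute_series()].
#' @param cfg A [scoring_config()].
#' @return Logical vector, `TRUE` where the minute's count is at or below the
#'   movement threshold.
#' @export
classify_candidate_rows <- function(series, cfg = scoring_config()) {
  stopifnot(inherits(series, "minute_series"), inherits(cfg, "scoring_config"))
  series$counts <= cfg$movement_threshold
}

#' Detect nonwear intervals
#'
#' Nonwear is flagged as any maximal run of exact-zero counts at least
#' `nonwear_zero_run_min` minutes long: natural sleep contains
#' micro-movements, so a long stretch of literal zeros indicates the device
#' was taken off. In `"naive"` mode the intervals are reported but not used
#' to exclude anything.
#'
#' @param series A [minute_series()].
#' @param cfg A [scoring_config()].
#' @return Data frame with 0-based half-open columns `start`, `end`.
#' @export
detect_nonwear <- function(series, cfg = scoring_config()) {
  stopifnot(inherits(series, "minute_series"), inherits(cfg, "scoring_config"))
  runs <- logical_runs(series$counts == 0)
  runs <- runs[runs$value & (runs$end - runs$start) >= cfg$nonwear_zero_run_min, ,
               drop = FALSE]
  rownames(runs) <- NULL
  runs[c("start", "end")]
}

#' Detect sleep periods with the candidate-row state machine
#'
#' Scans the per-minute candidate classification with a two-state machine.
#' While awake, a candidate run of at least `onset_run_min` minutes opens a
#' sleep period at the run's first minute. While asleep, movement runs
#' shorter than `close_movement_min` minutes are wake bouts inside the
#' period; a movement run of at least `close_movement_min` minutes closes the
#' period at the end of the last candidate run of length at least
#' `awakening_run_min`. End of recording closes an open period at its last
#' candidate minute and marks it truncated (no closing-movement confirmation
#' is possible on the final night of a wear).
#'
#' @param series A [minute_series()].
#' @param cfg A [scoring_config()].
#' @return Data frame with one row per period: 0-based half-open `onset`,
#'   `awakening`, and logical `truncated`. The per-minute sleep/wake
#'   classification within a period is the candidate classification
#'   ([classify_candidate_rows()]) restricted to `[onset, awakening)`.
#' @export
detect_sleep_periods <- function(series, cfg = scoring_config()) {
  cand <- classify_candidate_rows(series, cfg)
  empty <- data.frame(onset = integer(), awakening = integer(), truncated = logical())
  if (length(cand) < cfg$onset_run_min) return(empty)
  runs <- logical_runs(cand)
  onsets <- integer(); awakenings <- integer(); truncated <- logical()
  asleep <- FALSE
  onset <- NA_integer_
  last_qual_end <- NA_integer_  # end of last candidate run >= awakening_run_min
  last_cand_end <- NA_integer_  # end of last candidate run of any length
  for (i in seq_len(nrow(runs))) {
    len <- runs$end[i] - runs$start[i]
    if (!asleep) {
      if (runs$value[i] && len >= cfg$onset_run_min) {
        asleep <- TRUE
        onset <- runs$start[i]
        last_qual_end <- runs$end[i]
        last_cand_end <- runs$end[i]
      }
    } else {
      if (runs$value[i]) {
        last_cand_end <- runs$end[i]
        if (len >= cfg$awakening_run_min) last_qual_end <- runs$end[i]
      } else if (len >= cfg$close_movement_min) {
        onsets <- c(onsets, onset)
        awakenings <- c(awakenings, last_qual_end)
        truncated <- c(truncated, FALSE)
        asleep <- FALSE
      }
    }
  }
  if (asleep) {
    onsets <- c(onsets, onset)
    awakenings <- c(awakenings, last_cand_end)
    truncated <- c(truncated, TRUE)
  }
  data.frame(onset = onsets, awakening = awakenings, truncated = truncated)
}

#' Infer bedtime and latency for a sleep onset
#'
#' Without a self-reported bedtime, bedtime is inferred as the start of the
#' maximal sedentary run (counts at or below the sedentary threshold)
#' immediately preceding and adjacent to sleep onset; its length is the
#' latency. The run never extends into a preceding sleep period.
#'
#' @param series A [minute_series()].
#' @param onset_idx 0-based onset minute from [detect_sleep_periods()].
#' @param cfg A [scoring_config()].
#' @param prev_awakening 0-based awakening (exclusive end) of the previous
#'   sleep period, or 0 if none; the sedentary run is truncated there.
#' @return List with `bedtime_idx` (0-based) and `latency_min`.
#' @export
infer_latency <- function(series, onset_idx, cfg = scoring_config(),
                          prev_awakening = 0L) {
  stopifnot(inherits(series, "minute_series"))
  i <- onset_idx  # bedtime candidate; scan backwards over sedentary minutes
  while (i > prev_awakening && series$counts[i] <= cfg$sedentary_threshold) {
    i <- i - 1L
  }
  list(bedtime_idx = as.integer(i), latency_min = as.integer(onset_idx - i))
}

#' Wake after sleep onset
#'
#' WASO sums the lengths of all maximal wake bouts strictly longer than
#' `waso_bout_exclusive_min` minutes; shorter arousals are ignored as normal
#' sleep fragmentation.
#'
#' @param wake Logical vector over the sleep period's minutes, `TRUE` where
#'   the minute is wake (non-candidate).
#' @param cfg A [scoring_config()].
#' @return WASO in minutes.
#' @export
compute_waso <- function(wake, cfg = scoring_config()) {
  runs <- logical_runs(wake)
  lens <- runs$end - runs$start
  sum(lens[runs$value & lens > cfg$waso_bout_exclusive_min])
}

#' Sleep efficiency
#'
#' The ratio of total minutes asleep to total minutes in bed:
#' `(duration - WASO) / (latency + duration)`.
#'
#' @param duration_min Sleep-period duration (awakening - onset), minutes.
#' @param waso_min WASO, minutes.
#' @param latency_min Latency, minutes.
#' @return Efficiency as a fraction in `[0, 1]`.
#' @export
compute_sleep_efficiency <- function(duration_min, waso_min, latency_min) {
  if (waso_min < 0 || latency_min < 0 || duration_min < waso_min) {
    stop("require duration >= WASO >= 0 and latency >= 0")
  }
  if (duration_min + latency_min <= 0) stop("time in bed is zero; efficiency undefined")
  (duration_min - waso_min) / (latency_min + duration_min)
}

#' Label sleep quality from efficiency
#'
#' Efficiency at or above the threshold (default 85%) is good-quality sleep;
#' below it, poor. The boundary is inclusive: exactly 85% is good.
#'
#' @param efficiency Efficiency fraction(s) in `[0, 1]`.
#' @param cfg A [scoring_config()].
#' @return Character vector, `"good"` or `"poor"`.
#' @export
label_quality <- function(efficiency, cfg = scoring_config()) {
  stopifnot(all(efficiency >= 0 & efficiency <= 1))
  ifelse(efficiency >= cfg$efficiency_good_threshold, "good", "poor")
}

#' Score a recording into fully populated sleep periods
#'
#' Runs the state machine, infers bedtime/latency per period, computes WASO,
#' total sleep time, time in bed, efficiency and the good/poor label, and
#' flags periods overlapping detected nonwear. In `"naive"` mode nonwear
#' zero-blocks are scored like any other candidate run (a full-night zero
#' block therefore scores a perfect efficiency of 1); in `"exclude"` mode
#' flagged periods are retained in the output but marked for downstream
#' exclusion.
#'
#' @param series A [minute_series()].
#' @param cfg A [scoring_config()].
#' @return A data frame of class `sleep_periods`, one row per period, with
#'   0-based minute indices `bedtime`, `onset`, `awakening` (half-open end),
#'   `latency_min`, `duration_min`, `waso_min`, `tst_min`, `tib_min`,
#'   `efficiency`, `label`, `nonwear_flag`, `truncated`. Attributes carry the
#'   subject id, start time and scoring mode.
#' @export
score_recording <- function(series, cfg = scoring_config()) {
  stopifnot(inherits(series, "minute_series"), inherits(cfg, "scoring_config"))
  periods <- detect_sleep_periods(series, cfg)
  cand <- classify_candidate_rows(series, cfg)
  nonwear <- detect_nonwear(series, cfg)
  n <- nrow(periods)
  out <- data.frame(
    subject_id = rep(series$subject_id, n),
    bedtime = integer(n), onset = periods$onset, awakening = periods$awakening,
    latency_min = integer(n), duration_min = periods$awakening - periods$onset,
    waso_min = integer(n), tst_min = integer(n), tib_min = integer(n),
    efficiency = numeric(n), label = character(n),
    nonwear_flag = logical(n), truncated = periods$truncated)
  prev_awakening <- 0L
  for (i in seq_len(n)) {
    lat <- infer_latency(series, periods$onset[i], cfg, prev_awakening)
    wake <- !cand[(periods$onset[i] + 1L):periods$awakening[i]]
    waso <- compute_waso(wake, cfg)
    dur <- out$duration_min[i]
    eff <- compute_sleep_efficiency(dur, waso, lat$latency_min)
    out$bedtime[i] <- lat$bedtime_idx
    out$latency_min[i] <- lat$latency_min
    out$waso_min[i] <- waso
    out$tst_min[i] <- dur - waso
    out$tib_min[i] <- lat$latency_min + dur
    out$efficiency[i] <- eff
    out$label[i] <- label_quality(eff, cfg)
    out$nonwear_flag[i] <- nrow(nonwear) > 0 &&
      any(intervals_overlap(periods$onset[i], periods$awakening[i],
                            nonwear$start, nonwear$end))
    prev_awakening <- periods$awakening[i]
  }
  attr(out, "subject_id") <- series$subject_id
  attr(out, "start_time") <- series$start_time
  attr(out, "nonwear_mode") <- cfg$nonwear_mode
  class(out) <- c("sleep_periods", "data.frame")
  out
}

#' Write scored sleep periods as CSV
#'
#' One row per period with ISO 8601 bedtime/onset/awakening timestamps and
#' efficiency at 4 decimal places.
#'
#' @param periods A `sleep_periods` data frame from [score_recording()].
#' @param path Output path.
#' @param append Append without header (for multi-subject files).
#' @return `path`, invisibly.
#' @export
write_sleep_periods_csv <- function(periods, path, append = FALSE) {
  start_time <- attr(periods, "start_time")
  df <- data.frame(
    subject_id = periods$subject_id,
    bedtime = minutes_to_iso(start_time, periods$bedtime),
    onset = minutes_to_iso(start_time, periods$onset),
    awakening = minutes_to_iso(start_time, periods$awakening),
    latency_min = periods$latency_min, duration_min = periods$duration_min,
    waso_min = periods$waso_min, tst_min = periods$tst_min,
    tib_min = periods$tib_min,
    efficiency = sprintf("%.4f", periods$efficiency),
    label = periods$label, nonwear_flag = periods$nonwear_flag,
    nonwear_mode = attr(periods, "nonwear_mode") %||% "naive")
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}
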