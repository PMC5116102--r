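# Synthetic actigraphy cohort generator with per-night ground truth.
#
# Each subject-day is assembled as
#   [daytime activity][pre-bed sedentary run][sleep block][post-awakening tail]
# where the sleep block contains planted wake bouts sized so that the night's
# realized sleep efficiency lands in its class's range, and the boundary
# minutes are constructed so that the scoring rules recover bedtime, onset,
# awakening and WASO exactly: the minute before the sedentary run is active,
# the sedentary run sits strictly between the movement and sedentary
# thresholds, sleep micro-movements stay at or below the movement threshold,
# planted bouts exceed it, and the first 30 post-awakening minutes are
# active. Optionally a night is replaced by an exact-zero block emulating
# overnight device removal.

sample_int <- function(v) v[sample.int(length(v), 1L)]

#' Simulation configuration for synthetic actigraphy cohorts
#'
#' Defaults emulate a one-week adolescent wrist-actigraphy study: 92
#' subjects, 7 days each, nightly sleep of 6-9 hours, right-skewed daytime
#' counts with occasional low minutes, pre-bed sedentary runs of 10-45
#' minutes, sparse micro-movements during sleep, and a roughly 60/40 mix of
#' good and poor nights.
#'
#' Class signal enters the daytime signal through three interpretable
#' channels, all scaled by `coupling_strength`: nights destined to be good
#' sleep get higher total daytime volume, fewer low-activity (fragmented)
#' minutes and a calmer final two evening hours; poor nights the reverse. At
#' `coupling_strength = 0` the daytime distributions of the two classes are
#' identical, so no classifier can beat chance.
#'
#' @param n_subjects Number of subjects (default 92).
#' @param days_per_subject Recording days per subject (default 7).
#' @param p_good Probability a night is a good-sleep night (default 0.625).
#' @param wake_activity_mean Negative-binomial mean of active daytime
#'   counts/min (default 350).
#' @param wake_dispersion Negative-binomial size parameter (default 1.2).
#' @param wake_low_rate Probability a daytime minute is a low/zero minute
#'   (default 0.15), the fragmentation channel.
#' @param sedentary_run_range Min/max pre-bed sedentary run length, minutes
#'   (default `c(10, 45)`).
#' @param sleep_duration_range Min/max sleep-block length, minutes (default
#'   `c(360, 540)`).
#' @param sleep_micro_movement_rate Probability a sleeping minute has a
#'   nonzero micro-movement count (default 0.15); set 0 for noise-free runs.
#' @param sleep_micro_movement_max Maximum micro-movement count (default 80;
#'   must stay at or below the movement threshold).
#' @param good_se_range,poor_se_range Target sleep-efficiency ranges for the
#'   two classes; they must sit on opposite sides of 0.85.
#' @param coupling_strength Non-negative scale of the daytime/class coupling
#'   (default 0).
#' @param evening_window_min Length of the evening channel window (default
#'   120 minutes before bedtime).
#' @param p_nonwear Probability a night is replaced by an exact-zero
#'   device-removal block (default 0.05).
#' @param movement_threshold,sedentary_threshold Scoring thresholds the
#'   planted counts must respect; keep equal to the [scoring_config()] used
#'   downstream.
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 92L, days_per_subject = 7L,
                       p_good = 0.625,
                       wake_activity_mean = 350, wake_dispersion = 1.2,
                       wake_low_rate = 0.15,
                       sedentary_run_range = c(10L, 45L),
                       sleep_duration_range = c(360L, 540L),
                       sleep_micro_movement_rate = 0.15,
                       sleep_micro_movement_max = 80,
                       good_se_range = c(0.85, 0.98),
                       poor_se_range = c(0.55, 0.85),
                       coupling_strength = 0,
                       evening_window_min = 120L,
                       p_nonwear = 0.05,
                       movement_threshold = 100,
                       sedentary_threshold = 250,
                       seed = 1L) {
  if (good_se_range[1] < 0.85 || poor_se_range[2] > 0.85) {
    stop("class efficiency ranges must sit on opposite sides of 0.85")
  }
  if (sleep_micro_movement_max > movement_threshold) {
    stop("sleep micro-movements must not exceed the movement threshold")
  }
  if (coupling_strength < 0 || p_nonwear < 0 || p_nonwear > 1) {
    stop("'coupling_strength' must be >= 0 and 'p_nonwear' in [0, 1]")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Class-conditional multipliers for the three daytime channels.
coupling_multipliers <- function(label, coupling) {
  s <- if (identical(label, "good")) 1 else -1
  list(volume = exp(0.10 * coupling * s),
       low_rate = exp(-0.25 * coupling * s),
       evening = exp(-0.20 * coupling * s))
}

# Daytime minutes: zero-inflated negative binomial with an evening window.
draw_wake_minutes <- function(n, cfg, mult, evening_tail = 0L) {
  mu <- rep(cfg$wake_activity_mean * mult$volume, n)
  if (evening_tail > 0L && n > 0L) {
    ev <- max(1L, n - evening_tail + 1L):n
    mu[ev] <- mu[ev] * mult$evening
  }
  x <- stats::rnbinom(n, size = cfg$wake_dispersion, mu = mu)
  low <- stats::runif(n) < min(1, cfg$wake_low_rate * mult$low_rate)
  x[low] <- sample.int(61L, sum(low), replace = TRUE) - 1L  # 0..60
  x
}

# Pick the WASO total realizing a class-consistent efficiency for a night of
# duration d and latency l. Feasible WASO totals are 0 or >= 6 (shorter
# bouts never count), capped so bouts fit the block interior.
choose_waso <- function(d, l, label, cfg) {
  rng <- if (identical(label, "good")) cfg$good_se_range else cfg$poor_se_range
  cap <- (d - 2L * 15L) %/% 2L
  w_all <- c(0L, seq(6L, cap))
  se <- (d - w_all) / (l + d)
  ok <- if (identical(label, "good")) se >= rng[1] & se <= rng[2]
        else se >= rng[1] & se < rng[2]
  w_ok <- w_all[ok]
  if (length(w_ok) == 0L) {
    stop(sprintf("no feasible WASO for duration %d, latency %d, class %s", d, l, label))
  }
  target_se <- stats::runif(1, rng[1], min(rng[2], max(se)))
  w_target <- d - target_se * (l + d)
  w_ok[which.min(abs(w_ok - w_target))]
}

# Split a WASO total into bout lengths, each in [6, 25] minutes (shorter
# bouts would not count; 30+ would close the period).
split_into_bouts <- function(w) {
  bouts <- integer()
  rem <- w
  while (rem > 25L) {
    smax <- min(25L, rem - 6L)
    s <- sample_int(6L:smax)
    bouts <- c(bouts, s)
    rem <- rem - s
  }
  if (rem > 0L) bouts <- c(bouts, rem)
  bouts
}

# Build one sleep block of d minutes with planted wake bouts; returns counts
# and the realized WASO. Bouts sit strictly inside [15, d-15) separated by
# at least one sleeping minute.
build_sleep_block <- function(d, waso, cfg) {
  bouts <- if (waso > 0L) split_into_bouts(waso) else integer()
  if (stats::runif(1) < 0.4) bouts <- c(bouts, sample_int(1L:5L))  # decoy, never in WASO
  if (length(bouts) > 1L) bouts <- sample(bouts)
  k <- length(bouts)
  sleep_minute <- function(n) {
    x <- numeric(n)
    mm <- stats::runif(n) < cfg$sleep_micro_movement_rate
    x[mm] <- sample.int(max(1L, cfg$sleep_micro_movement_max), sum(mm), replace = TRUE)
    x
  }
  bout_minute <- function(n) {
    sample.int(500L, n, replace = TRUE) + cfg$movement_threshold + 49L
  }
  if (k == 0L) return(sleep_minute(d))
  interior <- d - 30L
  free <- interior - sum(bouts) - (k - 1L)
  stopifnot(free >= 0L)
  extra <- as.vector(stats::rmultinom(1L, free, rep(1, k + 1L)))
  gaps <- extra + c(0L, rep(1L, k - 1L), 0L)
  counts <- sleep_minute(15L)
  for (i in seq_len(k)) {
    counts <- c(counts, sleep_minute(gaps[i]), bout_minute(bouts[i]))
  }
  c(counts, sleep_minute(gaps[k + 1L]), sleep_minute(15L))
}

#' Generate a synthetic actigraphy cohort with ground truth
#'
#' @param cfg A [sim_config()].
#' @return List with `series` (list of [minute_series()], one per subject)
#'   and `truth`, a data frame with one row per night: `subject_id`, `day`,
#'   0-based `bedtime_idx`, `onset_idx`, `awakening_idx` (half-open end),
#'   `latency_min`, `duration_min`, `waso_min`, `se`, `label`, `nonwear`
#'   (truth fields are `NA` on nonwear nights).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  start_time <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC")
  series <- vector("list", cfg$n_subjects)
  truth <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%03d", s)
    nd <- cfg$days_per_subject
    labels <- ifelse(stats::runif(nd) < cfg$p_good, "good", "poor")
    nonwear <- stats::runif(nd) < cfg$p_nonwear
    counts <- numeric(0)
    for (d in seq_len(nd)) {
      base <- (d - 1L) * 1440L
      l <- sample_int(seq(cfg$sedentary_run_range[1], cfg$sedentary_run_range[2]))
      dur <- sample_int(seq(cfg$sleep_duration_range[1], cfg$sleep_duration_range[2]))
      tail_len <- 30L + sample_int(0L:60L)
      day_len <- 1440L - l - dur - tail_len
      mult <- coupling_multipliers(labels[d], cfg$coupling_strength)
      day <- draw_wake_minutes(day_len, cfg, mult, evening_tail = cfg$evening_window_min)
      # the minute adjacent to the sedentary run must read as active
      day[day_len] <- cfg$sedentary_threshold + 150 + sample_int(0L:400L)
      if (nonwear[d]) {
        # device removed at bedtime: the pre-bed run and the night are a
        # single exact-zero block, which naive scoring rates as perfect sleep
        sed <- numeric(l)
        sleep <- numeric(dur)
        waso <- NA_integer_
      } else {
        sed <- sample.int(cfg$sedentary_threshold - cfg$movement_threshold, l,
                          replace = TRUE) + cfg$movement_threshold
        waso <- choose_waso(dur, l, labels[d], cfg)
        sleep <- build_sleep_block(dur, waso, cfg)
        stopifnot(length(sleep) == dur)
      }
      # next night's class drives the post-awakening tail it belongs to
      tail_mult <- if (d < nd) coupling_multipliers(labels[d + 1L], cfg$coupling_strength)
                   else list(volume = 1, low_rate = 1, evening = 1)
      tail_seg <- draw_wake_minutes(tail_len, cfg, tail_mult)
      tail_seg[seq_len(30L)] <- 300 + sample.int(500L, 30L, replace = TRUE)
      counts <- c(counts, day, sed, sleep, tail_seg)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = sid, day = d,
        bedtime_idx = base + day_len,
        onset_idx = base + day_len + if (nonwear[d]) 0L else l,
        awakening_idx = base + day_len + l + dur,
        latency_min = if (nonwear[d]) 0L else l,
        duration_min = if (nonwear[d]) l + dur else dur,
        waso_min = waso,
        se = if (nonwear[d]) NA_real_ else (dur - waso) / (l + dur),
        label = if (nonwear[d]) NA_character_ else labels[d],
        nonwear = nonwear[d])
    }
    series[[s]] <- minute_series(sid, start_time, counts)
  }
  list(series = series, truth = do.call(rbind, truth), config = cfg)
}

#' Empirical class balance of a generated cohort
#'
#' @param truth Ground-truth data frame from [generate_cohort()].
#' @return Fraction of (worn) nights labelled good.
#' @export
class_balance <- function(truth) {
  lab <- truth$label[!truth$nonwear]
  if (length(lab) == 0L) stop("no worn nights in ground truth")
  mean(lab == "good")
}

#' Write a cohort to minute-epoch CSVs plus a ground-truth JSON
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$series) {
    write_minute_csv(s, file.path(dir, paste0(s$subject_id, ".csv")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}
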