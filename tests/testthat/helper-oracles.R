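# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately re-derive results from the verbatim scoring rules
# by exhaustive index scanning, independently of the package's run-length
# implementation, so agreement is evidence and not tautology.

make_series <- function(counts, subject = "T", start = "2026-01-05T00:00:00") {
  minute_series(subject, start, counts)
}

# Literal rule checker for sleep-period detection. 1-based internally,
# returns 0-based half-open [onset, awakening) like the package.
bf_detect_periods <- function(cand, onset_run = 15L, awaken_run = 15L,
                              close_run = 30L) {
  n <- length(cand)
  res <- data.frame(onset = integer(), awakening = integer())
  pos <- 1L
  while (pos <= n - onset_run + 1L) {
    if (all(cand[pos:(pos + onset_run - 1L)])) {
      onset <- pos
      close_at <- NA_integer_
      j <- onset
      while (j <= n - close_run + 1L) {
        if (all(!cand[j:(j + close_run - 1L)])) { close_at <- j; break }
        j <- j + 1L
      }
      limit <- if (is.na(close_at)) n else close_at - 1L
      # awakening: last index whose trailing awaken_run minutes are all sleep
      e <- NA_integer_
      for (k in seq(limit, onset + awaken_run - 1L)) {
        if (all(cand[(k - awaken_run + 1L):k])) { e <- k; break }
      }
      if (is.na(close_at)) {
        # truncated close: last candidate minute of the open period
        e <- max(which(cand[onset:n])) + onset - 1L
        res <- rbind(res, data.frame(onset = onset - 1L, awakening = e))
        break
      }
      res <- rbind(res, data.frame(onset = onset - 1L, awakening = e))
      pos <- close_at + close_run
    } else {
      pos <- pos + 1L
    }
  }
  res
}

# Brute-force WASO: scan every wake bout by explicit index walking.
bf_waso <- function(wake, exclusive_min = 5L) {
  total <- 0L
  i <- 1L
  n <- length(wake)
  while (i <= n) {
    if (wake[i]) {
      j <- i
      while (j < n && wake[j + 1L]) j <- j + 1L
      if (j - i + 1L > exclusive_min) total <- total + (j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  total
}

# Rank-statistic AUC: P(score_pos > score_neg), ties counted one half.
bf_rank_auc <- function(labels, scores) {
  y <- as.integer(labels)
  sp <- scores[y == 1]; sn <- scores[y == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Random minute counts with roughly even candidate/movement mix at the
# default threshold of 100.
random_counts <- function(n) {
  sample(c(0, 20, 80, 150, 400, 900), n, replace = TRUE,
         prob = c(0.2, 0.15, 0.15, 0.15, 0.2, 0.15))
}

# Tiny labeled instances with a planted mean shift for learnability checks.
toy_instances <- function(n_per_class, len = 60L, gap = 3) {
  out <- list()
  for (i in seq_len(n_per_class)) {
    out[[length(out) + 1L]] <- list(subject_id = "A",
                                    x = stats::rnorm(len, 10 + gap, 1),
                                    label = "good", T = len)
    out[[length(out) + 1L]] <- list(subject_id = "B",
                                    x = stats::rnorm(len, 10 - gap, 1),
                                    label = "poor", T = len)
  }
  out
}

# Score a cohort and pair detected periods with planted truth by onset.
match_truth <- function(cohort, cfg = scoring_config()) {
  rows <- list()
  for (s in cohort$series) {
    sc <- score_recording(s, cfg)
    tr <- cohort$truth[cohort$truth$subject_id == s$subject_id, ]
    for (i in seq_len(nrow(tr))) {
      j <- which.min(abs(sc$onset - tr$onset_idx[i]))
      rows[[length(rows) + 1L]] <- cbind(tr[i, ], data.frame(
        det_onset = sc$onset[j], det_awakening = sc$awakening[j],
        det_latency = sc$latency_min[j], det_waso = sc$waso_min[j],
        det_se = sc$efficiency[j], det_label = sc$label[j],
        det_nonwear = sc$nonwear_flag[j]))
    }
  }
  do.call(rbind, rows)
}

# Shared small cohorts for model tests (built once per test run).
cohort_instances <- function(n_subjects, coupling, seed,
                             cfg = scoring_config(nonwear_mode = "exclude")) {
  co <- generate_cohort(sim_config(n_subjects = n_subjects,
                                   coupling_strength = coupling, seed = seed))
  out <- list()
  for (s in co$series) {
    out <- c(out, segment_awake_pairs(score_recording(s, cfg), s))
  }
  out
}

shuffle_labels <- function(instances, seed) {
  set.seed(seed)
  labs <- sample(vapply(instances, function(z) z$label, character(1)))
  for (i in seq_along(instances)) instances[[i]]$label <- labs[i]
  instances
}

test_auc <- function(instances, arch, seed, max_epochs) {
  split <- stratified_split(instances, seed = seed)
  m <- build_model(model_spec(arch), seed = seed)
  m <- train_model(m, instances[split$train], instances[split$validation],
                   train_config(arch, max_epochs = max_epochs, seed = seed))
  pred <- predict(m, instances[split$test])
  y <- vapply(instances[split$test], function(z) z$label, character(1))
  roc_auc(y, pred$confidence)$auc
}
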