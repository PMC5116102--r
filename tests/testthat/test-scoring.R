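cfg <- scoring_config()

test_that("candidate rows are thresholded at the movement cut-off", {
  s <- make_series(c(500, 3, 0, 800))
  expect_equal(classify_candidate_rows(s, cfg), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(classify_candidate_rows(make_series(rep(300, 20)), cfg)))
  expect_true(all(classify_candidate_rows(make_series(rep(0, 20)), cfg)))
})

test_that("nonwear detection flags long exact-zero runs only", {
  s <- make_series(c(rep(400, 30), rep(0, 120), rep(400, 30)))
  nw <- detect_nonwear(s, cfg)
  expect_equal(nrow(nw), 1L)
  expect_equal(nw$start, 30L)
  expect_equal(nw$end, 150L)

  short <- make_series(c(rep(400, 30), rep(0, 30), rep(400, 30)))
  expect_equal(nrow(detect_nonwear(short, cfg)), 0L)
  expect_equal(nrow(detect_nonwear(make_series(rep(400, 100)), cfg)), 0L)
})

test_that("the state machine finds onset and awakening at the stated runs", {
  expect_equal(nrow(detect_sleep_periods(make_series(rep(500, 600)), cfg)), 0L)

  s <- make_series(c(rep(500, 60), rep(0, 480), rep(500, 60)))
  p <- detect_sleep_periods(s, cfg)
  expect_equal(p$onset, 60L)
  expect_equal(p$awakening, 540L)
  expect_false(p$truncated)

  # a 14-minute run never opens a period; the following 15-run does
  s2 <- make_series(c(rep(500, 60), rep(0, 14), 500, rep(0, 15), rep(500, 40)))
  p2 <- detect_sleep_periods(s2, cfg)
  expect_equal(p2$onset, 75L)
  expect_equal(p2$awakening, 90L)

  # series shorter than the onset run: no periods, no error
  expect_equal(nrow(detect_sleep_periods(make_series(rep(0, 10)), cfg)), 0L)
})

test_that("state machine equals the literal-rule brute force on random series", {
  set.seed(101)
  for (rep_i in 1:400) {
    n <- sample(30:200, 1)
    counts <- random_counts(n)
    s <- make_series(counts)
    mine <- detect_sleep_periods(s, cfg)
    ref <- bf_detect_periods(counts <= cfg$movement_threshold)
    expect_equal(mine$onset, ref$onset)
    expect_equal(mine$awakening, ref$awakening)
  }
})

test_that("latency is the adjacent sedentary run, truncated at prior sleep", {
  # active right up to onset: zero latency
  s <- make_series(c(rep(500, 60), rep(0, 60), rep(500, 60)))
  lat <- infer_latency(s, 60L, cfg)
  expect_equal(lat$latency_min, 0L)
  expect_equal(lat$bedtime_idx, 60L)

  # 20 sedentary minutes (counts 140, above movement, below sedentary cut)
  s2 <- make_series(c(rep(500, 40), rep(140, 20), rep(0, 60), rep(500, 60)))
  lat2 <- infer_latency(s2, 60L, cfg)
  expect_equal(lat2$latency_min, 20L)
  expect_equal(lat2$bedtime_idx, 40L)

  # sedentary run abutting a previous awakening is cut there
  lat3 <- infer_latency(s2, 60L, cfg, prev_awakening = 50L)
  expect_equal(lat3$latency_min, 10L)
})

test_that("WASO counts only bouts strictly longer than five minutes", {
  expect_equal(compute_waso(rep(FALSE, 100), cfg), 0L)
  wake <- c(rep(FALSE, 10), rep(TRUE, 3), rep(FALSE, 10), rep(TRUE, 6),
            rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(compute_waso(wake, cfg), 16L)
  expect_equal(compute_waso(c(rep(FALSE, 20), rep(TRUE, 5), rep(FALSE, 20)), cfg), 0L)
})

test_that("WASO equals brute-force bout enumeration on random sequences", {
  set.seed(77)
  for (i in 1:1000) {
    wake <- stats::runif(sample(5:120, 1)) < stats::runif(1)
    expect_identical(as.integer(compute_waso(wake, cfg)), as.integer(bf_waso(wake)))
  }
})

test_that("sleep efficiency follows the in-bed ratio and its monotonicities", {
  expect_equal(compute_sleep_efficiency(480, 0, 0), 1)
  expect_equal(compute_sleep_efficiency(460, 30, 20), 430 / 480)
  expect_equal(compute_sleep_efficiency(420, 63, 60), 0.74375)
  expect_error(compute_sleep_efficiency(0, 0, 0), "undefined")
  expect_error(compute_sleep_efficiency(10, 20, 0))

  set.seed(9)
  for (i in 1:50) {
    d <- sample(300:540, 1); w <- sample(0:100, 1); l <- sample(0:60, 1)
    e <- compute_sleep_efficiency(d, w, l)
    expect_gte(e, 0); expect_lte(e, 1)
    expect_lt(compute_sleep_efficiency(d, w + 1, l), e)
    expect_lt(compute_sleep_efficiency(d, w, l + 1), e)
  }
})

test_that("quality labelling is inclusive at the 85% boundary", {
  expect_equal(label_quality(0.85, cfg), "good")
  expect_equal(label_quality(0.8499, cfg), "poor")
  expect_equal(label_quality(1.0, cfg), "good")
})

test_that("scored periods are disjoint, ordered, and internally consistent", {
  set.seed(33)
  co <- generate_cohort(sim_config(n_subjects = 3, days_per_subject = 5, seed = 5))
  for (s in co$series) {
    sc <- score_recording(s, cfg)
    expect_true(all(diff(sc$onset) > 0))
    expect_true(all(sc$awakening[-nrow(sc)] <= sc$onset[-1]))
    expect_true(all(sc$awakening - sc$onset >= cfg$onset_run_min))
    expect_equal(sc$latency_min, sc$onset - sc$bedtime)
    expect_equal(sc$tst_min, sc$duration_min - sc$waso_min)
    expect_equal(sc$tib_min, sc$latency_min + sc$duration_min)
    expect_true(all(sc$efficiency >= 0 & sc$efficiency <= 1))
    expect_equal(sc$label, ifelse(sc$efficiency >= 0.85, "good", "poor"))
  }
})

test_that("scoring ignores count magnitude above both thresholds", {
  set.seed(11)
  counts <- random_counts(400)
  scaled <- ifelse(counts > cfg$sedentary_threshold, counts * 4, counts)
  a <- score_recording(make_series(counts), cfg)
  b <- score_recording(make_series(scaled), cfg)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("nonwear zero-blocks score as perfect sleep in naive mode and are flagged in exclude mode", {
  day <- c(rep(600, 480), rep(0, 480), rep(600, 480))
  s <- make_series(day)
  naive <- score_recording(s, scoring_config(nonwear_mode = "naive"))
  expect_equal(naive$efficiency, 1)
  expect_equal(naive$label, "good")
  expect_true(naive$nonwear_flag)

  excl <- score_recording(s, scoring_config(nonwear_mode = "exclude"))
  expect_true(excl$nonwear_flag)
  inst <- segment_awake_pairs(excl, s)
  expect_length(inst, 0L)
})

test_that("sleep-periods CSV export carries ISO timestamps and the scoring mode", {
  s <- make_series(c(rep(500, 120), rep(0, 480), rep(500, 120)))
  sc <- score_recording(s, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sleep_periods_csv(sc, path)
  df <- utils::read.csv(path)
  expect_equal(df$onset, "2026-01-05T02:00:00")
  expect_equal(df$efficiency, 1)
  expect_equal(df$nonwear_mode, "naive")
})
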