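test_that("cohort generation is exactly reproducible from its seed", {
  cfg <- sim_config(n_subjects = 2, days_per_subject = 1, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$series, `[[`, "counts"),
                   lapply(b$series, `[[`, "counts"))
  expect_identical(a$truth, b$truth)
})

test_that("ground truth is consistent with the emitted counts", {
  co <- generate_cohort(sim_config(n_subjects = 4, days_per_subject = 4,
                                   p_nonwear = 0.15, seed = 19))
  for (s in co$series) {
    tr <- co$truth[co$truth$subject_id == s$subject_id, ]
    for (i in seq_len(nrow(tr))) {
      sleep <- s$counts[(tr$onset_idx[i] + 1L):tr$awakening_idx[i]]
      if (tr$nonwear[i]) {
        expect_true(all(sleep == 0))
      } else {
        # within-sleep wake minutes exceed the movement threshold, sleep
        # minutes stay at or below it, and their bouts reproduce the WASO
        wake <- sleep > 100
        expect_equal(bf_waso(wake), tr$waso_min[i])
        # sedentary latency run sits between the two thresholds
        lat <- s$counts[(tr$bedtime_idx[i] + 1L):tr$onset_idx[i]]
        if (tr$latency_min[i] > 0) expect_true(all(lat > 100 & lat <= 250))
        # the minute before bedtime reads active
        expect_gt(s$counts[tr$bedtime_idx[i]], 250)
      }
      expect_equal(tr$se[i],
                   if (tr$nonwear[i]) NA_real_ else
                     (tr$duration_min[i] - tr$waso_min[i]) /
                       (tr$latency_min[i] + tr$duration_min[i]))
    }
  }
})

test_that("planted efficiencies land in the class bands on the right side of 85%", {
  co <- generate_cohort(sim_config(n_subjects = 10, days_per_subject = 7, seed = 23))
  tr <- co$truth[!co$truth$nonwear, ]
  expect_true(all(tr$se[tr$label == "good"] >= 0.85))
  expect_true(all(tr$se[tr$label == "good"] <= 0.98))
  expect_true(all(tr$se[tr$label == "poor"] < 0.85))
  expect_true(all(tr$se[tr$label == "poor"] >= 0.55))
})

test_that("class balance matches the configured mix within binomial error", {
  co <- generate_cohort(sim_config(n_subjects = 58, days_per_subject = 7,
                                   p_good = 0.5, p_nonwear = 0, seed = 29))
  expect_gt(nrow(co$truth), 399)
  expect_gte(class_balance(co$truth), 0.44)
  expect_lte(class_balance(co$truth), 0.56)

  all_good <- generate_cohort(sim_config(n_subjects = 3, p_good = 1, seed = 1))
  expect_equal(class_balance(all_good$truth), 1.0)
  all_poor <- generate_cohort(sim_config(n_subjects = 3, p_good = 0, seed = 1))
  expect_equal(class_balance(all_poor$truth), 0.0)
})

test_that("zero coupling leaves daytime activity independent of the class", {
  co <- generate_cohort(sim_config(n_subjects = 29, days_per_subject = 7,
                                   coupling_strength = 0, p_nonwear = 0, seed = 31))
  means <- list(good = c(), poor = c())
  for (s in co$series) {
    tr <- co$truth[co$truth$subject_id == s$subject_id, ]
    prev <- 0L
    for (i in seq_len(nrow(tr))) {
      awake <- s$counts[(prev + 1L):tr$bedtime_idx[i]]
      means[[tr$label[i]]] <- c(means[[tr$label[i]]], mean(awake))
      prev <- tr$awakening_idx[i]
    }
  }
  se <- sqrt(stats::var(means$good) / length(means$good) +
             stats::var(means$poor) / length(means$poor))
  expect_lt(abs(mean(means$good) - mean(means$poor)), 2 * se)
  expect_gt(length(means$good) + length(means$poor), 199)
})

test_that("coupling strengthens daytime class separation monotonically", {
  auc_of <- function(coupling) {
    co <- generate_cohort(sim_config(n_subjects = 20, days_per_subject = 7,
                                     coupling_strength = coupling,
                                     p_nonwear = 0, seed = 37))
    vols <- c(); labs <- c()
    for (s in co$series) {
      tr <- co$truth[co$truth$subject_id == s$subject_id, ]
      prev <- 0L
      for (i in seq_len(nrow(tr))) {
        vols <- c(vols, mean(s$counts[(prev + 1L):tr$bedtime_idx[i]]))
        labs <- c(labs, tr$label[i])
        prev <- tr$awakening_idx[i]
      }
    }
    roc_auc(labs, vols / max(vols))$auc
  }
  a0 <- auc_of(0); a2 <- auc_of(2)
  expect_gt(a2, a0)
  expect_gt(a2, 0.8)
  expect_lt(abs(a0 - 0.5), 0.12)
})

test_that("infeasible efficiency targets are rejected", {
  expect_error(sim_config(good_se_range = c(0.80, 0.98)), "opposite sides")
  expect_error(sim_config(sleep_micro_movement_max = 150), "micro-movements")
})

test_that("a written cohort feeds back through the readers unchanged", {
  co <- generate_cohort(sim_config(n_subjects = 2, days_per_subject = 1, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_minute_csv(file.path(dir, "S001.csv"))
  expect_equal(back$counts, co$series[[1]]$counts)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(co$truth))
})
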