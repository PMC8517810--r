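test_that("trailing moving average matches direct windowed means", {
  expect_equal(moving_average_2s(rep(70, 500)), rep(70, 301))
  # step 60 -> 80: MA rises linearly across the step
  x <- c(rep(60, 200), rep(80, 200))
  ma <- moving_average_2s(x)
  expect_equal(ma[1], 60)
  expect_equal(ma[201], 80)
  expect_equal(diff(ma), rep(20 / 200, 200))

  set.seed(7)
  x <- rnorm(700, 90, 15)
  expect_equal(moving_average_2s(x), oracle_ma_slow(x), tolerance = 1e-12)
  expect_error(moving_average_2s(rnorm(150)), "shorter")
})

test_that("detect_events equals an independent run scan on random records", {
  th <- label_thresholds()
  for (seed in 1:60) {
    rec <- random_step_record(seed)
    ev <- detect_events(rec, th)
    ma <- oracle_ma(rec$pressure)
    for (kind in c("hypotensive", "nonhypotensive")) {
      cond <- if (kind == "hypotensive") ma < 65 else ma > 75
      want <- oracle_runs(cond, 6000)
      got <- ev[ev$kind == kind, , drop = FALSE]
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        # ma index j is aligned to record sample j + 199
        expect_equal(got$onset_index, want$start + 199L)
        expect_equal(got$end_index, want$end + 199L)
      }
    }
  }
})

test_that("boundary records yield no events", {
  rec <- waveform_record(rep(70, 20000), 100)  # 65 <= 70 <= 75 throughout
  expect_equal(nrow(detect_events(rec)), 0)
  short <- waveform_record(rep(50, 100), 100)  # shorter than the MA window
  expect_equal(nrow(detect_events(short)), 0)
})

test_that("a scheduled dip produces one event and correctly anchored pairs", {
  cfg <- sim_config(n_patients = 1, duration_s = 1400,
                    event_schedule = list(c(800, 120, 55)),
                    noise_sd = 0, seed = 3)
  sim <- simulate_record(cfg, 1)
  ev <- detect_events(sim$record)
  hypo <- ev[ev$kind == "hypotensive", ]
  expect_equal(nrow(hypo), 1)
  gt <- sim$ground_truth$episodes
  expect_equal(nrow(gt), 1)
  # onset within the scheduled dip: at or after the true envelope
  # crossing, at most the moving-average ripple later
  expect_gte(hypo$onset_s, gt$onset_s - 3)
  expect_lte(hypo$onset_s, gt$onset_s + 30)

  pairs <- extract_segment_pairs(sim$record)
  # the input segment ends exactly 300 s before its outcome window
  expect_true(all(pairs$outcome_start_index -
                    (pairs$input_start_index + 2000) == 30000))
  # event-anchored pair present: input = [onset - 320 s, onset - 300 s)
  anchor <- pairs[pairs$outcome_start_index == hypo$onset_index, ]
  expect_equal(nrow(anchor), 1)
  expect_equal(anchor$label, "positive")
  expect_equal(anchor$input_start_s, hypo$onset_s - 320)
  # label trichotomy
  expect_true(all(pairs$label %in% c("positive", "negative",
                                     "indeterminate")))
})

test_that("early events are skipped when the input would precede the record", {
  # a dip whose onset is at 250 s: input would start at -70 s
  cfg <- sim_config(n_patients = 1, duration_s = 600, predrift_s = 120,
                    event_schedule = list(c(250, 120, 55)),
                    noise_sd = 0, seed = 5)
  sim <- simulate_record(cfg, 1)
  pairs <- extract_segment_pairs(sim$record)
  expect_gt(attr(pairs, "n_skipped"), 0)
  expect_true(all(pairs$input_start_index >= 1))
})

test_that("lowering the hypotension threshold never adds positives", {
  for (seed in 1:10) {
    rec <- random_step_record(seed, duration_s = 500)
    n_pos <- function(hypo) {
      p <- extract_segment_pairs(rec, label_thresholds(hypo_map = hypo))
      sum(p$label == "positive")
    }
    expect_lte(n_pos(60), n_pos(65))
  }
})

test_that("patient split is disjoint, deterministic and leakage-free", {
  ids <- sprintf("p%02d", 1:10)
  sp <- split_patients(ids, 0.7, seed = 9)
  expect_length(sp$train, 7)
  expect_length(sp$validation, 3)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(sp, split_patients(ids, 0.7, seed = 9))
  expect_false(identical(sp, split_patients(ids, 0.7, seed = 10)))
  expect_error(split_patients(ids, 1.2), "between 0 and 1")
  expect_error(split_patients("p1"), "at least 2")

  # every segment inherits its patient's fold
  seg_pat <- sample(ids, 200, replace = TRUE)
  fold <- ifelse(seg_pat %in% sp$train, "train", "validation")
  for (id in ids) {
    expect_length(unique(fold[seg_pat == id]), 1)
  }
})
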