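test_that("the simulator is deterministic and honours its schedule", {
  cfg <- sim_config(n_patients = 1, duration_s = 400,
                    event_schedule = list(c(250, 80, 55)),
                    predrift_s = 120, noise_sd = 0.5, seed = 21)
  a <- simulate_record(cfg, 1)
  b <- simulate_record(cfg, 1)
  expect_identical(a$record$pressure, b$record$pressure)
  expect_identical(a$ground_truth, b$ground_truth)
  # different patients differ
  c2 <- simulate_record(cfg, 2)
  expect_false(identical(a$record$pressure, c2$record$pressure))
})

test_that("a dip-free record never approaches the hypotension threshold", {
  cfg <- sim_config(n_patients = 1, duration_s = 600,
                    event_schedule = list(), baseline_map_range = c(88, 92),
                    noise_sd = 0.5, seed = 2)
  sim <- simulate_record(cfg, 1)
  ma <- moving_average_2s(sim$record$pressure)
  expect_gt(min(ma), 75)
  expect_equal(nrow(sim$ground_truth$episodes), 0)
})

test_that("a scheduled dip below 65 yields exactly one true episode", {
  cfg <- sim_config(n_patients = 1, duration_s = 900,
                    event_schedule = list(c(500, 120, 55)),
                    noise_sd = 0, seed = 9)
  sim <- simulate_record(cfg, 1)
  expect_equal(nrow(sim$ground_truth$episodes), 1)
  expect_true(sim$ground_truth$episodes$end_s -
                sim$ground_truth$episodes$onset_s >= 60)
  # episodes are sorted and non-overlapping by construction of the runs
  eps <- sim$ground_truth$episodes
  if (nrow(eps) > 1) {
    expect_true(all(diff(eps$onset_s) > 0))
    expect_true(all(eps$onset_s[-1] >= eps$end_s[-nrow(eps)]))
  }
})

test_that("a schedule extending past the record is rejected", {
  expect_error(sim_config(duration_s = 300,
                          event_schedule = list(c(250, 100, 55))),
               "extends past")
})

test_that("artifact injection is a logged no-op at rate zero", {
  cfg <- sim_config(n_patients = 1, duration_s = 120,
                    event_schedule = list(), seed = 3)
  sim <- simulate_record(cfg, 1)
  out <- inject_artifacts(sim$record, cfg)
  expect_identical(out$record$pressure, sim$record$pressure)
  expect_equal(nrow(out$log), 0)
})

test_that("each injected artifact class trips its screening criterion", {
  cfg <- sim_config(n_patients = 1, duration_s = 1200,
                    event_schedule = list(), artifact_rate = 6,
                    seed = 31)
  sim <- simulate_record(cfg, 1)
  out <- inject_artifacts(sim$record, cfg)
  expect_gt(nrow(out$log), 0)
  expect_true(all(out$log$type %in% c("missing", "spike", "flat", "jump")))
  trip <- c(missing = "MISSING", spike = "RANGE", flat = "FLAT",
            jump = "JUMP")
  p <- out$record$pressure
  for (i in seq_len(nrow(out$log))) {
    span <- out$log$start_index[i]:(out$log$end_index[i] - 1L)
    # a 20-s window centred on the artifact must fail screening; for
    # flats the window must lie fully inside the injected stretch
    win <- if (out$log$type[i] == "flat") {
      span[1]:(span[1] + 1999L)
    } else {
      s <- max(1L, span[1] - 1000L)
      s:(s + 1999L)
    }
    if (max(win) > length(p)) next
    res <- check_segment(p[win])
    expect_false(res$valid)
    if (out$log$type[i] == "flat") {
      expect_true("FLAT" %in% res$violations)
    }
  }
})

test_that("cohorts are written deterministically with a complete manifest", {
  cfg <- sim_config(n_patients = 3, duration_s = 120,
                    event_schedule = list(), seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- simulate_cohort(cfg, d1)
  m2 <- simulate_cohort(cfg, d2)
  expect_equal(nrow(m1$manifest), 3)
  expect_true(all(file.exists(m1$manifest$path)))
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  # identical cohort content across runs
  m1$manifest$path <- basename(m1$manifest$path)
  m2$manifest$path <- basename(m2$manifest$path)
  expect_identical(m1$manifest, m2$manifest)
  expect_identical(read_record(file.path(d1, "p0002.abp"))$pressure,
                   read_record(file.path(d2, "p0002.abp"))$pressure)

  # empty cohort is not an error
  m0 <- simulate_cohort(sim_config(n_patients = 0, duration_s = 60,
                                   event_schedule = list()), tempfile())
  expect_equal(nrow(m0$manifest), 0)
})

test_that("segments before positive onsets sit lower than negative segments", {
  # learnability of the five-minute-ahead task: population mean of the
  # 20-s inputs preceding positives is strictly below the negatives'
  cfg <- small_pipeline_config(seed = 5, n_patients = 12)
  dir <- tempfile()
  simulate_cohort(cfg$sim, file.path(dir, "records"))
  ds <- build_dataset(cfg, file.path(dir, "records"))
  expect_gt(length(ds$y), 400)
  expect_true(all(c(0, 1) %in% ds$y))
  mean_pos <- mean(rowMeans(ds$x_cnn[ds$y == 1, ]))
  mean_neg <- mean(rowMeans(ds$x_cnn[ds$y == 0, ]))
  expect_lt(mean_pos, mean_neg)
  # and the class-conditional feature ordering matches clinical data:
  # lower MAP, shorter beats, higher pulse-pressure variation
  f <- ds$features
  expect_lt(mean(f[ds$y == 1, "map_avg"]), mean(f[ds$y == 0, "map_avg"]))
  expect_lt(mean(f[ds$y == 1, "mean_beat_length"]),
            mean(f[ds$y == 0, "mean_beat_length"]))
  expect_gt(mean(f[ds$y == 1, "ppv"]), mean(f[ds$y == 0, "ppv"]))
})
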