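test_that("beat matrix is always 30 x 100 with front-loaded zero padding", {
  for (hr in seq(40, 150, by = 10)) {
    fx <- sim_clean_segment(seed = hr, hr = c(hr, hr), noise_sd = 0.3)
    pp <- preprocess_segment(fx$segment)
    expect_identical(dim(pp$matrix), c(30L, 100L))
    k <- attr(pp$matrix, "n_real_beats")
    expect_true(k >= 1 && k <= 30)
    if (k < 30) {
      expect_true(all(pp$matrix[seq_len(30 - k), ] == 0))
    }
    # zero rows never appear after a real-beat row
    zero_row <- rowSums(pp$matrix != 0) == 0
    if (any(zero_row) && any(!zero_row)) {
      expect_lt(max(which(zero_row)), min(which(!zero_row)))
    }
    expect_true(all(pp$matrix >= 0 & pp$matrix <= 1))
  }
})

test_that("detected beat counts track the simulator's ground truth", {
  for (seed in 1:15) {
    hr <- sample(seq(50, 140, 10), 1)
    fx <- sim_clean_segment(seed = seed * 3, hr = c(hr, hr), noise_sd = 0.3)
    b <- detect_beats(fx$segment)
    feet <- fx$gt$feet
    lo <- fx$from; hi <- fx$from + 1999
    inside <- feet[feet >= lo & feet <= hi]
    # complete ground-truth cycles inside the window
    gt_n <- sum(inside[-length(inside)] >= lo & inside[-1] <= hi + 1)
    expect_lte(abs(nrow(b) - gt_n), 1)
  }
})

test_that("degenerate segments are reported as unsliceable", {
  expect_error(detect_beats(rep(80, 2000)), "unsliceable")
  expect_error(detect_beats(seq(40, 180, length.out = 2000)), "unsliceable")
})

test_that("beat interpolation matches a direct piecewise-linear oracle", {
  # length-100 beat: endpoints preserved exactly
  beat <- sin(seq(0, pi, length.out = 100)) * 40 + 70
  out <- normalize_beat(beat)
  expect_equal(out[1], beat[1])
  expect_equal(out[100], beat[100])
  # a linear ramp stays linear
  ramp <- seq(60, 100, length.out = 80)
  out <- normalize_beat(ramp)
  expect_equal(out, seq(60, 100, length.out = 100), tolerance = 1e-12)
  # arbitrary beat equals an independent interpolation oracle
  set.seed(4)
  for (len in c(2, 7, 55, 130)) {
    beat <- runif(len, 50, 130)
    xout <- seq(1, len, length.out = 100)
    want <- vapply(xout, function(x) {
      i <- min(floor(x), len - 1)
      beat[i] + (x - i) * (beat[i + 1] - beat[i])
    }, numeric(1))
    expect_equal(normalize_beat(beat), want, tolerance = 1e-9)
  }
  expect_error(normalize_beat(5), "at least 2")
})

test_that("pre-truncation keeps the newest beats, pre-padding leads with zeros", {
  mk <- function(v) rep(v, 100)  # constant beat at level v
  beats20 <- lapply(1:20, function(i) mk(20 + i))  # scale_values -> i/180
  m <- build_beat_matrix(beats20)
  expect_true(all(m[1:10, ] == 0))
  expect_equal(m[11, 1], 1 / 180)
  expect_equal(m[30, 1], 20 / 180)
  expect_equal(attr(m, "n_real_beats"), 20)

  beats35 <- lapply(1:35, function(i) mk(20 + i))
  m <- build_beat_matrix(beats35)
  expect_equal(attr(m, "n_real_beats"), 30)
  expect_equal(m[1, 1], 6 / 180)    # oldest retained beat is number 6
  expect_equal(m[30, 1], 35 / 180)  # newest beat is last

  beats30 <- lapply(1:30, function(i) mk(20 + i))
  m <- build_beat_matrix(beats30)
  expect_equal(m[, 1], (1:30) / 180)
  expect_error(build_beat_matrix(list()), "no beats")
})

test_that("waveform scaling is the fixed affine map anchored at 20/200", {
  expect_equal(scale_values(20), 0)
  expect_equal(scale_values(200), 1)
  expect_equal(scale_values(110), 0.5)
  # clipped outside the anchors, strictly monotone inside
  expect_equal(scale_values(c(10, 250)), c(0, 1))
  x <- seq(20, 200, length.out = 500)
  expect_true(all(diff(scale_values(x)) > 0))
})

test_that("un-scaled beat means recover the true per-beat pressure level", {
  for (seed in c(2, 12, 22)) {
    fx <- sim_clean_segment(seed = seed, noise_sd = 0)
    pp <- preprocess_segment(fx$segment)
    bmeans <- vapply(seq_len(nrow(pp$boundaries)), function(i) {
      mean(fx$segment[pp$boundaries$start[i]:(pp$boundaries$end[i] - 1L)])
    }, numeric(1))
    env_at_feet <- fx$env[pp$boundaries$start]
    expect_lt(max(abs(bmeans - env_at_feet)), 1)
  }
})
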