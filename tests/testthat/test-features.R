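# two hand-built rectangular beats: constant level for exactly 1 s each
rect_two_beats <- function(l1 = 100, l2 = 100) {
  seg <- c(rep(l1, 100), rep(l2, 100), l1)
  bounds <- data.frame(start = c(1L, 101L), end = c(101L, 201L),
                       peak = c(1L, 101L))
  list(segment = seg, bounds = bounds)
}

test_that("pulse-pressure variation follows the printed formula", {
  # equal pulse pressures (40 and 40) give PPV exactly 0
  seg <- c(rep(80, 40), rep(120, 40), rep(70, 40), rep(110, 40), 70)
  bounds <- data.frame(start = c(1L, 81L), end = c(81L, 161L),
                       peak = c(41L, 121L))
  f <- extract_features(seg, bounds)
  expect_equal(unname(f["pp_max"]), 40)
  expect_equal(unname(f["pp_min"]), 40)
  expect_equal(unname(f["ppv"]), 0)

  # PP 60 and 40 -> PPV = (60 - 40) * 2 / (60 + 40) = 0.4 exactly
  seg <- c(rep(60, 40), rep(120, 40), rep(70, 40), rep(110, 40), 60)
  f <- extract_features(seg, bounds)
  expect_identical(unname(f["ppv"]), 0.4)
  expect_equal(unname(f["pp_range"]), unname(f["pp_max"] - f["pp_min"]))
})

test_that("a constant 1-s beat has area 100 mmHg*s and MAP 100", {
  fx <- rect_two_beats()
  f <- extract_features(fx$segment, fx$bounds)
  expect_equal(unname(f["beat_area_avg"]), 100)
  expect_equal(unname(f["map_avg"]), 100)
  expect_equal(unname(f["mean_beat_length"]), 1)
})

test_that("PPV is invariant to a common pressure scale factor", {
  fx <- sim_clean_segment(8)
  b <- detect_beats(fx$segment)
  f1 <- extract_features(fx$segment, b)
  f2 <- extract_features(fx$segment * 1.3, b)
  expect_equal(unname(f1["ppv"]), unname(f2["ppv"]), tolerance = 1e-12)
})

test_that("every feature matches a per-beat brute-force recomputation", {
  fs <- 100
  for (seed in 1:25) {
    fx <- sim_clean_segment(seed * 7)
    b <- detect_beats(fx$segment)
    f <- extract_features(fx$segment, b)
    seg <- fx$segment
    per <- lapply(seq_len(nrow(b)), function(i) {
      cyc <- seg[b$start[i]:(b$end[i] - 1L)]
      full <- seg[b$start[i]:b$end[i]]
      list(sys = max(cyc), dia = min(cyc), pp = max(cyc) - min(cyc),
           map = mean(cyc), len = (b$end[i] - b$start[i]) / fs,
           st = (b$peak[i] - b$start[i]) / fs,
           area = sum(diff(seq_along(full) / fs) *
                        (head(full, -1) + tail(full, -1)) / 2))
    })
    g <- function(x) vapply(per, `[[`, numeric(1), x)
    want <- c(mean_beat_length = mean(g("len")), map_avg = mean(g("map")),
              pp_max = max(g("pp")), pp_min = min(g("pp")),
              pp_range = max(g("pp")) - min(g("pp")),
              pp_avg = mean(g("pp")),
              ppv = (max(g("pp")) - min(g("pp"))) * 2 /
                (max(g("pp")) + min(g("pp"))),
              systolic_time_avg = mean(g("st")),
              systolic_pressure_avg = mean(g("sys")),
              systolic_pressure_range = max(g("sys")) - min(g("sys")),
              diastolic_pressure_avg = mean(g("dia")),
              beat_area_avg = mean(g("area")))
    expect_equal(f, want, tolerance = 1e-9)
  }
})

test_that("segments with fewer than two beats are dropped", {
  expect_error(extract_features(rep(80, 100),
                                data.frame(start = 1L, end = 50L,
                                           peak = 10L)),
               "fewer than 2")
})

test_that("robust scaling centres on training medians and uses the IQR", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(10, 10, 10, 10, 10))
  sc <- fit_robust_scaler(x)
  # linear-interpolation quartile convention
  expect_equal(unname(sc$q1["a"]), 2)
  expect_equal(unname(sc$q2["a"]), 3)
  expect_equal(unname(sc$q3["a"]), 4)
  out <- apply_scaler(sc, x)
  expect_equal(unname(out[3, "a"]), 0)              # x = Q2 -> 0
  expect_equal(unname(out[4, "a"]), (4 - 3) / (4 - 2))  # x = Q3
  # degenerate feature flagged, scaled to zero
  expect_true(sc$degenerate["b"])
  expect_true(all(out[, "b"] == 0))
  expect_error(fit_robust_scaler(x[1:3, ]), "at least 4")
})

test_that("scaled training medians are zero and shifts cancel", {
  set.seed(13)
  x <- matrix(rnorm(400, 50, 8), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  sc <- fit_robust_scaler(x)
  med <- apply(apply_scaler(sc, x), 2, stats::median)
  expect_true(all(abs(med) < 1e-12))
  # translation invariance: shifting inputs before fitting changes nothing
  x2 <- x + 17.3
  out2 <- apply_scaler(fit_robust_scaler(x2), x2)
  expect_equal(out2, apply_scaler(sc, x), tolerance = 1e-9)
  # random table matches the one-line formula
  want <- sweep(sweep(x, 2, sc$q2, "-"), 2, sc$q3 - sc$q1, "/")
  expect_equal(apply_scaler(sc, x), want, tolerance = 1e-12)
  # feature-name mismatch is an error
  colnames(x2) <- paste0("g", 1:4)
  expect_error(apply_scaler(sc, x2), "mismatch")
})
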