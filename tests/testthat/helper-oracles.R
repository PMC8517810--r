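# Independent brute-force oracles and small fixture builders shared by
# the tests. These deliberately avoid the package's own code paths.

# trailing moving average via stats::filter (independent of the cumsum
# implementation in moving_average_2s)
oracle_ma <- function(x, w = 200) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[w:length(x)]
}

# direct windowed mean, O(n * w); for small inputs only
oracle_ma_slow <- function(x, w = 200) {
  vapply(w:length(x), function(i) mean(x[(i - w + 1):i]), numeric(1))
}

# maximal runs of TRUE with length >= min_run, found by index splitting
# (independent of the rle-based scan in the package)
oracle_runs <- function(cond, min_run) {
  cond[is.na(cond)] <- FALSE
  idx <- which(cond)
  if (!length(idx)) return(data.frame(start = integer(0), end = integer(0)))
  grp <- cumsum(c(1L, diff(idx) != 1L))
  out <- do.call(rbind, lapply(split(idx, grp), function(ii) {
    data.frame(start = ii[1], end = ii[length(ii)] + 1L)
  }))
  out <- out[out$end - out$start >= min_run, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sample-by-sample artifact predicate scan (plain loop, independent of
# the vectorized check_segment)
oracle_qc <- function(v) {
  miss <- FALSE; range_v <- FALSE; jump <- FALSE
  mx <- -Inf; mn <- Inf
  prev <- NA_real_
  for (x in v) {
    if (is.na(x)) {
      miss <- TRUE
      prev <- NA_real_
      next
    }
    if (x > 200 || x < 20) range_v <- TRUE
    if (x > mx) mx <- x
    if (x < mn) mn <- x
    if (!is.na(prev) && abs(x - prev) > 30) jump <- TRUE
    prev <- x
  }
  out <- character(0)
  if (miss) out <- c(out, "MISSING")
  if (range_v) out <- c(out, "RANGE")
  if (is.finite(mx) && mx - mn < 20) out <- c(out, "FLAT")
  if (jump) out <- c(out, "JUMP")
  out
}

# average precision by explicit enumeration of PR points at every
# unique threshold (descending)
oracle_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  p_total <- sum(labels)
  ap <- 0; prev_tp <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    ap <- ap + (tp - prev_tp) / p_total * (tp / sum(sel))
    prev_tp <- tp
  }
  ap
}

# AUROC by exhaustive pairwise comparison, ties counted one half
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# piecewise-constant random pressure trace (for labeling oracle tests):
# steps between hypotensive / intermediate / normotensive levels
random_step_record <- function(seed, duration_s = 150) {
  set.seed(seed)
  n <- duration_s * 100
  p <- numeric(0)
  while (length(p) < n) {
    lvl <- sample(c(55, 62, 70, 78, 90), 1)
    len <- sample(500:9000, 1)
    p <- c(p, rep(lvl, len) + stats::rnorm(len, 0, 0.5))
  }
  waveform_record(p[1:n], 100, patient_id = paste0("step", seed))
}

# one clean pulsatile 20-s segment from the simulator, plus its ground
# truth
sim_clean_segment <- function(seed, hr = c(60, 110), noise_sd = 0.5,
                              from = 1001) {
  cfg <- sim_config(n_patients = 1, duration_s = 60,
                    event_schedule = list(), hr_range = hr,
                    noise_sd = noise_sd, seed = seed)
  sim <- simulate_record(cfg, 1)
  idx <- from:(from + 1999)
  list(segment = sim$record$pressure[idx],
       gt = sim$ground_truth, from = from,
       env = sim$ground_truth$map[idx])
}
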