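#' Event-labeling thresholds
#'
#' A hypotensive event is a stretch where the 2-second trailing moving
#' average of arterial pressure stays under `hypo_map` (65 mmHg) for at
#' least `event_min_duration` (60 s); a nonhypotensive (negative)
#' stretch keeps the moving average over `normo_map` (75 mmHg) for at
#' least 60 s. Each 60-s outcome window is paired with the 20-s input
#' segment whose end precedes the outcome window's start by `horizon`
#' (300 s), so a positive prediction is a true five-minute warning.
#'
#' @param hypo_map Hypotension threshold on the moving average, mmHg.
#' @param normo_map Normotension threshold on the moving average, mmHg.
#' @param ma_window Moving-average window, seconds (default 2).
#' @param event_min_duration Minimum event duration, seconds (default 60).
#' @param horizon Prediction horizon, seconds (default 300).
#' @param input_len Input segment length, seconds (default 20).
#' @param outcome_len Outcome window length, seconds (default 60).
#' @return An object of class `label_thresholds`.
#' @export
label_thresholds <- function(hypo_map = 65, normo_map = 75, ma_window = 2,
                             event_min_duration = 60, horizon = 300,
                             input_len = 20, outcome_len = 60) {
  stopifnot(horizon > 0, hypo_map < normo_map, ma_window > 0,
            event_min_duration > 0, input_len > 0, outcome_len > 0)
  structure(list(hypo_map = hypo_map, normo_map = normo_map,
                 ma_window = ma_window,
                 event_min_duration = event_min_duration,
                 horizon = horizon, input_len = input_len,
                 outcome_len = outcome_len),
            class = "label_thresholds")
}

#' Trailing 2-second moving average
#'
#' Causal (trailing) mean over `window_s * fs` samples: output element
#' `j` is the mean of input samples `j .. j + w - 1`, i.e. the moving
#' average aligned to input index `j + w - 1` (its most recent sample).
#' The output has `length(values) - w + 1` elements. A trailing window
#' is used so the labeling is computable in real time.
#'
#' @param values Pressure sequence at `fs` Hz. Missing values propagate:
#'   any window containing `NA` yields `NA`.
#' @param fs Sampling rate, Hz (default 100).
#' @param window_s Window length in seconds (default 2).
#' @return Numeric vector of windowed means.
#' @export
moving_average_2s <- function(values, fs = 100, window_s = 2) {
  w <- as.integer(round(window_s * fs))
  n <- length(values)
  if (n < w) stop("input shorter than the ", window_s, "-s window (", w,
                  " samples)")
  if (anyNA(values)) {
    # cumsum would poison everything after the first NA
    out <- as.numeric(stats::filter(values, rep(1 / w, w), sides = 1))
    return(out[w:n])
  }
  cs <- cumsum(values)
  (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
}

#' Detect hypotensive and nonhypotensive events in a record
#'
#' Scans the 2-s moving average for maximal contiguous runs under
#' `hypo_map` (hypotensive) or over `normo_map` (nonhypotensive) lasting
#' at least `event_min_duration`. Each maximal qualifying run is
#' reported once; `onset_index` is the record sample index (1-based) to
#' which the first qualifying moving-average value is aligned, and
#' `end_index` is one past the last (half-open).
#'
#' @param record A [waveform_record()] at 100 Hz.
#' @param thresholds A [label_thresholds()] object.
#' @return A data frame with columns `kind`
#'   (`"hypotensive"`/`"nonhypotensive"`), `onset_index`, `end_index`,
#'   `onset_s`, `end_s`, sorted by onset. Zero rows when the record is
#'   too short or has no qualifying run.
#' @export
detect_events <- function(record, thresholds = label_thresholds()) {
  stopifnot(inherits(record, "waveform_record"), record$sampling_rate == 100)
  fs <- 100
  w <- as.integer(round(thresholds$ma_window * fs))
  empty <- data.frame(kind = character(0), onset_index = integer(0),
                      end_index = integer(0), onset_s = numeric(0),
                      end_s = numeric(0))
  if (length(record$pressure) < w) return(empty)
  ma <- moving_average_2s(record$pressure, fs = fs,
                          window_s = thresholds$ma_window)
  min_run <- as.integer(round(thresholds$event_min_duration * fs))
  ev <- rbind(
    .ma_runs(ma < thresholds$hypo_map, min_run, "hypotensive"),
    .ma_runs(ma > thresholds$normo_map, min_run, "nonhypotensive")
  )
  if (nrow(ev) == 0) return(empty)
  # ma[j] is aligned to record index j + w - 1
  ev$onset_index <- ev$onset_index + w - 1L
  ev$end_index <- ev$end_index + w - 1L
  ev$onset_s <- record$t0 + (ev$onset_index - 1L) / fs
  ev$end_s <- record$t0 + (ev$end_index - 1L) / fs
  ev[order(ev$onset_index), , drop = FALSE]
}

# Maximal TRUE runs of length >= min_run in a logical vector (NA = FALSE).
.ma_runs <- function(cond, min_run, kind) {
  cond[is.na(cond)] <- FALSE
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(kind = rep(kind, sum(keep)),
             onset_index = starts[keep],
             end_index = ends[keep] + 1L)  # half-open
}

#' Enumerate labeled input/outcome segment pairs for a record
#'
#' Candidate 60-s outcome windows are enumerated on a `stride_s` grid
#' and additionally at every detected event onset. A window is labeled
#' `"positive"` when the moving average stays under `hypo_map`
#' throughout (it begins a qualifying hypotensive run), `"negative"`
#' when it stays over `normo_map` throughout, and `"indeterminate"`
#' otherwise. Each outcome window is paired with the 20-s input segment
#' ending `horizon` seconds before the window starts. Pairs whose input
#' would begin before the record start are skipped and counted; pairs
#' failing artifact screening on either window are retained in the
#' table with `qc_ok = FALSE` but excluded from model data
#' (`usable = FALSE`); indeterminate pairs are likewise retained but
#' unusable.
#'
#' @param record A [waveform_record()] at 100 Hz.
#' @param thresholds A [label_thresholds()] object.
#' @param stride_s Enumeration stride in seconds (default 20,
#'   non-overlapping inputs).
#' @param qc A [qc_thresholds()] object.
#' @return A data frame with columns `patient_id`, `input_start_index`,
#'   `outcome_start_index` (1-based sample indices), `input_start_s`,
#'   `outcome_start_s`, `label`, `qc_input`, `qc_outcome` (violation
#'   code strings, `""` when clean), `qc_ok`, `usable`. The attribute
#'   `n_skipped` counts windows whose input fell before the record
#'   start. The invariant
#'   `outcome_start_index - (input_start_index + 2000) == 30000` holds
#'   for every row.
#' @export
extract_segment_pairs <- function(record, thresholds = label_thresholds(),
                                  stride_s = 20, qc = qc_thresholds()) {
  stopifnot(inherits(record, "waveform_record"), record$sampling_rate == 100)
  fs <- 100
  p <- record$pressure
  n <- length(p)
  w <- as.integer(round(thresholds$ma_window * fs))
  n_in <- as.integer(round(thresholds$input_len * fs))      # 2000
  n_out <- as.integer(round(thresholds$outcome_len * fs))   # 6000
  gap <- as.integer(round(thresholds$horizon * fs))         # 30000
  stride <- as.integer(round(stride_s * fs))

  empty <- data.frame(patient_id = character(0),
                      input_start_index = integer(0),
                      outcome_start_index = integer(0),
                      input_start_s = numeric(0), outcome_start_s = numeric(0),
                      label = character(0), qc_input = character(0),
                      qc_outcome = character(0), qc_ok = logical(0),
                      usable = logical(0))
  if (n < w) return(structure(empty, n_skipped = 0L))

  ma <- moving_average_2s(p, fs = fs, window_s = thresholds$ma_window)
  events <- detect_events(record, thresholds)
  starts <- sort(unique(c(seq(1L, max(1L, n - n_out + 1L), by = stride),
                          events$onset_index)))
  starts <- starts[starts + n_out - 1L <= n & starts >= w]
  min_input <- gap + n_in + 1L
  n_skipped <- sum(starts < min_input)
  starts <- starts[starts >= min_input]
  if (!length(starts)) return(structure(empty, n_skipped = n_skipped))

  # windowed extremes of the MA over each outcome window via cummax trick
  # ma[j] aligned to record index j + w - 1; outcome [s, s + n_out) needs
  # ma positions (s - w + 1) .. (s + n_out - w)
  lab <- vapply(starts, function(s) {
    j0 <- s - w + 1L
    seg <- ma[j0:(j0 + n_out - 1L)]
    if (anyNA(seg)) return("indeterminate")
    if (all(seg < thresholds$hypo_map)) "positive"
    else if (all(seg > thresholds$normo_map)) "negative"
    else "indeterminate"
  }, character(1))

  qin <- character(length(starts)); qout <- character(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    i0 <- s - gap - n_in
    qin[k] <- qc_code(check_segment(p[i0:(i0 + n_in - 1L)], qc))
    qout[k] <- qc_code(check_segment(p[s:(s + n_out - 1L)], qc))
  }
  ok <- qin == "" & qout == ""
  out <- data.frame(patient_id = record$patient_id,
                    input_start_index = starts - gap - n_in,
                    outcome_start_index = starts,
                    input_start_s = record$t0 + (starts - gap - n_in - 1L) / fs,
                    outcome_start_s = record$t0 + (starts - 1L) / fs,
                    label = lab, qc_input = qin, qc_outcome = qout,
                    qc_ok = ok, usable = ok & lab != "indeterminate")
  structure(out, n_skipped = n_skipped)
}

#' Random patient-level train/validation split
#'
#' Splitting at the patient level (never the segment level) guarantees
#' that no patient's segments leak across folds.
#'
#' @param patient_ids Character vector of unique patient identifiers
#'   (at least 2).
#' @param train_frac Fraction of patients assigned to training
#'   (default 0.7).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with elements `train` and `validation`, disjoint
#'   character vectors covering `patient_ids`.
#' @export
split_patients <- function(patient_ids, train_frac = 0.7, seed = 1) {
  patient_ids <- unique(as.character(patient_ids))
  if (length(patient_ids) < 2) stop("need at least 2 patients to split")
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly between 0 and 1")
  }
  n_train <- max(1L, min(length(patient_ids) - 1L,
                         as.integer(round(train_frac * length(patient_ids)))))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  train <- sort(sample(patient_ids, n_train))
  list(train = train, validation = sort(setdiff(patient_ids, train)))
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
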