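#' The 12 waveform features of one 20-s segment
#'
#' Per-beat quantities are computed on the raw (un-scaled) mmHg values
#' over foot-to-foot cycles; segment-level features are averages or
#' extremes across the segment's full beats:
#'
#' * `mean_beat_length` — average cycle duration, s
#' * `map_avg` — average of per-beat mean arterial pressure, mmHg
#' * `pp_max`, `pp_min`, `pp_range`, `pp_avg` — extremes, range and mean
#'   of per-beat pulse pressure (cycle max minus cycle min), mmHg
#' * `ppv` — pulse pressure variation,
#'   `(pp_max - pp_min) * 2.0 / (pp_max + pp_min)`
#' * `systolic_time_avg` — average time from cycle onset (foot) to the
#'   systolic peak, s
#' * `systolic_pressure_avg` — average of per-beat maxima, mmHg
#' * `systolic_pressure_range` — max minus min of per-beat maxima, mmHg
#' * `diastolic_pressure_avg` — average of per-beat minima, mmHg
#' * `beat_area_avg` — average trapezoidal integral of pressure over the
#'   cycle (area under the curve above 0 mmHg), mmHg*s
#'
#' @param segment Numeric pressure sequence (mmHg) at `fs` Hz.
#' @param boundaries Beat boundaries from [detect_beats()] (columns
#'   `start`, `end`, `peak`); at least 2 beats, otherwise the segment
#'   is dropped with an error.
#' @param fs Sampling rate, Hz (default 100).
#' @return Named numeric vector of the 12 features.
#' @export
extract_features <- function(segment, boundaries, fs = 100) {
  if (is.null(boundaries) || nrow(boundaries) < 2) {
    stop("segment dropped: fewer than 2 full beats")
  }
  nb <- nrow(boundaries)
  sys_p <- dia_p <- pp <- map <- area <- st <- len <- numeric(nb)
  for (i in seq_len(nb)) {
    s <- boundaries$start[i]; e <- boundaries$end[i]
    cyc <- segment[s:(e - 1L)]
    sys_p[i] <- max(cyc)
    dia_p[i] <- min(cyc)
    pp[i] <- sys_p[i] - dia_p[i]
    map[i] <- mean(cyc)
    len[i] <- (e - s) / fs
    st[i] <- (boundaries$peak[i] - s) / fs
    # trapezoid over the full cycle span [s, e]; the sample at e is the
    # next beat's foot and exists by the half-open boundary convention
    y <- segment[s:e]
    area[i] <- sum((y[-1] + y[-length(y)]) / 2) / fs
  }
  c(mean_beat_length = mean(len),
    map_avg = mean(map),
    pp_max = max(pp),
    pp_min = min(pp),
    pp_range = max(pp) - min(pp),
    pp_avg = mean(pp),
    ppv = (max(pp) - min(pp)) * 2.0 / (max(pp) + min(pp)),
    systolic_time_avg = mean(st),
    systolic_pressure_avg = mean(sys_p),
    systolic_pressure_range = max(sys_p) - min(sys_p),
    diastolic_pressure_avg = mean(dia_p),
    beat_area_avg = mean(area))
}

#' Fit a robust scaler on training features
#'
#' Robust scaling maps each feature as `x' = (x - Q2) / (Q3 - Q1)`
#' (median-centred, IQR-scaled). Quartiles use the linear-interpolation
#' convention (R's default type 7) and must be estimated on the
#' training fold only. A degenerate feature (`Q3 == Q1`) is flagged and
#' its scaled value defined as 0.
#'
#' @param features Numeric matrix or data frame of training rows (at
#'   least 4) with named feature columns.
#' @return An object of class `robust_scaler` with per-feature `q1`,
#'   `q2`, `q3` and a logical `degenerate` flag.
#' @export
fit_robust_scaler <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 4) stop("need at least 4 training rows")
  q <- apply(features, 2, stats::quantile,
             probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(q1 = q[1, ], q2 = q[2, ], q3 = q[3, ],
                 degenerate = q[3, ] - q[1, ] <= 0,
                 feature_names = colnames(features)),
            class = "robust_scaler")
}

#' Apply a fitted robust scaler
#'
#' Elementwise `(x - Q2) / (Q3 - Q1)` using the training quartiles;
#' validation rows must be scaled with the scaler fitted on training
#' data. Degenerate features scale to 0.
#'
#' @param scaler A [fit_robust_scaler()] object.
#' @param features Matrix or data frame whose columns match the
#'   training features by name.
#' @return Numeric matrix of scaled features.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "robust_scaler"))
  features <- as.matrix(features)
  if (!is.null(scaler$feature_names) && !is.null(colnames(features))) {
    if (!identical(colnames(features), scaler$feature_names)) {
      if (!all(scaler$feature_names %in% colnames(features))) {
        stop("feature-name mismatch between scaler and data")
      }
      features <- features[, scaler$feature_names, drop = FALSE]
    }
  }
  iqr <- scaler$q3 - scaler$q1
  out <- sweep(features, 2, scaler$q2, "-")
  out <- sweep(out, 2, ifelse(scaler$degenerate, 1, iqr), "/")
  out[, scaler$degenerate] <- 0
  out
}
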