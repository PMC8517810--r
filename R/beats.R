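#' Slice a 20-s segment into cardiac cycles
#'
#' Systolic peaks are found as local maxima with a minimum inter-peak
#' distance of `min_distance_s` (a 0.3-s refractory period) and a
#' topographic prominence of at least `min_prominence` mmHg. Cycle
#' boundaries are placed at the pressure minimum (the diastolic foot)
#' between consecutive peaks; a leading/trailing foot is also accepted
#' when a genuine downstroke precedes/follows it inside the segment.
#' Partial cycles at the segment edges are discarded. The foot-to-foot
#' convention is used so that systolic time (foot to peak) and beat
#' area are well defined.
#'
#' @param segment Numeric pressure sequence (mmHg) at `fs` Hz,
#'   artifact-free.
#' @param fs Sampling rate, Hz (default 100).
#' @param min_distance_s Minimum peak separation, seconds (default 0.3).
#' @param min_prominence Minimum peak prominence, mmHg (default 10).
#' @return A data frame of half-open beat boundaries (`start`, `end`,
#'   1-based sample indices; `end` of one beat is `start` of the next)
#'   with the detected peak index per beat in column `peak`.
#'   Throws `"unsliceable segment"` when fewer than 2 peaks are found.
#' @export
detect_beats <- function(segment, fs = 100, min_distance_s = 0.3,
                         min_prominence = 10) {
  stopifnot(is.numeric(segment), !anyNA(segment))
  peaks <- find_peaks(segment, min_distance = as.integer(min_distance_s * fs),
                      min_prominence = min_prominence)
  if (length(peaks) < 2) stop("unsliceable segment: fewer than 2 peaks found")
  n <- length(segment)
  # feet between consecutive peaks
  feet <- vapply(seq_len(length(peaks) - 1L), function(i) {
    span <- peaks[i]:peaks[i + 1L]
    span[which.min(segment[span])]
  }, integer(1))
  # leading foot: minimum before the first peak, only if preceded by a
  # genuine downstroke (otherwise the first cycle is partial)
  lead <- segment[1:peaks[1]]
  i0 <- which.min(lead)
  if (i0 > 1L && segment[1] > segment[i0] + 0.25 * min_prominence) {
    feet <- c(i0, feet)
  }
  # trailing foot: minimum after the last peak, only if the trace turns
  # back up before the segment ends
  tail_span <- peaks[length(peaks)]:n
  j0 <- tail_span[which.min(segment[tail_span])]
  if (j0 < n && segment[n] > segment[j0] + 0.25 * min_prominence) {
    feet <- c(feet, j0)
  }
  feet <- sort(unique(feet))
  if (length(feet) < 2) stop("unsliceable segment: fewer than 2 feet found")
  starts <- feet[-length(feet)]
  ends <- feet[-1]
  pk <- vapply(seq_along(starts), function(i) {
    inside <- peaks[peaks > starts[i] & peaks < ends[i]]
    if (length(inside)) inside[1] else starts[i] +
      which.max(segment[starts[i]:(ends[i] - 1L)]) - 1L
  }, integer(1))
  data.frame(start = starts, end = ends, peak = pk)
}

#' Local maxima with prominence and refractory-distance filters
#'
#' @param x Numeric vector.
#' @param min_distance Minimum index separation between retained peaks;
#'   when two candidates are closer, the higher one wins.
#' @param min_prominence Minimum topographic prominence (height above
#'   the higher of the two lowest points separating the peak from
#'   higher terrain or the edges).
#' @return Sorted integer vector of peak indices.
#' @export
find_peaks <- function(x, min_distance = 30, min_prominence = 10) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # plateau-safe local maxima: rising before, falling after
  sgn <- sign(d)
  nz <- sgn != 0
  cand <- integer(0)
  last_sign <- 0
  last_rise_end <- 0L
  for (i in seq_len(n - 1L)) {
    if (sgn[i] == 0) next
    if (sgn[i] > 0) {
      last_sign <- 1
      last_rise_end <- i + 1L
    } else {
      if (last_sign > 0) cand <- c(cand, last_rise_end)
      last_sign <- -1
    }
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    h <- x[p]
    left <- p; lmin <- h
    while (left > 1L) {
      left <- left - 1L
      if (x[left] > h) break
      if (x[left] < lmin) lmin <- x[left]
    }
    right <- p; rmin <- h
    while (right < n) {
      right <- right + 1L
      if (x[right] > h) break
      if (x[right] < rmin) rmin <- x[right]
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep_cand <- cand[prom >= min_prominence]
  if (!length(keep_cand)) return(integer(0))
  # greedy refractory filter: highest first
  ord <- keep_cand[order(x[keep_cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_distance)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Interpolate one beat to a fixed length of 100 samples
#'
#' Linear interpolation onto 100 equally spaced points spanning the
#' beat's duration; the first and last output values equal the first
#' and last input values.
#'
#' @param beat Numeric pressure sequence of at least 2 samples.
#' @return Numeric vector of length 100.
#' @export
normalize_beat <- function(beat) {
  if (length(beat) < 2) stop("beat must have at least 2 samples")
  stats::approx(x = seq_along(beat), y = beat,
                xout = seq(1, length(beat), length.out = 100))$y
}

#' Scale pressures to the unit interval
#'
#' Fixed affine map anchored at the artifact-screening bounds:
#' `x' = (x - 20) / (200 - 20)`, clipped to `[0, 1]`. A fixed
#' physiologic-range map (rather than per-segment min-max) preserves
#' absolute pressure level, which the prediction task requires. The
#' same map is applied to the length-2000 network input and to each
#' beat-matrix row.
#'
#' @param values Numeric mmHg values.
#' @param lower,upper Anchors of the affine map (defaults 20 and 200).
#' @return Values in `[0, 1]`.
#' @export
scale_values <- function(values, lower = 20, upper = 200) {
  pmin(1, pmax(0, (values - lower) / (upper - lower)))
}

#' Assemble the 30 x 100 beat matrix
#'
#' Each interpolated beat is scaled with [scale_values()] and placed as
#' a row. Segments with more than 30 beats are pre-truncated (the
#' oldest beats are dropped, keeping the most recent 30); segments with
#' fewer are pre-padded with zero rows, so zero rows always occupy the
#' first `30 - n_real_beats` positions and real beats keep their
#' temporal order ending at row 30.
#'
#' @param beats A list of length-100 numeric vectors in mmHg (as
#'   returned by [normalize_beat()]), in temporal order.
#' @param n_rows Number of matrix rows (default 30).
#' @return A `n_rows x 100` numeric matrix with attribute
#'   `n_real_beats`.
#' @export
build_beat_matrix <- function(beats, n_rows = 30) {
  if (length(beats) == 0) stop("no beats to assemble")
  stopifnot(all(vapply(beats, length, integer(1)) == 100))
  if (length(beats) > n_rows) {
    beats <- beats[(length(beats) - n_rows + 1L):length(beats)]
  }
  k <- length(beats)
  m <- matrix(0, nrow = n_rows, ncol = 100)
  for (i in seq_len(k)) {
    m[n_rows - k + i, ] <- scale_values(beats[[i]])
  }
  structure(m, n_real_beats = k)
}

#' Full beat preprocessing for one 20-s segment
#'
#' Convenience wrapper: detect beats, interpolate each to length 100,
#' and assemble the 30 x 100 matrix. Also returns the scaled
#' length-2000 array (the convolutional-network input).
#'
#' @param segment Numeric pressure sequence at 100 Hz (2000 samples for
#'   the standard 20-s input).
#' @param fs Sampling rate, Hz.
#' @return A list with `boundaries` (data frame from [detect_beats()]),
#'   `beats` (list of length-100 mmHg vectors), `matrix` (30 x 100
#'   scaled), and `scaled` (the scaled input array).
#' @export
preprocess_segment <- function(segment, fs = 100) {
  boundaries <- detect_beats(segment, fs = fs)
  beats <- lapply(seq_len(nrow(boundaries)), function(i) {
    normalize_beat(segment[boundaries$start[i]:(boundaries$end[i] - 1L)])
  })
  list(boundaries = boundaries, beats = beats,
       matrix = build_beat_matrix(beats), scaled = scale_values(segment))
}
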