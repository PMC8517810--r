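#' Artifact-screening thresholds
#'
#' Four physiologic-range criteria exclude artifact-contaminated
#' waveform segments: any missing sample; any pressure strictly over
#' `p_max` or strictly under `p_min`; a max-minus-min range strictly
#' under `flat_range` (a flatlined or heavily damped trace); any
#' adjacent-sample difference strictly over `max_jump` (equivalently a
#' pressure gradient over 3000 mmHg/s at 100 Hz). All four inequalities
#' are strict: a value of exactly 200 or 20 mmHg, a range of exactly
#' 20 mmHg, or a jump of exactly 30 mmHg does not violate.
#'
#' @param p_max Upper pressure bound, mmHg (default 200).
#' @param p_min Lower pressure bound, mmHg (default 20).
#' @param flat_range Minimum admissible max-minus-min range, mmHg
#'   (default 20).
#' @param max_jump Maximum admissible absolute adjacent-sample
#'   difference, mmHg (default 30).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(p_max = 200, p_min = 20, flat_range = 20,
                          max_jump = 30) {
  stopifnot(p_max > 0, p_min > 0, flat_range > 0, max_jump > 0)
  structure(list(p_max = p_max, p_min = p_min, flat_range = flat_range,
                 max_jump = max_jump),
            class = "qc_thresholds")
}

#' Screen one waveform segment against the artifact criteria
#'
#' Every violated criterion is reported, not just the first; the input
#' values are never modified. A sample pair straddling a missing
#' sentinel is not evaluated for the jump criterion (the missing
#' criterion already excludes the segment).
#'
#' @param values Numeric pressure segment at 100 Hz (mmHg, `NA` =
#'   missing).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `qc_result` with elements `valid` (logical)
#'   and `violations` (character subset of
#'   `c("MISSING", "RANGE", "FLAT", "JUMP")`). `valid` is `TRUE` iff
#'   `violations` is empty.
#' @examples
#' check_segment(rep(80, 2000))          # FLAT
#' check_segment(c(80, 120, 205, 80))    # RANGE (and JUMP)
#' @export
check_segment <- function(values, thresholds = qc_thresholds()) {
  if (length(values) == 0) stop("empty segment")
  stopifnot(inherits(thresholds, "qc_thresholds"))
  v <- character(0)
  miss <- is.na(values)
  if (any(miss)) v <- c(v, "MISSING")
  ok <- values[!miss]
  if (length(ok)) {
    if (any(ok > thresholds$p_max) || any(ok < thresholds$p_min)) {
      v <- c(v, "RANGE")
    }
    if (max(ok) - min(ok) < thresholds$flat_range) v <- c(v, "FLAT")
  }
  if (length(values) > 1) {
    d <- abs(diff(values))   # NA where a pair straddles a sentinel
    if (any(d > thresholds$max_jump, na.rm = TRUE)) v <- c(v, "JUMP")
  }
  structure(list(valid = length(v) == 0, violations = v),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  if (x$valid) cat("<qc_result> valid\n")
  else cat("<qc_result> excluded:", paste(x$violations, collapse = "+"), "\n")
  invisible(x)
}

# Compact code string for manifests, "" when valid.
qc_code <- function(qc) paste(qc$violations, collapse = "+")
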