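#' Construct a waveform record
#'
#' A `waveform_record` holds one patient's continuous arterial blood
#' pressure (ABP) trace together with its sampling rate. Missing samples
#' (e.g. transducer disconnections) are represented by `NA_real_`, a
#' sentinel distinguishable from any physiologic pressure. Sample `i`
#' (1-based) corresponds to time `t0 + (i - 1) / sampling_rate` seconds.
#'
#' @param pressure Numeric vector of arterial pressure in mmHg; `NA` marks
#'   missing samples.
#' @param sampling_rate Sampling rate in Hz; must be 100 or 500 on ingest.
#'   The analysis pipeline operates at 100 Hz (see
#'   [resample_to_100hz()]).
#' @param patient_id Character scalar identifying the patient.
#' @param t0 Time offset of the first sample in seconds (default 0).
#' @return An object of class `waveform_record`: a list with elements
#'   `patient_id`, `sampling_rate`, `pressure`, `t0`.
#' @export
waveform_record <- function(pressure, sampling_rate = 100,
                            patient_id = "p1", t0 = 0) {
  stopifnot(is.numeric(pressure), length(pressure) >= 1)
  if (!sampling_rate %in% c(100, 500)) {
    stop("sampling_rate must be 100 or 500 Hz, got ", sampling_rate)
  }
  structure(
    list(patient_id = as.character(patient_id),
         sampling_rate = as.numeric(sampling_rate),
         pressure = as.numeric(pressure),
         t0 = as.numeric(t0)),
    class = "waveform_record"
  )
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$pressure)
  cat(sprintf("<waveform_record> patient %s: %d samples @ %g Hz (%.1f s), %d missing\n",
              x$patient_id, n, x$sampling_rate, n / x$sampling_rate,
              sum(is.na(x$pressure))))
  invisible(x)
}

#' @export
length.waveform_record <- function(x) length(x$pressure)

# magic bytes for the binary container, version 1
.STEPOP_MAGIC <- charToRaw("ABPW1")

#' Read a waveform record from disk
#'
#' Two formats are supported. `"csv"` is a two-column text file with
#' header `time_s,abp_mmhg`; empty pressure cells parse to the missing
#' sentinel (`NA`). `"bin"` is the package's versioned binary container
#' (magic bytes `ABPW1`, then sampling rate, patient id, sample count,
#' missing-value mask and little-endian double payload) which
#' round-trips records losslessly.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"bin"`. Default guesses from the file
#'   extension.
#' @return A [waveform_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "bin")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") .read_record_csv(path) else .read_record_bin(path)
}

.read_record_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, check.names = FALSE)
  need <- c("time_s", "abp_mmhg")
  if (!all(need %in% names(raw))) {
    stop("CSV must have columns time_s and abp_mmhg; found: ",
         paste(names(raw), collapse = ", "))
  }
  tt <- suppressWarnings(as.numeric(raw$time_s))
  bad <- which(is.na(tt) | raw$time_s == "")
  if (length(bad)) {
    stop("malformed time_s value at line ", bad[1] + 1L,
         " of ", path, ": '", raw$time_s[bad[1]], "'")
  }
  if (length(tt) > 1 && any(diff(tt) <= 0)) {
    stop("time_s column is not strictly increasing at line ",
         which(diff(tt) <= 0)[1] + 2L, " of ", path)
  }
  pc <- raw$abp_mmhg
  p <- suppressWarnings(as.numeric(pc))
  bad <- which(is.na(p) & pc != "")  # empty cells are legitimate missing
  if (length(bad)) {
    stop("malformed abp_mmhg value at line ", bad[1] + 1L,
         " of ", path, ": '", pc[bad[1]], "'")
  }
  fs <- if (length(tt) > 1) 1 / stats::median(diff(tt)) else 100
  fs <- if (abs(fs - 500) < 1) 500 else 100
  waveform_record(p, sampling_rate = fs,
                  patient_id = sub("\\.[^.]*$", "", basename(path)),
                  t0 = tt[1])
}

.read_record_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(.STEPOP_MAGIC))
  if (!identical(magic, .STEPOP_MAGIC)) {
    stop("not a stepop binary record (bad magic bytes): ", path)
  }
  fs <- readBin(con, "double", 1, endian = "little")
  t0 <- readBin(con, "double", 1, endian = "little")
  nid <- readBin(con, "integer", 1, endian = "little")
  id <- rawToChar(readBin(con, "raw", nid))
  n <- readBin(con, "integer", 1, endian = "little")
  mask <- readBin(con, "integer", n, size = 1, signed = FALSE)
  p <- readBin(con, "double", n, endian = "little")
  p[mask == 1L] <- NA_real_
  waveform_record(p, sampling_rate = fs, patient_id = id, t0 = t0)
}

#' Write a waveform record to disk
#'
#' @inheritParams read_record
#' @param record A [waveform_record()].
#' @return The path, invisibly.
#' @seealso [read_record()] for the format descriptions.
#' @export
write_record <- function(record, path, format = c("auto", "csv", "bin")) {
  stopifnot(inherits(record, "waveform_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin"
  }
  if (format == "csv") {
    n <- length(record$pressure)
    tt <- record$t0 + (seq_len(n) - 1) / record$sampling_rate
    # %.17g keeps the round trip exact for doubles
    lines <- paste(sprintf("%.17g", tt),
                   ifelse(is.na(record$pressure), "",
                          sprintf("%.17g", record$pressure)),
                   sep = ",")
    ok <- try(writeLines(c("time_s,abp_mmhg", lines), path), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write record to ", path)
  } else {
    con <- try(file(path, "wb"), silent = TRUE)
    if (inherits(con, "try-error")) stop("cannot write record to ", path)
    on.exit(close(con))
    writeBin(.STEPOP_MAGIC, con)
    writeBin(as.double(record$sampling_rate), con, endian = "little")
    writeBin(as.double(record$t0), con, endian = "little")
    idr <- charToRaw(record$patient_id)
    writeBin(length(idr), con, endian = "little")
    writeBin(idr, con)
    p <- record$pressure
    writeBin(length(p), con, endian = "little")
    writeBin(as.integer(is.na(p)), con, size = 1)
    p[is.na(p)] <- 0
    writeBin(p, con, endian = "little")
  }
  invisible(path)
}

#' Resample a record to the canonical 100 Hz
#'
#' 500 Hz records are decimated by keeping every 5th sample (so every
#' retained value equals a source sample exactly); 100 Hz records pass
#' through unchanged. Missing sentinels propagate. An optional
#' anti-alias pre-filter (centred 5-point moving average) can be enabled;
#' it is off by default so that decimation is exactly value-preserving.
#'
#' @param record A [waveform_record()] at 100 or 500 Hz.
#' @param anti_alias Apply a 5-point moving-average low-pass before
#'   decimating a 500 Hz record? Default `FALSE`.
#' @return A [waveform_record()] at 100 Hz.
#' @export
resample_to_100hz <- function(record, anti_alias = FALSE) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$sampling_rate
  if (fs == 100) return(record)
  if (fs != 500) stop("unsupported sampling rate: ", fs)
  p <- record$pressure
  if (anti_alias) {
    sm <- as.numeric(stats::filter(p, rep(1 / 5, 5), sides = 2))
    p <- ifelse(is.na(sm), p, sm)  # edges keep raw values
  }
  keep <- seq(1, length(p), by = 5)
  waveform_record(p[keep], sampling_rate = 100,
                  patient_id = record$patient_id, t0 = record$t0)
}
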