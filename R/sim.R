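#' Simulator configuration
#'
#' Parameters of the synthetic arterial-waveform generator. The
#' generator produces pulsatile beat morphology (systolic upstroke plus
#' dicrotic wave) riding between diastolic and systolic envelopes
#' derived from a mean-arterial-pressure (MAP) trajectory: a
#' per-patient baseline with slow sinusoidal wander, scheduled
#' hypotensive dips preceded by a linear pre-onset MAP decline of
#' `predrift_s` seconds (so a five-minute-ahead prediction task is
#' learnable), and a 60-s linear recovery after each dip. Heart rate
#' varies beat to beat by an AR(1) process; pulse pressure is modulated
#' by a slow respiratory oscillation so that pulse-pressure variation
#' is non-zero. Additive Gaussian noise with `noise_sd` mmHg completes
#' the trace.
#'
#' @param n_patients Number of records in a cohort.
#' @param duration_s Record length in seconds.
#' @param sampling_rate 100 or 500 Hz.
#' @param hr_range Heart-rate interval in beats/min (within (20, 240)).
#' @param baseline_map_range Per-patient baseline MAP interval, mmHg.
#' @param pulse_pressure_range Per-patient mean pulse-pressure interval,
#'   mmHg.
#' @param event_schedule Either `"random"` (each record draws
#'   `n_events` dips at admissible times) or a list of
#'   `c(onset_s, duration_s, target_map)` triplets applied to every
#'   record. An explicit schedule extending past `duration_s` is
#'   rejected.
#' @param n_events Number of dips per record when `event_schedule` is
#'   `"random"`.
#' @param event_duration_s Dip plateau duration, seconds.
#' @param target_map_range Dip target MAP interval, mmHg (random
#'   schedules).
#' @param predrift_s Seconds of linear MAP decline before each dip
#'   onset (default 420).
#' @param recovery_s Seconds of linear recovery after each dip.
#' @param artifact_rate Expected injected artifacts per hour per type
#'   (see [inject_artifacts()]); default 0.
#' @param noise_sd Additive noise standard deviation, mmHg.
#' @param seed Integer seed. Identical configurations (including seed)
#'   produce bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 10, duration_s = 1800,
                       sampling_rate = 100,
                       hr_range = c(60, 110),
                       baseline_map_range = c(85, 100),
                       pulse_pressure_range = c(35, 55),
                       event_schedule = "random",
                       n_events = 2, event_duration_s = 120,
                       target_map_range = c(50, 60),
                       predrift_s = 420, recovery_s = 180,
                       artifact_rate = 0, noise_sd = 1, seed = 1) {
  stopifnot(duration_s > 0, sampling_rate %in% c(100, 500),
            hr_range[1] > 20, hr_range[2] < 240, hr_range[1] <= hr_range[2],
            predrift_s >= 0, recovery_s >= 0, artifact_rate >= 0,
            noise_sd >= 0, n_patients >= 0)
  if (is.list(event_schedule)) {
    for (ev in event_schedule) {
      stopifnot(length(ev) == 3)
      if (ev[1] + ev[2] > duration_s) {
        stop("event schedule extends past duration_s: dip at ", ev[1],
             " s lasting ", ev[2], " s exceeds ", duration_s, " s")
      }
    }
  } else if (!identical(event_schedule, "random")) {
    stop("event_schedule must be \"random\" or a list of",
         " (onset_s, duration_s, target_map) triplets")
  }
  structure(list(n_patients = n_patients, duration_s = duration_s,
                 sampling_rate = sampling_rate, hr_range = hr_range,
                 baseline_map_range = baseline_map_range,
                 pulse_pressure_range = pulse_pressure_range,
                 event_schedule = event_schedule, n_events = n_events,
                 event_duration_s = event_duration_s,
                 target_map_range = target_map_range,
                 predrift_s = predrift_s, recovery_s = recovery_s,
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Beat template on n samples of one foot-to-foot cycle, range [0, 1]:
# a fast asymmetric systolic bump, a smaller dicrotic wave, and a linear
# diastolic runoff so the pressure minimum (the foot) falls just before
# the next upstroke.
beat_template <- function(n) {
  u <- (seq_len(n) - 1) / n
  sl <- ifelse(u < 0.15, 0.07, 0.16)
  sys <- exp(-((u - 0.15) / sl)^2)
  dic <- 0.22 * exp(-((u - 0.45) / 0.07)^2)
  tp <- sys + dic - 0.18 * u
  tp <- tp - min(tp)
  tp / max(tp)
}

#' Simulate one synthetic arterial-waveform record
#'
#' @param config A [sim_config()].
#' @param patient_index Positive integer; together with `config$seed` it
#'   determines the record, so records are reproducible individually.
#' @return A list with elements `record` (a [waveform_record()] at
#'   `config$sampling_rate`) and `ground_truth`, a list holding
#'   `episodes` (data frame of true hypotensive episodes `onset_s`,
#'   `end_s`, derived from the noise-free MAP envelope crossing
#'   65 mmHg for at least 60 s, non-overlapping and sorted),
#'   `normotensive` (same for envelope over 75 mmHg), `map` (the
#'   per-sample true MAP envelope) and `feet` (sample indices of the
#'   true beat onsets).
#' @export
simulate_record <- function(config, patient_index = 1) {
  stopifnot(inherits(config, "sim_config"), patient_index >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(((config$seed %% 100000L) * 20011L + patient_index * 7919L) %%
             2147483647L)
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration_s * fs))

  baseline <- stats::runif(1, config$baseline_map_range[1],
                           config$baseline_map_range[2])
  pp_base <- stats::runif(1, config$pulse_pressure_range[1],
                          config$pulse_pressure_range[2])
  hr_base <- stats::runif(1, config$hr_range[1], config$hr_range[2])

  schedule <- if (is.list(config$event_schedule)) {
    config$event_schedule
  } else {
    .random_schedule(config)
  }

  # MAP envelope: baseline + slow wander, overwritten by dip ramps.
  # Each dip has a two-phase pre-onset drift: a slow decline to just
  # above the hypotension threshold over the first 40% of predrift_s,
  # then a steadier descent reaching 65 mmHg exactly at the scheduled
  # onset, a quick final drop to the target, a plateau, and a linear
  # recovery. The two-phase shape leaves the pressure 5 minutes before
  # onset already visibly depressed, mirroring the near-hypotensive
  # pre-event levels seen in real cohorts.
  tt <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  env <- baseline + 2 * sin(2 * pi * tt / 300 + phase)
  for (ev in schedule) {
    onset <- ev[1]; dur <- ev[2]; target <- ev[3]
    t0e <- max(0, onset - config$predrift_s)
    i0 <- which(tt >= t0e)[1]
    b0 <- env[i0]
    mid_level <- 65 + 0.3 * (b0 - 65)
    drop_end <- onset + min(30, 0.2 * dur)
    idx <- which(tt >= t0e & tt < drop_end)
    if (length(idx) && onset > t0e) {
      env[idx] <- stats::approx(
        x = c(t0e, t0e + 0.4 * (onset - t0e), onset, drop_end),
        y = c(b0, mid_level, 65, target),
        xout = tt[idx], rule = 2)$y
    }
    idx <- which(tt >= drop_end & tt < onset + dur)
    env[idx] <- target
    idx <- which(tt >= onset + dur & tt < onset + dur + config$recovery_s)
    if (length(idx)) {
      frac <- (tt[idx] - (onset + dur)) / config$recovery_s
      env[idx] <- target + frac * (env[idx] - target)
    }
  }

  # Beat-by-beat synthesis anchored to the envelope at each foot.
  # Falling MAP triggers a compensatory response: heart rate rises
  # (shorter beats) and respiratory pulse-pressure modulation deepens
  # (higher PPV) while mean pulse pressure shrinks slightly.
  pressure <- numeric(n)
  feet <- integer(0)
  pos <- 1L
  hr <- hr_base
  while (pos <= n) {
    deficit <- max(0, (baseline - env[pos]) / baseline)
    hr_t <- hr_base * (1 + 0.25 * deficit)
    hr <- hr_t + 0.8 * (hr - hr_t) + stats::rnorm(1, 0, 2)
    hr <- min(max(hr, config$hr_range[1]), config$hr_range[2])
    nb <- max(2L, as.integer(round(60 / hr * fs)))
    amp <- 0.06 * (1 + 2 * deficit)
    pp <- pp_base * (1 - 0.15 * deficit) *
      (1 + amp * sin(2 * pi * tt[pos] / 5) + stats::rnorm(1, 0, 0.02))
    pp <- max(pp, 5)
    tpl <- beat_template(nb)
    dia <- env[pos] - pp * mean(tpl)
    last <- min(pos + nb - 1L, n)
    pressure[pos:last] <- (dia + pp * tpl)[seq_len(last - pos + 1L)]
    feet <- c(feet, pos)
    pos <- pos + nb
  }
  if (config$noise_sd > 0) {
    pressure <- pressure + stats::rnorm(n, 0, config$noise_sd)
  }

  min_run <- as.integer(round(60 * fs))
  gt <- list(
    episodes = .envelope_runs(env < 65, min_run, fs),
    normotensive = .envelope_runs(env > 75, min_run, fs),
    map = env,
    feet = feet
  )
  list(record = waveform_record(pressure, sampling_rate = fs,
                                patient_id = sprintf("p%04d", patient_index)),
       ground_truth = gt)
}

# Draw non-overlapping dip onsets, one per equal block of the record;
# dips that cannot fit are dropped. Each dip sits near the end of its
# block so a long stable-baseline stretch precedes it — the typical
# presentation of a slow intraoperative decline — and the last dip's
# recovery may run off the record end.
.random_schedule <- function(config) {
  lead <- config$predrift_s + 60
  if (config$n_events < 1) return(list())
  block <- (config$duration_s - lead) / config$n_events
  sched <- list()
  for (k in seq_len(config$n_events)) {
    hi <- lead + k * block - config$event_duration_s - 120
    lo <- max(lead + (k - 1) * block, hi - 120)
    if (hi <= lo) next
    onset <- stats::runif(1, lo, hi)
    target <- stats::runif(1, config$target_map_range[1],
                           config$target_map_range[2])
    sched[[length(sched) + 1L]] <- c(onset, config$event_duration_s, target)
  }
  sched
}

.envelope_runs <- function(cond, min_run, fs) {
  r <- rle(as.vector(cond))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(onset_s = (starts[keep] - 1L) / fs,
             end_s = ends[keep] / fs)
}

#' Inject artifacts of each exclusion class into a record
#'
#' Inserts, at logged positions, artifacts matching the four screening
#' criteria: missing-value gaps (2-5 s of `NA`), out-of-range spikes
#' (>200 mmHg) alternating with troughs (<20 mmHg), flat stretches of
#' 20-30 s with range under 20 mmHg, and step discontinuities over
#' 30 mmHg between adjacent samples (a 2-10 s span offset by
#' 35-60 mmHg). The expected number of artifacts per type is
#' `artifact_rate` per hour of record; with `artifact_rate = 0` the
#' record is returned unchanged with an empty log.
#'
#' @param record A [waveform_record()] at 100 Hz.
#' @param config A [sim_config()] (uses `artifact_rate` and `seed`).
#' @return A list with elements `record` (the contaminated record) and
#'   `log`, a data frame of injected spans (`type`, `start_index`,
#'   `end_index`, half-open 1-based).
#' @export
inject_artifacts <- function(record, config) {
  stopifnot(inherits(record, "waveform_record"),
            record$sampling_rate == 100, inherits(config, "sim_config"))
  empty_log <- data.frame(type = character(0), start_index = integer(0),
                          end_index = integer(0))
  if (config$artifact_rate <= 0) {
    return(list(record = record, log = empty_log))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(((config$seed %% 100000L) * 48271L +
              sum(utf8ToInt(record$patient_id)) * 131L + 777L) %% 2147483647L)
  fs <- 100
  p <- record$pressure
  n <- length(p)
  hours <- n / fs / 3600
  lam <- config$artifact_rate * hours
  log <- empty_log
  add <- function(type, start, end) {
    log <<- rbind(log, data.frame(type = type, start_index = start,
                                  end_index = end))
  }
  draw_start <- function(len) {
    if (n - len < 1) return(NA_integer_)
    sample.int(n - len, 1)
  }
  for (type in c("missing", "spike", "flat", "jump")) {
    k <- stats::rpois(1, lam)
    for (j in seq_len(k)) {
      if (type == "missing") {
        len <- as.integer(stats::runif(1, 2, 5) * fs)
        s <- draw_start(len); if (is.na(s)) next
        p[s:(s + len - 1L)] <- NA_real_
        add("missing", s, s + len)
      } else if (type == "spike") {
        len <- sample(1:3, 1)
        s <- draw_start(len); if (is.na(s)) next
        val <- if (j %% 2 == 1) stats::runif(1, 205, 240)
               else stats::runif(1, 5, 18)
        p[s:(s + len - 1L)] <- val
        add("spike", s, s + len)
      } else if (type == "flat") {
        len <- as.integer(stats::runif(1, 20, 30) * fs)
        s <- draw_start(len); if (is.na(s)) next
        p[s:(s + len - 1L)] <- mean(p[s:(s + len - 1L)], na.rm = TRUE)
        add("flat", s, s + len)
      } else {
        len <- as.integer(stats::runif(1, 2, 10) * fs)
        s <- draw_start(len); if (is.na(s)) next
        off <- sample(c(-1, 1), 1) * stats::runif(1, 35, 60)
        p[s:(s + len - 1L)] <- p[s:(s + len - 1L)] + off
        add("jump", s, s + len)
      }
    }
  }
  rec <- record
  rec$pressure <- p
  list(record = rec, log = log)
}

#' Simulate and write a cohort of synthetic records
#'
#' Writes `n_patients` records (with artifacts injected at
#' `artifact_rate`) through [write_record()] plus a tab-separated
#' manifest (`manifest.tsv`: patient_id, path, n_samples, n_events,
#' events) and one ground-truth JSON per record (episodes, normotensive
#' stretches, beat feet; the dense MAP envelope is not serialized —
#' call [simulate_record()] for it).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param format Record file format, `"bin"` (default) or `"csv"`.
#' @return Invisibly, a list with `manifest` (data frame) and
#'   `ground_truth` (per-patient list). Deterministic given `config`.
#' @export
simulate_cohort <- function(config, dir, format = c("bin", "csv")) {
  stopifnot(inherits(config, "sim_config"))
  format <- match.arg(format)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, mode = 2) != 0) stop("output directory not writable: ", dir)
  ext <- if (format == "csv") ".csv" else ".abp"
  rows <- vector("list", config$n_patients)
  gts <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    sim <- simulate_record(config, i)
    rec <- sim$record
    if (rec$sampling_rate != 100) rec <- resample_to_100hz(rec)
    if (config$artifact_rate > 0) {
      inj <- inject_artifacts(rec, config)
      rec <- inj$record
      sim$ground_truth$artifact_log <- inj$log
    }
    path <- file.path(dir, paste0(rec$patient_id, ext))
    write_record(rec, path, format)
    gt <- sim$ground_truth
    gt$map <- NULL
    jsonlite::write_json(gt, file.path(dir, paste0(rec$patient_id, "_gt.json")),
                         digits = NA, auto_unbox = TRUE)
    ev <- gt$episodes
    rows[[i]] <- data.frame(
      patient_id = rec$patient_id, path = path,
      n_samples = length(rec$pressure), n_events = nrow(ev),
      events = paste(sprintf("%.2f-%.2f", ev$onset_s, ev$end_s),
                     collapse = ";"))
    gts[[i]] <- sim$ground_truth
    names(gts)[i] <- rec$patient_id
  }
  manifest <- if (config$n_patients > 0) do.call(rbind, rows) else
    data.frame(patient_id = character(0), path = character(0),
               n_samples = integer(0), n_events = integer(0),
               events = character(0))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, ground_truth = gts))
}
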