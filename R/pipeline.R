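#' Pipeline configuration
#'
#' Bundles every stage's settings with a single global seed that is
#' expanded deterministically into per-stage seeds (simulation, patient
#' split, model training, bootstrap), so one knob reproduces a whole
#' run. Defaults equal the published constants wherever the method
#' states them (thresholds, horizon, optimizer, class weights, 70/30
#' split, alpha grid); problem-size knobs (cohort size, epochs, batch
#' size, hidden size, stride) are the package's own defaults.
#'
#' @param sim A [sim_config()].
#' @param labels A [label_thresholds()].
#' @param qc A [qc_thresholds()].
#' @param train A [train_config()] (used by the CNN and, unless
#'   `train_rnn` is given, by the LSTM).
#' @param train_rnn Optional separate [train_config()] for the LSTM;
#'   the recurrent model typically needs more epochs than the
#'   convolutional one at the shared learning rate. Its seed is forced
#'   to `train`'s so both deep models share the inner 90/10 split.
#' @param cnn A [cnn_config()].
#' @param rnn An [rnn_config()].
#' @param stride_s Outcome-window enumeration stride, seconds.
#' @param train_frac Patient-level training fraction (default 0.7).
#' @param alpha_grid_step Ensemble weight grid step (default 0.01).
#' @param n_resamples,resample_fraction Bootstrap settings for the
#'   evaluation report.
#' @param format Record file format for the simulated cohort.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), labels = label_thresholds(),
                            qc = qc_thresholds(), train = train_config(),
                            train_rnn = NULL, cnn = cnn_config(),
                            rnn = rnn_config(), stride_s = 20,
                            train_frac = 0.7, alpha_grid_step = 0.01,
                            n_resamples = 1000, resample_fraction = 0.5,
                            format = "bin", seed = 1) {
  seed <- as.integer(seed)
  sim$seed <- seed + 101L
  train$seed <- seed + 202L
  if (is.null(train_rnn)) train_rnn <- train
  train_rnn$seed <- train$seed
  train_rnn$model_select_frac <- train$model_select_frac
  structure(list(sim = sim, labels = labels, qc = qc, train = train,
                 train_rnn = train_rnn,
                 cnn = cnn, rnn = rnn, stride_s = stride_s,
                 train_frac = train_frac, alpha_grid_step = alpha_grid_step,
                 n_resamples = n_resamples,
                 resample_fraction = resample_fraction, format = format,
                 seed = seed, split_seed = seed + 303L,
                 boot_seed = seed + 404L),
            class = "pipeline_config")
}

#' Desk-scale demonstration configuration
#'
#' A complete pipeline configuration sized to run on one CPU in a few
#' minutes: 50 synthetic patients of 30 minutes each, one scheduled
#' hypotensive dip per record (180-s plateau, 7-minute pre-onset
#' drift), a 30-s enumeration stride, compact network sizes
#' (8/16/32-filter CNN, hidden-32 LSTM), 12 CNN epochs and 35 LSTM
#' epochs at batch size 16, and 500 bootstrap resamples. All published
#' constants (thresholds, horizon, optimizer settings, class weights)
#' keep their defaults.
#'
#' @param seed Global integer seed.
#' @param n_patients Cohort size (default 50).
#' @return A [pipeline_config()].
#' @export
small_pipeline_config <- function(seed = 1, n_patients = 50) {
  pipeline_config(
    sim = sim_config(n_patients = n_patients, duration_s = 1800,
                     n_events = 1, event_duration_s = 180,
                     target_map_range = c(48, 56)),
    train = train_config(epochs = 12, batch_size = 16),
    train_rnn = train_config(epochs = 35, batch_size = 16),
    cnn = cnn_config(filters = c(8, 16, 32)),
    rnn = rnn_config(hidden = 32),
    stride_s = 30, n_resamples = 500, seed = seed)
}

#' Assemble the model dataset from a simulated cohort on disk
#'
#' Reads every record listed in the cohort manifest, enumerates and
#' labels segment pairs, applies artifact screening, runs beat
#' preprocessing and feature extraction on the usable pairs, and
#' returns aligned model inputs plus stage-by-stage accounting.
#'
#' @param config A [pipeline_config()].
#' @param records_dir Directory written by [simulate_cohort()].
#' @return A list with `x_cnn` (n x 2000 scaled), `x_rnn`
#'   (n x 30 x 100), `features` (n x 12, raw mmHg scale), `y` (0/1),
#'   `patient_id`, `pairs` (the full pair manifest with a
#'   `modeled` flag), and `counts` (named stage counts).
#' @export
build_dataset <- function(config, records_dir) {
  manifest <- utils::read.table(file.path(records_dir, "manifest.tsv"),
                                sep = "\t", header = TRUE,
                                colClasses = c(patient_id = "character"))
  n2000 <- as.integer(round(config$labels$input_len * 100))
  all_pairs <- list()
  seg_list <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    rec <- read_record(manifest$path[i])
    pairs <- extract_segment_pairs(rec, config$labels,
                                   stride_s = config$stride_s,
                                   qc = config$qc)
    n_skipped <- n_skipped + attr(pairs, "n_skipped")
    pairs$record_path <- manifest$path[i]
    all_pairs[[i]] <- pairs
    seg_list[[i]] <- lapply(which(pairs$usable), function(k) {
      s <- pairs$input_start_index[k]
      rec$pressure[s:(s + n2000 - 1L)]
    })
  }
  pairs <- do.call(rbind, all_pairs)
  usable <- which(pairs$usable)
  segs <- do.call(c, seg_list)
  stopifnot(length(segs) == length(usable))

  x_cnn <- matrix(NA_real_, length(usable), n2000)
  x_rnn <- array(NA_real_, c(length(usable), 30, 100))
  feats <- matrix(NA_real_, length(usable), 12)
  ok <- logical(length(usable))
  for (j in seq_along(usable)) {
    seg <- segs[[j]]
    pp <- tryCatch(preprocess_segment(seg), error = function(e) NULL)
    if (is.null(pp) || nrow(pp$boundaries) < 2) next  # unsliceable
    x_cnn[j, ] <- pp$scaled
    x_rnn[j, , ] <- pp$matrix
    feats[j, ] <- extract_features(seg, pp$boundaries)
    ok[j] <- TRUE
  }
  colnames(feats) <- names(extract_features(
    c(60, 80, 100, 80, 60, 60, 80, 100, 80, 60, 60),
    data.frame(start = c(1, 6), end = c(6, 11), peak = c(3, 8))))
  pairs$modeled <- FALSE
  pairs$modeled[usable[ok]] <- TRUE
  keep <- usable[ok]
  counts <- c(patients = nrow(manifest),
              windows_candidate = nrow(pairs) + n_skipped,
              windows_skipped_pre_start = n_skipped,
              windows_enumerated = nrow(pairs),
              qc_excluded = sum(!pairs$qc_ok),
              indeterminate = sum(pairs$qc_ok &
                                    pairs$label == "indeterminate"),
              usable = length(usable),
              unsliceable = sum(!ok),
              modeled = sum(ok),
              positives = sum(pairs$label[keep] == "positive"),
              negatives = sum(pairs$label[keep] == "negative"))
  list(x_cnn = x_cnn[ok, , drop = FALSE],
       x_rnn = x_rnn[ok, , , drop = FALSE],
       features = feats[ok, , drop = FALSE],
       y = as.integer(pairs$label[keep] == "positive"),
       patient_id = pairs$patient_id[keep],
       pairs = pairs, counts = counts)
}

#' Fit the full hypotension-prediction ensemble
#'
#' Runs the whole pipeline: simulate a synthetic cohort (unless
#' `records_dir` points at an existing one), screen/label/preprocess
#' segments, split patients 70/30, train the CNN and the bidirectional
#' LSTM (each on 90% of training patients with checkpoint selection on
#' the inner 10%), fit the robust-scaled logistic baseline with
#' patient-grouped 5-fold CV, tune the ensemble weight `alpha` on the
#' inner 10% predictions, and evaluate all four models on the
#' validation patients with bootstrap CIs. Every stage writes a
#' manifest into `dir`; the run is reproducible from its config.
#'
#' @param config A [pipeline_config()].
#' @param dir Run directory (created; default a fresh temporary
#'   directory).
#' @param records_dir Optional pre-existing cohort directory; default
#'   simulates into `dir/records`.
#' @return An object of class `stepop`; see [predict.stepop()],
#'   [summary.stepop()], [plot.stepop()].
#' @export
stepop <- function(config = pipeline_config(), dir = tempfile("stepop_run"),
                   records_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name),
                 file.path(dir, "PARTIAL_RUN"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  if (is.null(records_dir)) {
    records_dir <- file.path(dir, "records")
    stage("simulate", simulate_cohort(config$sim, records_dir,
                                      format = config$format))
  }
  ds <- stage("label+preprocess", build_dataset(config, records_dir))
  utils::write.table(ds$pairs[, setdiff(names(ds$pairs), "record_path")],
                     file.path(dir, "segments.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  split <- stage("split", split_patients(unique(ds$patient_id),
                                         train_frac = config$train_frac,
                                         seed = config$split_seed))
  tr <- ds$patient_id %in% split$train
  va <- !tr
  counts <- c(ds$counts,
              train_patients = length(split$train),
              validation_patients = length(split$validation),
              train_segments = sum(tr),
              validation_segments = sum(va))

  cnn <- stage("train_cnn",
               train_cnn(ds$x_cnn[tr, , drop = FALSE], ds$y[tr],
                         ds$patient_id[tr], config$train, config$cnn))
  rnn <- stage("train_rnn",
               train_rnn(ds$x_rnn[tr, , , drop = FALSE], ds$y[tr],
                         ds$patient_id[tr], config$train_rnn, config$rnn))

  scaler <- stage("features", fit_robust_scaler(ds$features[tr, ,
                                                            drop = FALSE]))
  logistic <- stage("train_logistic",
                    train_logistic(apply_scaler(scaler,
                                                ds$features[tr, , drop = FALSE]),
                                   ds$y[tr], ds$patient_id[tr],
                                   seed = config$train$seed + 31L))

  # the two deep models share the inner 90/10 split by construction
  stopifnot(identical(cnn$tune$index, rnn$tune$index))
  weights <- stage("tune_alpha", {
    if (length(unique(cnn$tune$labels)) < 2) {
      # degenerate tuning split (single class): fall back to an even mix
      grid <- seq(0, 1, by = config$alpha_grid_step)
      structure(list(alpha = 0.5,
                     curve = data.frame(alpha = grid, auprc = NA_real_)),
                class = "ensemble_weights")
    } else {
      optimize_alpha(rnn$tune$probabilities, cnn$tune$probabilities,
                     cnn$tune$labels, grid_step = config$alpha_grid_step)
    }
  })

  p_cnn <- predict(cnn, ds$x_cnn[va, , drop = FALSE])
  p_rnn <- predict(rnn, ds$x_rnn[va, , , drop = FALSE])
  p_log <- predict(logistic,
                   apply_scaler(scaler, ds$features[va, , drop = FALSE]))
  p_ens <- ensemble_predict(p_rnn, p_cnn, weights)
  y_va <- ds$y[va]

  evals <- stage("evaluate", list(
    stepop = eval_report(p_ens, y_va, config$n_resamples,
                         config$resample_fraction, config$boot_seed),
    cnn = eval_report(p_cnn, y_va, config$n_resamples,
                      config$resample_fraction, config$boot_seed),
    rnn = eval_report(p_rnn, y_va, config$n_resamples,
                      config$resample_fraction, config$boot_seed),
    logistic = eval_report(p_log, y_va, config$n_resamples,
                           config$resample_fraction, config$boot_seed)))

  jsonlite::write_json(lapply(evals, unclass),
                       file.path(dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA)
  consort <- data.frame(stage = names(counts), count = as.integer(counts))
  utils::write.table(consort, file.path(dir, "consort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(alpha = weights$alpha, seed = config$seed),
                       file.path(dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(config = config, dir = dir, records_dir = records_dir,
                 split = split, models = list(cnn = cnn, rnn = rnn,
                                              logistic = logistic),
                 scaler = scaler, weights = weights, eval = evals,
                 consort = consort,
                 validation = list(labels = y_va,
                                   patient_id = ds$patient_id[va],
                                   p_cnn = p_cnn, p_rnn = p_rnn,
                                   p_logistic = p_log, p_stepop = p_ens),
                 data = ds),
            class = "stepop")
}

#' Run the full pipeline (alias of [stepop()])
#'
#' @inheritParams stepop
#' @return The fitted `stepop` object.
#' @export
run_all <- function(config = pipeline_config(), dir = tempfile("stepop_run"),
                    records_dir = NULL) {
  stepop(config, dir, records_dir)
}

#' Stage-by-stage data-flow accounting
#'
#' @param x A fitted `stepop` object or a run directory containing
#'   `consort.tsv`.
#' @return A data frame with columns `stage` and `count`, internally
#'   consistent at every stage (kept + excluded = in).
#' @export
consort_summary <- function(x) {
  if (inherits(x, "stepop")) return(x$consort)
  path <- file.path(x, "consort.tsv")
  if (!file.exists(path)) stop("missing manifest: ", path)
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' @export
print.stepop <- function(x, ...) {
  cat("Five-minute hypotension prediction ensemble\n")
  cat(sprintf("  cohort: %d patients, %d modeled segments (prevalence %.3f)\n",
              x$consort$count[x$consort$stage == "patients"],
              x$consort$count[x$consort$stage == "modeled"],
              mean(x$data$y)))
  cat(sprintf("  ensemble weight alpha = %.2f (tuned on inner 10%%)\n",
              x$weights$alpha))
  cat(sprintf("  validation AUPRC: ensemble %.4f | CNN %.4f | RNN %.4f | logistic %.4f\n",
              x$eval$stepop$auprc, x$eval$cnn$auprc, x$eval$rnn$auprc,
              x$eval$logistic$auprc))
  invisible(x)
}

#' @export
summary.stepop <- function(object, ...) {
  cat("== Validation performance (bootstrap 95% CI) ==\n")
  for (m in names(object$eval)) {
    cat(sprintf("-- %s --\n", m))
    print(object$eval[[m]])
  }
  cat("== Data flow ==\n")
  print(object$consort, row.names = FALSE)
  invisible(object)
}

#' @export
coef.stepop <- function(object, ...) coef(object$models$logistic)

#' Sliding-window ensemble prediction over a whole record
#'
#' Slides a 20-s input window along the record at `stride_s`, screens
#' each window, preprocesses it and emits the CNN, RNN and ensemble
#' probabilities aligned to the window end time. Windows failing
#' artifact screening or beat slicing yield `NA` (a missing marker),
#' so the trace can be plotted against the 2-s moving-average
#' pressure.
#'
#' @param record A [waveform_record()] at 100 Hz, at least 20 s long.
#' @param fit A fitted `stepop` object.
#' @param stride_s Window stride in seconds (default 20).
#' @return A data frame with `end_s`, `qc_ok`, `p_cnn`, `p_rnn`,
#'   `p_stepop`.
#' @export
predict_over_record <- function(record, fit, stride_s = 20) {
  stopifnot(inherits(record, "waveform_record"),
            record$sampling_rate == 100, inherits(fit, "stepop"))
  n <- length(record$pressure)
  n_in <- 2000L
  if (n < n_in) stop("record shorter than 20 s")
  ends <- seq(n_in, n, by = as.integer(round(stride_s * 100)))
  m <- length(ends)
  qc_ok <- logical(m)
  xs <- matrix(NA_real_, m, n_in)
  xr <- array(NA_real_, c(m, 30, 100))
  for (k in seq_len(m)) {
    seg <- record$pressure[(ends[k] - n_in + 1L):ends[k]]
    if (!check_segment(seg, fit$config$qc)$valid) next
    pp <- tryCatch(preprocess_segment(seg), error = function(e) NULL)
    if (is.null(pp)) next
    qc_ok[k] <- TRUE
    xs[k, ] <- pp$scaled
    xr[k, , ] <- pp$matrix
  }
  p_cnn <- p_rnn <- rep(NA_real_, m)
  if (any(qc_ok)) {
    p_cnn[qc_ok] <- predict(fit$models$cnn, xs[qc_ok, , drop = FALSE])
    p_rnn[qc_ok] <- predict(fit$models$rnn, xr[qc_ok, , , drop = FALSE])
  }
  data.frame(end_s = record$t0 + (ends - 1L) / 100,
             qc_ok = qc_ok, p_cnn = p_cnn, p_rnn = p_rnn,
             p_stepop = ensemble_predict(p_rnn, p_cnn, fit$weights))
}

#' @export
#' @rdname predict_over_record
#' @param object A fitted `stepop` object.
#' @param newdata A [waveform_record()].
#' @param ... Passed to [predict_over_record()].
predict.stepop <- function(object, newdata, ...) {
  predict_over_record(newdata, object, ...)
}

#' Diagnostic plots for a fitted ensemble
#'
#' `which = "alpha"` draws the tuning AUPRC over the mixing-weight
#' grid; `"pr"` the validation precision-recall curves of the four
#' models; `"history"` the deep models' training curves.
#'
#' @param x A fitted `stepop` object.
#' @param which One of `"alpha"`, `"pr"`, `"history"`.
#' @param ... Ignored.
#' @export
plot.stepop <- function(x, which = c("alpha", "pr", "history"), ...) {
  which <- match.arg(which)
  if (which == "alpha") {
    curve <- x$weights$curve
    graphics::plot(curve$alpha, curve$auprc, type = "l",
                   xlab = expression(alpha), ylab = "tuning AUPRC",
                   main = "Ensemble weight tuning")
    graphics::abline(v = x$weights$alpha, lty = 2)
  } else if (which == "pr") {
    v <- x$validation
    cols <- c(stepop = "black", cnn = "tomato", rnn = "steelblue",
              logistic = "darkgreen")
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                   ylab = "Precision", main = "Validation PR curves")
    ps <- list(stepop = v$p_stepop, cnn = v$p_cnn, rnn = v$p_rnn,
               logistic = v$p_logistic)
    for (m in names(ps)) {
      pr <- .pr_points(ps[[m]], v$labels)
      graphics::lines(pr$recall, pr$precision, col = cols[m])
    }
    graphics::legend("bottomleft", names(ps), col = cols, lty = 1, bty = "n")
  } else {
    h1 <- x$models$cnn$history
    h2 <- x$models$rnn$history
    graphics::plot(h1$epoch, h1$tune_auprc, type = "b", col = "tomato",
                   ylim = range(c(h1$tune_auprc, h2$tune_auprc)),
                   xlab = "epoch", ylab = "inner-split AUPRC",
                   main = "Checkpoint selection")
    graphics::lines(h2$epoch, h2$tune_auprc, type = "b", col = "steelblue")
    graphics::legend("bottomright", c("CNN", "RNN"),
                     col = c("tomato", "steelblue"), lty = 1, bty = "n")
  }
  invisible(x)
}

.pr_points <- function(scores, labels, n_thresholds = 200) {
  thr <- sort(unique(scores), decreasing = TRUE)
  if (length(thr) > n_thresholds) {
    thr <- thr[unique(as.integer(seq(1, length(thr),
                                     length.out = n_thresholds)))]
  }
  p_total <- sum(labels)
  out <- t(vapply(thr, function(t) {
    sel <- scores >= t
    c(sum(labels[sel]) / p_total, sum(labels[sel]) / sum(sel))
  }, numeric(2)))
  data.frame(recall = out[, 1], precision = out[, 2])
}
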