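#' Area under the precision-recall curve (average precision)
#'
#' Average-precision form: ranking by score descending, the AUPRC is
#' the sum over ranks holding a positive of (recall increment times
#' precision at that rank). Tied scores are grouped into a single step
#' so the value does not depend on the ordering within ties. The
#' average-precision (step) estimator is used rather than trapezoidal
#' interpolation of the PR curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUPRC in `[0, 1]`.
#' @examples
#' auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1: perfect ranking
#' auprc(c(0.9, 0.8, 0.7), c(0, 1, 1))          # 7/12
#' @export
auprc <- function(scores, labels) {
  labels <- .check_binary(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores into one PR step: ends[k] = last index of group k
  ends <- c(which(!duplicated(s))[-1] - 1L, length(s))
  tp <- cumsum(y)[ends]
  prec <- tp / ends
  d_tp <- diff(c(0, tp))
  sum(d_tp / sum(y) * prec)
}

#' Area under the ROC curve
#'
#' Computed in rank-statistic form: the probability that a randomly
#' chosen positive outranks a randomly chosen negative, with tied
#' scores counted one half.
#'
#' @inheritParams auprc
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- .check_binary(scores, labels)
  r <- rank(scores)  # midranks handle ties as 1/2
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.check_binary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present")
  }
  labels
}

#' Precision at a target sensitivity
#'
#' Chooses the highest decision threshold whose sensitivity (recall) is
#' at least `target` and reports the precision and achieved sensitivity
#' there; no interpolation between thresholds is performed.
#'
#' @inheritParams auprc
#' @param target Target sensitivity in `(0, 1]`.
#' @return A list with `threshold`, `precision`, `sensitivity`.
#' @export
precision_at_sensitivity <- function(scores, labels, target) {
  labels <- .check_binary(scores, labels)
  stopifnot(target > 0, target <= 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  p_total <- sum(labels)
  for (t in thr) {
    sel <- scores >= t
    sens <- sum(labels[sel]) / p_total
    if (sens >= target) {
      return(list(threshold = t,
                  precision = sum(labels[sel]) / sum(sel),
                  sensitivity = sens))
    }
  }
  # target <= 1 with >= 1 positive always reachable at the lowest threshold
  sel <- rep(TRUE, length(scores))
  list(threshold = min(scores), precision = mean(labels), sensitivity = 1)
}

#' Tune the ensemble mixing weight on held-out predictions
#'
#' Evaluates the AUPRC of the convex combination
#' `alpha * p_rnn + (1 - alpha) * p_cnn` over the grid
#' `{0, grid_step, ..., 1}` on the tuning segments (the inner 10% of
#' training patients) and returns the maximizing `alpha`; ties are
#' broken toward the smallest `alpha`. The full tuning curve is
#' retained for plotting. Because the grid contains 0 and 1, the
#' tuning-set AUPRC at the returned weight is never below either
#' single model's tuning AUPRC.
#'
#' @param p_rnn,p_cnn Prediction vectors on the same tuning segments,
#'   aligned elementwise (misaligned lengths are an error).
#' @param labels Binary labels of the tuning segments.
#' @param grid_step Grid resolution (default 0.01).
#' @return An object of class `ensemble_weights`: list with `alpha`
#'   and `curve` (data frame `alpha`, `auprc`).
#' @export
optimize_alpha <- function(p_rnn, p_cnn, labels, grid_step = 0.01) {
  if (length(p_rnn) != length(p_cnn) || length(p_rnn) != length(labels)) {
    stop("p_rnn, p_cnn and labels must be aligned on the same segments")
  }
  grid <- seq(0, 1, by = grid_step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  vals <- vapply(grid, function(a) auprc(a * p_rnn + (1 - a) * p_cnn, labels),
                 numeric(1))
  structure(list(alpha = grid[which.max(vals)],
                 curve = data.frame(alpha = grid, auprc = vals)),
            class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat(sprintf("<ensemble_weights> alpha = %.2f (tuning AUPRC %.4f)\n",
              x$alpha, max(x$curve$auprc)))
  invisible(x)
}

#' Weighted-average ensemble prediction
#'
#' Elementwise convex combination
#' `alpha * p_rnn + (1 - alpha) * p_cnn`.
#'
#' @param p_rnn,p_cnn Aligned prediction vectors in `[0, 1]`.
#' @param alpha Mixing weight in `[0, 1]`, or an `ensemble_weights`
#'   object.
#' @return Numeric vector in `[0, 1]`.
#' @export
ensemble_predict <- function(p_rnn, p_cnn, alpha) {
  if (inherits(alpha, "ensemble_weights")) alpha <- alpha$alpha
  stopifnot(alpha >= 0, alpha <= 1)
  if (length(p_rnn) != length(p_cnn)) {
    stop("p_rnn and p_cnn must be aligned on the same segments")
  }
  alpha * p_rnn + (1 - alpha) * p_cnn
}

#' Subsampling bootstrap confidence interval for a ranking metric
#'
#' Each resample draws `fraction * n` segments without replacement (a
#' subsampling bootstrap; with-replacement resampling is available by
#' flag), recomputes the metric, and the CI is the 2.5th/97.5th
#' percentile of the `n_resamples` values. Resamples containing a
#' single class are redrawn and counted in the `n_redrawn` attribute.
#'
#' @inheritParams auprc
#' @param metric Function `(scores, labels) -> numeric` (e.g. [auprc()]).
#' @param n_resamples Number of resamples (default 1000).
#' @param fraction Fraction of segments per resample (default 0.5).
#' @param seed Integer seed; the interval is deterministic given it.
#' @param replace Resample with replacement? Default `FALSE`.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` with attributes `n_redrawn` and
#'   `values` (the resample metric values).
#' @export
bootstrap_ci <- function(scores, labels, metric = auprc,
                         n_resamples = 1000, fraction = 0.5, seed = 1,
                         replace = FALSE, level = 0.95) {
  labels <- .check_binary(scores, labels)
  n <- length(scores)
  m <- max(2L, as.integer(floor(fraction * n)))
  if (!replace && m >= n) stop("n too small for the resample fraction")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  vals <- numeric(n_resamples)
  n_redrawn <- 0L
  for (b in seq_len(n_resamples)) {
    repeat {
      idx <- sample.int(n, m, replace = replace)
      if (length(unique(labels[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    vals[b] <- metric(scores[idx], labels[idx])
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  structure(ci, n_redrawn = n_redrawn, values = vals)
}

#' Full evaluation report for one prediction set
#'
#' AUPRC, AUROC and precision at sensitivity 0.6/0.7/0.8, each with a
#' subsampling-bootstrap 95% CI (1000 resamples of 50% by default).
#'
#' @inheritParams bootstrap_ci
#' @param sens_targets Sensitivity targets (default `c(0.6, 0.7, 0.8)`).
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(scores, labels, n_resamples = 1000, fraction = 0.5,
                        seed = 1, sens_targets = c(0.6, 0.7, 0.8)) {
  labels <- .check_binary(scores, labels)
  rep <- list(
    n = length(scores),
    prevalence = mean(labels),
    auprc = auprc(scores, labels),
    auroc = auroc(scores, labels),
    n_resamples = n_resamples,
    resample_fraction = fraction
  )
  ci <- bootstrap_ci(scores, labels, auprc, n_resamples, fraction, seed)
  rep$auprc_ci <- as.numeric(ci)
  ci <- bootstrap_ci(scores, labels, auroc, n_resamples, fraction, seed + 1)
  rep$auroc_ci <- as.numeric(ci)
  rep$precision_at_sensitivity <- lapply(sens_targets, function(tg) {
    pt <- precision_at_sensitivity(scores, labels, tg)
    ci <- bootstrap_ci(scores, labels,
                       function(s, y) precision_at_sensitivity(s, y, tg)$precision,
                       n_resamples, fraction, seed + round(100 * tg))
    list(target = tg, threshold = pt$threshold, precision = pt$precision,
         sensitivity = pt$sensitivity, ci = as.numeric(ci))
  })
  names(rep$precision_at_sensitivity) <- paste0("sens_", sens_targets)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, prevalence = %.3f\n", x$n, x$prevalence))
  cat(sprintf("  AUPRC %.4f (95%% CI %.4f-%.4f)\n",
              x$auprc, x$auprc_ci[1], x$auprc_ci[2]))
  cat(sprintf("  AUROC %.4f (95%% CI %.4f-%.4f)\n",
              x$auroc, x$auroc_ci[1], x$auroc_ci[2]))
  for (p in x$precision_at_sensitivity) {
    cat(sprintf("  precision at sensitivity %.1f: %.4f (achieved %.3f, CI %.4f-%.4f)\n",
                p$target, p$precision, p$sensitivity, p$ci[1], p$ci[2]))
  }
  invisible(x)
}
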