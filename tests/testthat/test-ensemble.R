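test_that("AUPRC matches enumeration oracles including tied scores", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(0, 1, 1)), 7 / 12)
  set.seed(31)
  for (i in 1:40) {
    n <- sample(5:200, 1)
    scores <- if (i %% 2) runif(n) else sample(seq(0, 1, 0.1), n, TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auprc(scores, labels), oracle_ap(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auprc(runif(5), rep(1, 5)), "both classes")
})

test_that("random scores give AUPRC near the prevalence", {
  set.seed(5)
  n <- 1e5
  labels <- rbinom(n, 1, 0.3)
  expect_lt(abs(auprc(runif(n), labels) - mean(labels)), 0.01)
})

test_that("AUROC equals the tie-corrected pairwise-comparison statistic", {
  expect_equal(auroc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  expect_equal(auroc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:150, 1)
    scores <- sample(seq(0, 1, 0.05), n, TRUE)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("precision at sensitivity picks the highest admissible threshold", {
  # perfect classifier
  res <- precision_at_sensitivity(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.8)
  expect_equal(res$precision, 1)
  # worked 4-point fixture: threshold must admit both positives
  res <- precision_at_sensitivity(c(0.9, 0.6, 0.4, 0.2),
                                  c(1, 0, 1, 0), 0.6)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$precision, 2 / 3)
  expect_equal(res$threshold, 0.4)
  # target 1 captures every positive
  res <- precision_at_sensitivity(c(0.9, 0.6, 0.4, 0.2),
                                  c(1, 0, 1, 0), 1)
  expect_lte(res$threshold, 0.4)
  expect_equal(res$sensitivity, 1)
  # enumeration oracle over random fixtures
  set.seed(14)
  for (i in 1:20) {
    n <- 40
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    for (tg in c(0.6, 0.7, 0.8)) {
      res <- precision_at_sensitivity(scores, labels, tg)
      cand <- sort(unique(scores), decreasing = TRUE)
      sens <- vapply(cand, function(t) {
        sum(labels[scores >= t]) / sum(labels)
      }, numeric(1))
      best <- cand[sens >= tg][1]
      expect_equal(res$threshold, best)
      expect_equal(res$precision,
                   sum(labels[scores >= best]) / sum(scores >= best))
    }
  }
})

test_that("alpha optimization equals brute-force grid search with its tie-break", {
  set.seed(3)
  y <- rbinom(60, 1, 0.35)
  y[1] <- 1; y[2] <- 0
  p_rnn <- runif(60); p_cnn <- runif(60)
  w <- optimize_alpha(p_rnn, p_cnn, y)
  grid <- seq(0, 1, 0.01)
  vals <- vapply(grid, function(a) auprc(a * p_rnn + (1 - a) * p_cnn, y),
                 numeric(1))
  expect_equal(w$alpha, grid[which.max(vals)])
  expect_equal(w$curve$auprc, vals, tolerance = 1e-12)
  # identical inputs: the curve is flat, the tie-break returns alpha 0
  w0 <- optimize_alpha(p_cnn, p_cnn, y)
  expect_equal(w0$alpha, 0)
  # one model perfectly ranks while the other anti-ranks
  sep <- c(rep(0.9, 20), rep(0.1, 40))
  ysep <- c(rep(1, 20), rep(0, 40))
  w1 <- optimize_alpha(sep, 1 - sep, ysep)
  expect_equal(max(w1$curve$auprc), 1)
  expect_equal(auprc(w1$alpha * sep + (1 - w1$alpha) * (1 - sep), ysep), 1)
  expect_error(optimize_alpha(p_rnn[1:10], p_cnn, y), "aligned")
})

test_that("the tuned weight never loses to either single model on the tuning set", {
  set.seed(9)
  for (i in 1:10) {
    y <- rbinom(80, 1, 0.3)
    if (length(unique(y)) < 2) next
    p_rnn <- pmin(pmax(y * 0.3 + runif(80), 0), 1)
    p_cnn <- pmin(pmax(y * 0.2 + runif(80), 0), 1)
    w <- optimize_alpha(p_rnn, p_cnn, y)
    best <- auprc(ensemble_predict(p_rnn, p_cnn, w), y)
    expect_gte(best, auprc(p_rnn, y))
    expect_gte(best, auprc(p_cnn, y))
  }
})

test_that("ensemble prediction is the stated convex combination", {
  expect_equal(ensemble_predict(0.8, 0.6, 0.65), 0.73)
  p_rnn <- runif(20); p_cnn <- runif(20)
  expect_identical(ensemble_predict(p_rnn, p_cnn, 0), p_cnn)
  expect_identical(ensemble_predict(p_rnn, p_cnn, 1), p_rnn)
  # monotone in alpha when p_rnn >= p_cnn elementwise
  hi <- pmax(p_rnn, p_cnn); lo <- pmin(p_rnn, p_cnn)
  out <- vapply(seq(0, 1, 0.1),
                function(a) mean(ensemble_predict(hi, lo, a)), numeric(1))
  expect_true(all(diff(out) >= 0))
  expect_error(ensemble_predict(runif(3), runif(4), 0.5), "aligned")
})

test_that("subsampling bootstrap CIs are deterministic and well-ordered", {
  set.seed(2)
  y <- rbinom(300, 1, 0.25)
  s <- y * 0.4 + runif(300) * 0.6
  ci1 <- bootstrap_ci(s, y, auprc, n_resamples = 200, seed = 7)
  ci2 <- bootstrap_ci(s, y, auprc, n_resamples = 200, seed = 7)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  point <- auprc(s, y)
  expect_lte(ci1[1], ci1[2])
  # a perfect classifier has a degenerate (zero-width) interval
  sp <- ifelse(y == 1, 0.9, 0.1)
  ci0 <- bootstrap_ci(sp, y, auprc, n_resamples = 100, seed = 1)
  expect_equal(unname(ci0[1]), 1)
  expect_equal(unname(ci0[2]), 1)
  # the interval covers the point estimate on typical fixtures
  expect_true(ci1[1] <= point && point <= ci1[2])
  expect_error(bootstrap_ci(c(0.2, 0.8), c(0, 1), auprc, fraction = 0.5),
               "too small")
})

test_that("the evaluation report assembles all metrics with CIs", {
  set.seed(6)
  y <- rbinom(250, 1, 0.3)
  s <- y * 0.35 + runif(250) * 0.65
  rep <- eval_report(s, y, n_resamples = 100, seed = 4)
  expect_equal(rep$auprc, auprc(s, y))
  expect_equal(rep$auroc, auroc(s, y))
  expect_true(rep$auprc_ci[1] <= rep$auprc &&
                rep$auprc <= rep$auprc_ci[2])
  expect_named(rep$precision_at_sensitivity,
               c("sens_0.6", "sens_0.7", "sens_0.8"))
  for (p in rep$precision_at_sensitivity) {
    expect_gte(p$sensitivity, p$target)
  }
})
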