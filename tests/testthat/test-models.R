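# compact shared fixture: separable two-feature problem rendered as
# waveform-level inputs via the simulator is exercised in the
# acceptance suite; here a tiny cohort keeps unit runtimes low
tiny_cohort <- function(seed = 3, n_patients = 8) {
  cfg <- small_pipeline_config(seed = seed, n_patients = n_patients)
  dir <- tempfile()
  simulate_cohort(cfg$sim, file.path(dir, "records"))
  ds <- build_dataset(cfg, file.path(dir, "records"))
  ds$cfg <- cfg
  ds
}

test_that("weighted binary cross entropy matches hand-computed values", {
  expect_equal(weighted_bce(0.5, 1), 20 * log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 0), log(2), tolerance = 1e-12)
  # batch {pos p = 0.9, neg p = 0.1}: mean(20 * -log(.9), -log(.9))
  expect_equal(weighted_bce(c(0.9, 0.1), c(1, 0)),
               mean(c(20, 1) * -log(0.9)), tolerance = 1e-12)
  # probabilities at the boundary are clipped, not infinite
  expect_true(is.finite(weighted_bce(c(0, 1), c(1, 0))))
  # linearity in the class weight: duplicating the positive doubles its
  # contribution exactly as the formula predicts
  l1 <- weighted_bce(c(0.8, 0.3), c(1, 0))
  l2 <- weighted_bce(c(0.8, 0.8, 0.3), c(1, 1, 0))
  expect_equal(l2, (2 * 20 * -log(0.8) + -log(0.7)) / 3, tolerance = 1e-12)
  expect_equal(l1, (20 * -log(0.8) + -log(0.7)) / 2, tolerance = 1e-12)
})

test_that("deep-model training is bitwise deterministic under a fixed seed", {
  ds <- tiny_cohort(seed = 3, n_patients = 6)
  tc <- train_config(epochs = 2, batch_size = 32, seed = 4)
  ca <- cnn_config(filters = c(4, 8), kernels = c(7, 5), pool = c(4, 4))
  m1 <- train_cnn(ds$x_cnn, ds$y, ds$patient_id, tc, ca)
  m2 <- train_cnn(ds$x_cnn, ds$y, ds$patient_id, tc, ca)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, ds$x_cnn), predict(m2, ds$x_cnn))

  ra <- rnn_config(n_layers = 2, hidden = 8)
  r1 <- train_rnn(ds$x_rnn, ds$y, ds$patient_id, tc, ra)
  r2 <- train_rnn(ds$x_rnn, ds$y, ds$patient_id, tc, ra)
  expect_identical(r1$params, r2$params)
  expect_identical(predict(r1, ds$x_rnn), predict(r2, ds$x_rnn))

  # predictions are probabilities, duplicated inputs give duplicated
  # outputs, empty input gives empty output
  p <- predict(m1, ds$x_cnn)
  expect_true(all(p >= 0 & p <= 1 & is.finite(p)))
  expect_equal(predict(m1, ds$x_cnn[c(1, 1), ])[1],
               predict(m1, ds$x_cnn[c(1, 1), ])[2])
  expect_length(predict(m1, ds$x_cnn[0, , drop = FALSE]), 0)
  expect_length(predict(r1, ds$x_rnn[0, , , drop = FALSE]), 0)

  expect_error(train_cnn(ds$x_cnn, rep(1, length(ds$y)), ds$patient_id,
                         tc, ca),
               "single-class")
})

test_that("ridge logistic coefficients match a penalized-likelihood oracle", {
  set.seed(11)
  n <- 400
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  eta <- 1.2 * x[, "a"] - 0.7 * x[, "b"]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  lam <- 0.05
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lam, standardize = FALSE,
                        thresh = 1e-12)
  beta_glmnet <- as.numeric(rbind(fit$a0, fit$beta))
  # independent optimizer on the same objective:
  # -(1/n) loglik + lambda/2 * ||beta||^2 (intercept unpenalized)
  obj <- function(b) {
    z <- b[1] + x %*% b[-1]
    -mean(y * z - log1p(exp(z))) + lam / 2 * sum(b[-1]^2)
  }
  opt <- stats::optim(rep(0, 4), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  expect_equal(beta_glmnet, opt$par, tolerance = 1e-4)
})

test_that("the logistic baseline behaves correctly in degenerate settings", {
  set.seed(21)
  n <- 300
  pid <- rep(sprintf("p%d", 1:10), each = 30)
  # one feature perfectly separates the classes
  y <- rep(c(0, 1), 150)
  x <- cbind(sep = ifelse(y == 1, 1, -1) + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  m <- train_logistic(x, y, pid)
  expect_gt(auprc(predict(m, x), y), 0.99)
  # all-constant features: predictions collapse to the prevalence
  xc <- cbind(a = rep(1, n), b = rep(2, n))
  y2 <- rbinom(n, 1, 0.3)
  m2 <- train_logistic(xc, y2, pid)
  expect_equal(unname(predict(m2, xc)), rep(mean(y2), n), tolerance = 1e-6)
  expect_error(train_logistic(x, rep(0, n), pid), "single-class")
})
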