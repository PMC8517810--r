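#' Training configuration for the deep models
#'
#' Defaults follow the optimization recipe of the method: AdamW with
#' `beta1 = 0.9`, `beta2 = 0.99`, learning rate `1e-4`, class-weighted
#' binary cross entropy with weights 1 (negative) and 20 (positive),
#' and model selection on an inner 10% of training patients (training
#' runs on the remaining 90%; the checkpoint with the best inner-split
#' AUPRC is kept). Epochs, batch size and weight decay are not part of
#' the published recipe and are tunable.
#'
#' @param learning_rate AdamW learning rate (default `1e-4`).
#' @param adam_beta1,adam_beta2 AdamW moment decays (defaults 0.9, 0.99).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param class_weights Length-2 vector `c(negative, positive)` loss
#'   weights (default `c(1, 20)`).
#' @param epochs Training epochs (default 20).
#' @param batch_size Minibatch size (default 256).
#' @param model_select_frac Fraction of training patients held out for
#'   checkpoint selection (default 0.10).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.99, weight_decay = 0.01,
                         class_weights = c(1, 20), epochs = 20,
                         batch_size = 256, model_select_frac = 0.10,
                         seed = 1) {
  stopifnot(all(class_weights > 0), epochs >= 1, batch_size >= 1,
            model_select_frac > 0, model_select_frac < 1)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, weight_decay = weight_decay,
                 class_weights = class_weights, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 model_select_frac = model_select_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Convolutional-network architecture
#'
#' One-dimensional convolution blocks (convolution, batch
#' normalization, ReLU, max pooling), global average pooling and a
#' fully connected sigmoid head on the scaled length-2000 waveform.
#'
#' @param kernels Kernel size per block (default `c(7, 5, 3)`).
#' @param filters Filter count per block (default `c(16, 32, 64)`).
#' @param pool Max-pool width per block (default `c(4, 4, 4)`).
#' @param dropout Dropout rate on the pooled feature vector (default 0).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(kernels = c(7, 5, 3), filters = c(16, 32, 64),
                       pool = c(4, 4, 4), dropout = 0) {
  stopifnot(length(kernels) >= 1, length(kernels) == length(filters),
            length(kernels) == length(pool), all(kernels %% 2 == 1))
  structure(list(kernels = as.integer(kernels),
                 filters = as.integer(filters),
                 pool = as.integer(pool), dropout = dropout),
            class = "cnn_config")
}

#' Recurrent-network architecture
#'
#' Stacked bidirectional LSTM over the 30 x 100 beat matrix (each
#' cardiac cycle is one time step); the final forward and backward
#' hidden states are concatenated into a fully connected sigmoid head.
#' Zero-padded rows are fed as-is (no masking).
#'
#' @param n_layers Number of stacked layers (default 3).
#' @param hidden Hidden size per direction (default 64).
#' @param bidirectional Must be `TRUE` (kept for config completeness).
#' @param dropout Dropout rate on the concatenated final state
#'   (default 0).
#' @param clip Global gradient-norm clip (default 5).
#' @return An object of class `rnn_config`.
#' @export
rnn_config <- function(n_layers = 3, hidden = 64, bidirectional = TRUE,
                       dropout = 0, clip = 5) {
  stopifnot(n_layers >= 1, hidden >= 1, isTRUE(bidirectional))
  structure(list(n_layers = as.integer(n_layers),
                 hidden = as.integer(hidden), bidirectional = TRUE,
                 dropout = dropout, clip = clip),
            class = "rnn_config")
}

#' Class-weighted binary cross entropy
#'
#' Mean over the batch of `w(y) * (-y log p - (1 - y) log(1 - p))` with
#' `w(1)` the positive and `w(0)` the negative class weight.
#' Probabilities at exactly 0 or 1 are clipped at `eps`.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels (0/1).
#' @param class_weights `c(negative, positive)` weights (default
#'   `c(1, 20)`).
#' @param eps Clipping constant (default `1e-7`).
#' @return The scalar loss.
#' @examples
#' weighted_bce(0.5, 1)  # 20 * log(2)
#' weighted_bce(0.5, 0)  # log(2)
#' @export
weighted_bce <- function(probabilities, labels, class_weights = c(1, 20),
                         eps = 1e-7) {
  stopifnot(length(probabilities) == length(labels),
            all(probabilities >= 0), all(probabilities <= 1))
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  y <- as.numeric(labels)
  w <- ifelse(y == 1, class_weights[2], class_weights[1])
  mean(w * (-y * log(p) - (1 - y) * log(1 - p)))
}

# Deterministic inner 90/10 patient split + per-epoch shuffles shared by
# both deep models.
.inner_split <- function(patient_id, config) {
  ids <- unique(patient_id)
  if (length(ids) < 2) {
    return(list(fit = ids, tune = character(0)))
  }
  sp <- split_patients(ids, train_frac = 1 - config$model_select_frac,
                       seed = config$seed + 977L)
  list(fit = sp$train, tune = sp$validation)
}

.epoch_perms <- function(n, epochs, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  t(vapply(seq_len(epochs), function(e) sample.int(n), integer(n))) - 1L
}

.check_two_classes <- function(y) {
  if (length(unique(y)) < 2) stop("single-class training data")
}

#' Train the 1-D convolutional network
#'
#' Trains on the 90% of training patients not held out for model
#' selection and keeps the checkpoint with the best AUPRC on the inner
#' 10%. Deterministic given `config$seed` (single-threaded execution).
#'
#' @param x Numeric matrix, one scaled length-2000 segment per row (see
#'   [scale_values()]).
#' @param y Binary labels (1 = hypotensive outcome).
#' @param patient_id Character vector, one entry per row; the inner
#'   90/10 split is at patient level.
#' @param config A [train_config()].
#' @param arch A [cnn_config()].
#' @return An object of class `stepop_cnn` with elements `params`,
#'   `arch`, `config`, `history` (per-epoch train loss and inner
#'   AUPRC), `best_epoch`, `inner` (fit/tune patient ids), and `tune`
#'   (inner-split indices, labels and predictions from the selected
#'   checkpoint — the ensemble weight is tuned on these).
#' @export
train_cnn <- function(x, y, patient_id, config = train_config(),
                      arch = cnn_config()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), length(patient_id) == length(y))
  .check_two_classes(y)
  inner <- .inner_split(patient_id, config)
  fit_idx <- which(patient_id %in% inner$fit)
  tune_idx <- which(patient_id %in% inner$tune)
  .check_two_classes(y[fit_idx])
  perms <- .epoch_perms(length(fit_idx), config$epochs, config$seed + 11L)
  init <- .cnn_init(arch, ncol(x), config$seed + 13L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 17L)  # dropout draws inside C++
  res <- cnn_train_cpp(x[fit_idx, , drop = FALSE], y[fit_idx],
                       x[tune_idx, , drop = FALSE], y[tune_idx],
                       unclass(arch), .cpp_train_cfg(config), init, perms)
  tune_pred <- if (length(tune_idx)) {
    as.numeric(cnn_predict_cpp(x[tune_idx, , drop = FALSE], unclass(arch),
                               res$params))
  } else numeric(0)
  structure(list(params = res$params, arch = arch, config = config,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train_loss = res$train_loss,
                                      tune_auprc = res$tune_auprc),
                 best_epoch = res$best_epoch, inner = inner,
                 tune = list(index = tune_idx, labels = y[tune_idx],
                             probabilities = tune_pred)),
            class = "stepop_cnn")
}

#' Train the stacked bidirectional LSTM
#'
#' @param x Numeric array of beat matrices, `dim = c(n, 30, 100)`
#'   (scaled rows, as from [build_beat_matrix()]).
#' @inheritParams train_cnn
#' @param arch An [rnn_config()].
#' @return An object of class `stepop_rnn`, structured like
#'   [train_cnn()]'s result.
#' @export
train_rnn <- function(x, y, patient_id, config = train_config(),
                      arch = rnn_config()) {
  stopifnot(length(dim(x)) == 3)
  y <- as.numeric(y)
  stopifnot(dim(x)[1] == length(y), length(patient_id) == length(y))
  .check_two_classes(y)
  inner <- .inner_split(patient_id, config)
  fit_idx <- which(patient_id %in% inner$fit)
  tune_idx <- which(patient_id %in% inner$tune)
  .check_two_classes(y[fit_idx])
  perms <- .epoch_perms(length(fit_idx), config$epochs, config$seed + 19L)
  init <- .lstm_init(arch, input_dim = dim(x)[3], seed = config$seed + 23L)
  xc <- .to_cube(x)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 29L)
  res <- lstm_train_cpp(xc[, , fit_idx, drop = FALSE], y[fit_idx],
                        xc[, , tune_idx, drop = FALSE], y[tune_idx],
                        unclass(arch), .cpp_train_cfg(config), init, perms)
  tune_pred <- if (length(tune_idx)) {
    as.numeric(lstm_predict_cpp(xc[, , tune_idx, drop = FALSE],
                                unclass(arch), res$params))
  } else numeric(0)
  structure(list(params = res$params, arch = arch, config = config,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train_loss = res$train_loss,
                                      tune_auprc = res$tune_auprc),
                 best_epoch = res$best_epoch, inner = inner,
                 tune = list(index = tune_idx, labels = y[tune_idx],
                             probabilities = tune_pred)),
            class = "stepop_rnn")
}

# (n, T, D) array -> (T, D, n) cube layout expected by the C++ side
.to_cube <- function(x) aperm(x, c(2, 3, 1))

.cpp_train_cfg <- function(config) {
  list(learning_rate = config$learning_rate,
       adam_beta1 = config$adam_beta1, adam_beta2 = config$adam_beta2,
       weight_decay = config$weight_decay,
       w_neg = config$class_weights[1], w_pos = config$class_weights[2],
       epochs = config$epochs, batch_size = config$batch_size)
}

.cnn_init <- function(arch, input_len, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  init <- list()
  cin <- 1L
  for (l in seq_along(arch$kernels)) {
    k <- arch$kernels[l]; f <- arch$filters[l]
    sd <- sqrt(2 / (cin * k))  # He initialization for ReLU blocks
    init[[paste0("W", l)]] <- matrix(stats::rnorm(f * cin * k, 0, sd), f)
    init[[paste0("b", l)]] <- rep(0, f)
    init[[paste0("g", l)]] <- rep(1, f)
    init[[paste0("beta", l)]] <- rep(0, f)
    init[[paste0("rmean", l)]] <- rep(0, f)
    init[[paste0("rvar", l)]] <- rep(1, f)
    cin <- f
  }
  init$fcW <- matrix(stats::rnorm(cin, 0, 1 / sqrt(cin)), ncol = 1)
  init$fcb <- 0
  init
}

.lstm_init <- function(arch, input_dim, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  H <- arch$hidden
  s <- 1 / sqrt(H)
  init <- list()
  din <- input_dim
  for (l in seq_len(arch$n_layers)) {
    for (d in c("f", "b")) {
      init[[paste0("W_", d, l)]] <- matrix(stats::runif(din * 4 * H, -s, s),
                                           din)
      init[[paste0("U_", d, l)]] <- matrix(stats::runif(H * 4 * H, -s, s), H)
      init[[paste0("b_", d, l)]] <- matrix(stats::runif(4 * H, -s, s), 1)
    }
    din <- 2L * H
  }
  init$fcW <- matrix(stats::rnorm(2 * H, 0, s), ncol = 1)
  init$fcb <- 0
  init
}

#' @export
predict.stepop_cnn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  as.numeric(cnn_predict_cpp(newdata, unclass(object$arch), object$params))
}

#' @export
predict.stepop_rnn <- function(object, newdata, ...) {
  stopifnot(length(dim(newdata)) == 3)
  if (dim(newdata)[1] == 0) return(numeric(0))
  as.numeric(lstm_predict_cpp(.to_cube(newdata), unclass(object$arch),
                              object$params))
}

#' @export
print.stepop_cnn <- function(x, ...) {
  cat(sprintf("<stepop_cnn> %d blocks (k=%s, f=%s), best epoch %d, inner AUPRC %.4f\n",
              length(x$arch$kernels), paste(x$arch$kernels, collapse = "/"),
              paste(x$arch$filters, collapse = "/"), x$best_epoch,
              max(x$history$tune_auprc)))
  invisible(x)
}

#' @export
print.stepop_rnn <- function(x, ...) {
  cat(sprintf("<stepop_rnn> %d bidirectional layers, hidden %d, best epoch %d, inner AUPRC %.4f\n",
              x$arch$n_layers, x$arch$hidden, x$best_epoch,
              max(x$history$tune_auprc)))
  invisible(x)
}

#' Train the logistic-regression baseline
#'
#' Ridge (L2) logistic regression on the 12 robust-scaled waveform
#' features, with the regularization strength selected by 5-fold
#' cross-validation over a logarithmic grid. Folds are grouped by
#' patient to avoid leakage, then the model is refit on all training
#' rows at the selected strength.
#'
#' @param x Numeric matrix of robust-scaled features (see
#'   [apply_scaler()]).
#' @param y Binary labels.
#' @param patient_id Character vector for patient-grouped folds.
#' @param nfolds Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param lambda Optional penalty grid (default: logarithmic grid
#'   `10^seq(2, -6)`).
#' @return An object of class `stepop_logistic` wrapping the
#'   `cv.glmnet` fit.
#' @export
train_logistic <- function(x, y, patient_id, nfolds = 5, seed = 1,
                           lambda = 10^seq(2, -6, length.out = 60)) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  .check_two_classes(y)
  if (all(apply(x, 2, stats::var) == 0)) {
    # degenerate design: intercept-only model, probability = prevalence
    return(structure(list(fit = NULL, lambda = NA_real_,
                          intercept_only = TRUE, p = mean(y),
                          feature_names = colnames(x)),
                     class = "stepop_logistic"))
  }
  ids <- unique(patient_id)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nf <- min(nfolds, length(ids))
  fold_of <- sample(rep_len(seq_len(nf), length(ids)))
  names(fold_of) <- ids
  foldid <- fold_of[as.character(patient_id)]
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                           lambda = lambda, foldid = foldid,
                           standardize = FALSE)
  structure(list(fit = fit, lambda = fit$lambda.min,
                 feature_names = colnames(x)),
            class = "stepop_logistic")
}

#' @export
predict.stepop_logistic <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  if (isTRUE(object$intercept_only)) return(rep(object$p, nrow(newdata)))
  as.numeric(stats::predict(object$fit, newx = newdata,
                            s = object$lambda, type = "response"))
}

#' @export
print.stepop_logistic <- function(x, ...) {
  cat(sprintf("<stepop_logistic> ridge logistic baseline, lambda = %.3g\n",
              x$lambda))
  invisible(x)
}

#' @export
coef.stepop_logistic <- function(object, ...) {
  if (isTRUE(object$intercept_only)) {
    return(c("(Intercept)" = log(object$p / (1 - object$p))))
  }
  cf <- stats::coef(object$fit, s = object$lambda)
  stats::setNames(as.numeric(cf), rownames(cf))
}
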