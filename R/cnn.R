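#' Training hyper-parameters for the CNN
#'
#' @param learning_rate gradient-descent step size alpha (> 0).
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param train_fraction fraction of trials assigned to the training split,
#'   stratified by class, in (0, 1).
#' @param seed integer seed controlling the split, the weight initialization
#'   and the batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 50L, batch_size = 32L,
                         train_fraction = 0.8, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize the four-layer CNN
#'
#' Architecture: valid 2x2 convolution with `n_kernels` kernels -> ReLU ->
#' 2x2 max-pooling (stride 2) -> flatten -> dense ReLU layer of `fc1_units`
#' -> dense linear output layer with one score per class.  For the default
#' 25 x 500 input this gives 24 x 499 conv maps pooled to 12 x 249, i.e.
#' `12 * 249 * n_kernels` flattened features.  Weights are initialized from a
#' zero-mean uniform distribution scaled by 1/sqrt(fan-in); biases start at 0.
#'
#' @param input_shape integer 2-vector, bins x frames of the feature maps.
#' @param classes character vector of class labels (default the 8 labels of
#'   [class_labels()]).
#' @param n_kernels number of 2x2 convolution kernels.
#' @param fc1_units width of the first dense layer.
#' @param seed integer seed for the weight draw.
#' @param pipeline list of featurization settings baked into the model and
#'   used by [predict_epoch()]: `low`, `high`, `filter_order`, `step`,
#'   `kaiser_beta`.
#' @return An object of class `ssvep_cnn`.
#' @export
cnn_init <- function(input_shape = c(25L, 500L),
                     classes = class_labels(),
                     n_kernels = 8L, fc1_units = 64L, seed = 1L,
                     pipeline = list(low = 5, high = 30, filter_order = 4,
                                     step = 1, kaiser_beta = 0.5)) {
  d1 <- as.integer(input_shape[1]); d2 <- as.integer(input_shape[2])
  pu <- (d1 - 1L) %/% 2L; pv <- (d2 - 1L) %/% 2L
  if (pu < 1L || pv < 1L) stop("input_shape ", d1, "x", d2, " is too small")
  D <- n_kernels * pu * pv
  C <- length(classes)
  with_seed(seed, {
    model <- structure(list(
      conv_w = array(stats::runif(4 * n_kernels, -0.5, 0.5), c(2, 2, n_kernels)),
      conv_b = numeric(n_kernels),
      fc1_w = matrix(stats::runif(fc1_units * D, -1, 1) / sqrt(D), fc1_units, D),
      fc1_b = numeric(fc1_units),
      fc2_w = matrix(stats::runif(C * fc1_units, -1, 1) / sqrt(fc1_units),
                     C, fc1_units),
      fc2_b = numeric(C),
      input_shape = c(d1, d2), pooled_shape = c(pu, pv),
      n_kernels = as.integer(n_kernels), fc1_units = as.integer(fc1_units),
      n_classes = C, classes = as.character(classes),
      pipeline = pipeline, seed = as.integer(seed)),
      class = "ssvep_cnn")
    model
  })
}

#' @export
print.ssvep_cnn <- function(x, ...) {
  cat(sprintf(paste0("<ssvep_cnn> input %dx%d -> conv 2x2 (%d kernels) -> ",
                     "ReLU -> pool 2x2 -> fc %d -> %d classes\n"),
              x$input_shape[1], x$input_shape[2], x$n_kernels,
              x$fc1_units, x$n_classes))
  invisible(x)
}

# Coerce feature input (feature_map, matrix, or bins x frames x B array) to a
# 3-D batch array, checking the shape against the model.
as_feature_batch <- function(model, maps) {
  if (inherits(maps, "feature_map")) maps <- maps$power
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  d <- dim(maps)
  if (length(d) != 3L || d[1] != model$input_shape[1] || d[2] != model$input_shape[2])
    stop("feature shape mismatch: expected ",
         model$input_shape[1], "x", model$input_shape[2], ", got ",
         paste(d[seq_len(min(2, length(d)))], collapse = "x"))
  maps
}

# Full forward pass; returns scores plus the caches the backward pass needs.
forward_pass <- function(model, X) {
  cp <- conv_pool_fwd(X, model$conv_w, model$conv_b)
  B <- dim(X)[3]
  FF <- matrix(cp$P, ncol = B)                       # D x B flattened features
  H1 <- model$fc1_w %*% FF + model$fc1_b
  H1[H1 < 0] <- 0
  S <- model$fc2_w %*% H1 + model$fc2_b
  list(scores = S, FF = FF, H1 = H1, P = cp$P, argmax = cp$argmax, X = X)
}

#' CNN forward pass
#'
#' Computes raw class scores for one feature map or a batch.  The predicted
#' label is the arg-max score; ties break toward the lowest class index.
#'
#' @param model an `ssvep_cnn`.
#' @param maps a `feature_map`, a bins x frames matrix, or a
#'   bins x frames x trials array (normalized features).
#' @return A numeric matrix of scores, classes x batch.
#' @export
cnn_forward <- function(model, maps) {
  stopifnot(inherits(model, "ssvep_cnn"))
  X <- as_feature_batch(model, maps)
  forward_pass(model, X)$scores
}

# Mean-squared-error loss and its gradient at the scores:
# J = (1/B) * sum_i 0.5 * ||y_i - s_i||^2.
mse_loss <- function(S, Y) {
  B <- ncol(S)
  list(loss = sum((Y - S)^2) / (2 * B), dS = (S - Y) / B)
}

# One gradient evaluation on a batch; returns loss and parameter gradients.
backward_pass <- function(model, fwd, Y) {
  ls <- mse_loss(fwd$scores, Y)
  dS <- ls$dS
  dfc2_w <- dS %*% t(fwd$H1)
  dfc2_b <- rowSums(dS)
  dH1 <- t(model$fc2_w) %*% dS
  dH1[fwd$H1 <= 0] <- 0
  dfc1_w <- dH1 %*% t(fwd$FF)
  dfc1_b <- rowSums(dH1)
  dFF <- t(model$fc1_w) %*% dH1
  dP <- array(dFF, dim(fwd$P))
  cb <- conv_pool_bwd(fwd$X, dP, fwd$P, fwd$argmax)
  list(loss = ls$loss,
       grads = list(conv_w = cb$dW, conv_b = cb$db,
                    fc1_w = dfc1_w, fc1_b = dfc1_b,
                    fc2_w = dfc2_w, fc2_b = dfc2_b))
}

# Stratified index split: per class, the first `fraction` of a seeded
# permutation goes to training.
stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- floor(fraction * length(idx))
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(classes), length(labels))
  Y[cbind(match(as.character(labels), classes), seq_along(labels))] <- 1
  Y
}

#' Train the CNN by mini-batch gradient descent
#'
#' Minimizes the mean-squared error against one-hot targets,
#' `J = (1/m) sum_i 0.5 * ||y_i - h(x_i)||^2`, with plain (vanilla) gradient
#' descent at a fixed learning rate — no momentum and no adaptive steps.
#' Trials are split into stratified train/test sets with `config$seed`, which
#' also seeds the weight initialization and the per-epoch batch shuffling, so
#' a fixed seed reproduces the fit exactly.
#'
#' @param features a `feature_set` from [featurize_trials()], or a
#'   bins x frames x trials array.
#' @param labels factor of class labels (taken from `features` when it is a
#'   `feature_set`).
#' @param config a [train_config()].
#' @param n_kernels,fc1_units architecture sizes passed to [cnn_init()].
#' @return A list of class `cnn_fit`: `model`, `loss_history` (mean epoch
#'   loss), `train_idx`, `test_idx`, `config`.
#' @export
cnn_train <- function(features, labels = NULL, config = train_config(),
                      n_kernels = 8L, fc1_units = 64L) {
  if (inherits(features, "feature_set")) {
    if (is.null(labels)) labels <- features$labels
    pipeline <- list(low = 5, high = 30, filter_order = 4, step = 1,
                     kaiser_beta = 0.5)
    X <- features$features
  } else {
    X <- features
    pipeline <- list(low = 5, high = 30, filter_order = 4, step = 1,
                     kaiser_beta = 0.5)
  }
  stopifnot(length(dim(X)) == 3L, !is.null(labels))
  labels <- as.factor(labels)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("training needs at least 2 classes present")
  classes <- levels(labels)
  split <- stratified_split(labels, config$train_fraction, config$seed)
  model <- cnn_init(dim(X)[1:2], classes = classes, n_kernels = n_kernels,
                    fc1_units = fc1_units, seed = derive_seed(config$seed, 1),
                    pipeline = pipeline)
  Xtr <- X[, , split$train, drop = FALSE]
  Ytr <- one_hot(labels[split$train], classes)
  n_tr <- length(split$train)
  alpha <- config$learning_rate
  loss_history <- numeric(config$epochs)
  with_seed(derive_seed(config$seed, 2), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample(n_tr)
      batch_losses <- c()
      for (b0 in seq(1, n_tr, by = config$batch_size)) {
        idx <- perm[b0:min(b0 + config$batch_size - 1L, n_tr)]
        fwd <- forward_pass(model, Xtr[, , idx, drop = FALSE])
        bwd <- backward_pass(model, fwd, Ytr[, idx, drop = FALSE])
        if (!is.finite(bwd$loss))
          stop("non-finite training loss at epoch ", ep,
               " (learning rate too high or degenerate input)")
        for (nm in names(bwd$grads))
          model[[nm]] <- model[[nm]] - alpha * bwd$grads[[nm]]
        batch_losses <- c(batch_losses, bwd$loss)
      }
      loss_history[ep] <- mean(batch_losses)
    }
  })
  structure(list(model = model, loss_history = loss_history,
                 train_idx = split$train, test_idx = split$test,
                 config = config),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit> %d train / %d test trials, %d epochs, final loss %.4g\n",
              length(x$train_idx), length(x$test_idx),
              length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

#' Evaluate a trained CNN
#'
#' Computes the error rate (wrongly classified / total), the accuracy
#' `(1 - error_rate) * 100` %, the confusion matrix (true classes in rows)
#' and per-class accuracies on a labeled test set.
#'
#' @param model an `ssvep_cnn`.
#' @param features feature array (bins x frames x trials), or a `feature_set`.
#' @param labels factor of true labels; must lie within the model's classes.
#' @param batch_size forward-pass batch size (memory knob only).
#' @return A list of class `eval_report`: `error_rate`, `accuracy`,
#'   `confusion`, `per_class`, `n`.
#' @export
cnn_evaluate <- function(model, features, labels = NULL, batch_size = 128L) {
  if (inherits(features, "feature_set")) {
    if (is.null(labels)) labels <- features$labels
    features <- features$features
  }
  if (is.null(labels) || length(labels) == 0L)
    stop("test set is empty")
  labels <- as.character(labels)
  if (!all(labels %in% model$classes))
    stop("test labels outside the model's classes: ",
         paste(setdiff(labels, model$classes), collapse = ", "))
  X <- as_feature_batch(model, features)
  n <- dim(X)[3]
  if (n != length(labels)) stop("feature/label length mismatch")
  pred <- character(n)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    S <- forward_pass(model, X[, , idx, drop = FALSE])$scores
    pred[idx] <- model$classes[apply(S, 2L, which.max)]
  }
  confusion <- table(factor(labels, levels = model$classes),
                     factor(pred, levels = model$classes),
                     dnn = c("true", "predicted"))
  err <- 1 - sum(diag(confusion)) / n
  per_class <- diag(confusion) / pmax(1, rowSums(confusion))
  structure(list(error_rate = err, accuracy = (1 - err) * 100,
                 confusion = confusion, per_class = per_class, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% (error rate %.4f, n = %d)\n",
              x$accuracy, x$error_rate, x$n))
  invisible(x)
}

#' Decode one epoch end to end
#'
#' Runs the full per-epoch pipeline the model was trained with —
#' [analysis_bandpass()], [stft_feature()], [normalize_map()],
#' [cnn_forward()] — and returns the arg-max class label.  This composition
#' is the decoder handed to [run_closed_loop()].
#'
#' @param model a trained `ssvep_cnn`.
#' @param epoch an [eeg_epoch()].
#' @param return_scores also return the raw score vector.
#' @return The predicted label (character), or a list with `label` and
#'   `scores` when `return_scores = TRUE`.
#' @export
predict_epoch <- function(model, epoch, return_scores = FALSE) {
  stopifnot(inherits(model, "ssvep_cnn"), inherits(epoch, "eeg_epoch"))
  pl <- model$pipeline
  ep <- analysis_bandpass(epoch, pl$low, pl$high, pl$filter_order)
  fm <- normalize_map(stft_feature(ep, step = pl$step,
                                   kaiser_beta = pl$kaiser_beta,
                                   band = c(pl$low, pl$high)))
  s <- cnn_forward(model, fm)
  label <- model$classes[which.max(s[, 1])]
  if (return_scores) list(label = label, scores = s[, 1]) else label
}

#' Analytic gradients for a labeled batch (for verification)
#'
#' Exposes one gradient evaluation of the training loss so the analytic
#' gradients can be compared against finite differences.
#'
#' @param model an `ssvep_cnn`.
#' @param X bins x frames x batch feature array.
#' @param Y one-hot target matrix, classes x batch.
#' @return List with `loss` and `grads` (same shapes as the parameters).
#' @export
cnn_gradients <- function(model, X, Y) {
  X <- as_feature_batch(model, X)
  backward_pass(model, forward_pass(model, X), Y)
}

#' Training loss for a labeled batch
#'
#' @inheritParams cnn_gradients
#' @return The scalar mean-squared-error loss.
#' @export
cnn_loss <- function(model, X, Y) {
  X <- as_feature_batch(model, X)
  mse_loss(forward_pass(model, X)$scores, Y)$loss
}
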