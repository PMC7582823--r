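# A tiny model with hand-set parameters for layer-level checks.
tiny_model <- function(input_shape, n_kernels = 1L, fc1_units = 2L,
                       classes = c("a", "b")) {
  cnn_init(input_shape, classes = classes, n_kernels = n_kernels,
           fc1_units = fc1_units, seed = 1)
}

test_that("fused conv/pool layer matches hand and loop references", {
  # hand example: valid 2x2 conv of a 3x3 ramp with an identity-diagonal kernel
  X <- matrix(c(1, 4, 7, 2, 5, 8, 3, 6, 9), 3, 3)  # rows 1:3 = [[1,2,3],...]
  W <- matrix(c(1, 0, 0, 1), 2, 2)                 # picks X[u,v] + X[u+1,v+1]
  Z <- conv2_valid_ref(X, W)
  expect_equal(Z, matrix(c(6, 12, 8, 14), 2, 2))
  expect_equal(maxpool_ref(pmax(Z, 0)), matrix(14))

  cp <- hybridbci:::conv_pool_fwd(array(X, c(3, 3, 1)),
                                  array(W, c(2, 2, 1)), 0)
  expect_equal(as.numeric(cp$P), 14)

  # property: random sizes against the loop reference (conv -> relu -> pool)
  set.seed(42)
  for (i in 1:5) {
    d1 <- sample(4:9, 1); d2 <- sample(4:12, 1); K <- sample(1:3, 1)
    X <- array(rnorm(d1 * d2 * 2), c(d1, d2, 2))
    W <- array(rnorm(4 * K), c(2, 2, K))
    b <- rnorm(K)
    cp <- hybridbci:::conv_pool_fwd(X, W, b)
    for (n in 1:2) for (k in seq_len(K)) {
      want <- maxpool_ref(pmax(conv2_valid_ref(X[, , n], W[, , k], b[k]), 0))
      got <- matrix(cp$P[k, , , n], nrow = dim(cp$P)[2])
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("case %d kernel %d sample %d", i, k, n))
    }
  }
})

test_that("forward pass honours contracts on zero input and bad shapes", {
  m <- tiny_model(c(6L, 8L))
  zero <- matrix(0, 6, 8)
  s <- cnn_forward(m, zero)
  # zero input, zero bias: dense ReLU keeps everything at zero
  expect_true(all(s == 0))
  expect_equal(which.max(s[, 1]), 1L)   # tie-break to the lowest class

  expect_error(cnn_forward(m, matrix(0, 7, 8)), "expected 6x8, got 7x8")
})

test_that("analytic gradients match central finite differences", {
  set.seed(5)
  model <- cnn_init(c(6L, 9L), classes = c("a", "b", "c"), n_kernels = 2L,
                    fc1_units = 5L, seed = 3)
  X <- array(runif(6 * 9 * 4), c(6, 9, 4))
  Y <- one_hot_ref <- matrix(0, 3, 4); Y[cbind(c(1, 2, 3, 1), 1:4)] <- 1
  got <- cnn_gradients(model, X, Y)
  expect_true(is.finite(got$loss))
  for (nm in names(got$grads)) {
    num <- numeric_grad(model, nm, function(m) cnn_loss(m, X, Y))
    denom <- pmax(abs(num), 1e-4)      # guard tiny-magnitude entries
    expect_lt(max(abs(got$grads[[nm]] - num) / denom), 1e-5)
  }
})

test_that("training separates two linearly separable toy classes", {
  # class a: bright top-left quadrant; class b: bright bottom-right
  set.seed(9)
  n_per <- 20L
  X <- array(0, c(4, 4, 2 * n_per))
  labels <- rep(c("a", "b"), each = n_per)
  for (i in seq_len(n_per)) {
    X[1:2, 1:2, i] <- 0.8 + 0.2 * runif(4)
    X[3:4, 3:4, n_per + i] <- 0.8 + 0.2 * runif(4)
  }
  fit <- cnn_train(X, factor(labels),
                   config = train_config(epochs = 200, batch_size = 8,
                                         train_fraction = 0.5, seed = 2),
                   n_kernels = 2L, fc1_units = 8L)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  train_rep <- cnn_evaluate(fit$model, X[, , fit$train_idx, drop = FALSE],
                            labels[fit$train_idx])
  expect_equal(train_rep$accuracy, 100)
})

test_that("training is deterministic under a fixed seed and rejects one class", {
  set.seed(10)
  X <- array(runif(5 * 7 * 12), c(5, 7, 12))
  y <- factor(rep(c("a", "b"), 6))
  cfgt <- train_config(epochs = 3, batch_size = 4, train_fraction = 0.5,
                       seed = 33)
  f1 <- cnn_train(X, y, config = cfgt, n_kernels = 2L, fc1_units = 4L)
  f2 <- cnn_train(X, y, config = cfgt, n_kernels = 2L, fc1_units = 4L)
  expect_identical(f1$model$conv_w, f2$model$conv_w)
  expect_identical(f1$model$fc1_w, f2$model$fc1_w)
  expect_identical(f1$train_idx, f2$train_idx)
  expect_identical(f1$loss_history, f2$loss_history)

  expect_error(cnn_train(X, factor(rep("a", 12)), config = cfgt),
               "at least 2 classes")
})

test_that("the stratified 80/20 split reproduces the canonical 640/160 counts", {
  labels <- factor(rep(class_labels(), each = 100))
  split <- hybridbci:::stratified_split(labels, 0.8, seed = 1)
  expect_length(split$train, 640L)
  expect_length(split$test, 160L)
  expect_true(all(table(labels[split$train]) == 80L))
  expect_true(all(table(labels[split$test]) == 20L))
})

test_that("evaluation report satisfies its accounting identities", {
  m <- tiny_model(c(4L, 4L), n_kernels = 2L, fc1_units = 4L,
                  classes = c("a", "b"))
  set.seed(11)
  X <- array(runif(4 * 4 * 30), c(4, 4, 30))
  y <- factor(rep(c("a", "b"), 15))
  rep <- cnn_evaluate(m, X, y)
  expect_equal(rep$accuracy + 100 * rep$error_rate, 100)
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion), 1 - rep$error_rate)
  expect_equal(rowSums(rep$confusion), c(a = 15, b = 15))

  # 4 wrong out of 160 must give 97.5% by definition
  expect_equal((1 - 4 / 160) * 100, 97.5)
  expect_error(cnn_evaluate(m, X, NULL), "empty")
  expect_error(cnn_evaluate(m, X, factor(rep("zz", 30))), "outside")
})

test_that("an untrained model still returns a valid label end to end", {
  m <- cnn_init(c(25L, 500L), seed = 4)
  ep <- make_ssvep_epoch(10, signal_model_config(), seed = 2)
  expect_true(predict_epoch(m, ep) %in% class_labels())
})
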