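test_that("forward pass honors the shape contract", {
  h <- model_hyperparameters(n_filters = 8, kernel_size = 3, dense_units = 16)
  m <- build_cnn(h, seed = 1)
  out <- predict_co(m, rep(0, 150))
  expect_length(out, 1)
  expect_true(is.finite(out))
  X <- matrix(rnorm(5 * 150), 5, 150)
  expect_length(predict_co(m, X), 5)
  expect_error(predict_co(m, matrix(0, 2, 149)), "input length")
  expect_error(build_cnn(model_hyperparameters(kernel_size = 151)),
               "architecture error")
})

test_that("trainable parameter count matches the closed-form sum", {
  for (cfg in list(c(8L, 3L, 16L), c(16L, 9L, 64L), c(32L, 5L, 128L))) {
    nf <- cfg[1]; K <- cfg[2]; D <- cfg[3]
    h <- model_hyperparameters(n_filters = nf, kernel_size = K,
                               dense_units = D)
    m <- build_cnn(h, seed = 2)
    L1 <- 150 - K + 1; L2 <- L1 - K + 1; L3 <- L2 %/% 2
    expected <- (K * nf + nf) + 2 * nf +          # conv1 + BN1
      (K * nf * nf + nf) + 2 * nf +               # conv2 + BN2
      (L3 * nf * D + D) +                         # hidden dense
      (D + 1)                                     # linear output
    expect_equal(n_parameters(m), expected)
  }
})

test_that("backpropagation matches numerical gradients", {
  h <- model_hyperparameters(n_filters = 3, kernel_size = 5, dense_units = 6,
                             dropout_rate = 0)
  m <- build_cnn(h, input_length = 24, seed = 3)
  set.seed(31)
  X <- matrix(rnorm(5 * 24), 5, 24)
  y <- rnorm(5)
  fw <- pulseco:::cnn_forward(m, X, training = TRUE)
  gr <- pulseco:::cnn_backward(m, X, y, fw)
  loss_at <- function(mod) {
    f <- pulseco:::cnn_forward(mod, X, training = TRUE)
    mean((f$out - y)^2)
  }
  eps <- 1e-6
  for (nm in c("W1", "W2", "Wd", "Wo", "g1", "g2", "be1", "be2", "bd", "bo")) {
    idx <- seq_along(m$par[[nm]])
    if (length(idx) > 8) idx <- sort(sample(idx, 8))
    for (i in idx) {
      mp <- m; mp$par[[nm]][i] <- mp$par[[nm]][i] + eps
      mm <- m; mm$par[[nm]][i] <- mm$par[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]),
                1e-4 * max(1, abs(num)))
    }
  }
})

test_that("training on a constant target converges to that constant", {
  set.seed(5)
  X <- matrix(rnorm(60 * 150), 60, 150)
  y <- rep(6.2, 60)
  h <- model_hyperparameters(n_filters = 4, kernel_size = 5, dense_units = 8,
                             dropout_rate = 0, max_epochs = 30,
                             early_stopping_patience = 5)
  m <- build_cnn(h, seed = 6)
  m <- train_model(m, X[1:40, ], y[1:40], X[41:60, ], y[41:60], seed = 7)
  expect_lt(max(abs(predict_co(m, X[1:40, ]) - 6.2)), 0.1)
  expect_lt(sqrt(mean((predict_co(m, X) - 6.2)^2)), 0.1)
})

test_that("training and prediction are deterministic given seeds", {
  set.seed(15)
  X <- matrix(rnorm(50 * 150), 50, 150)
  y <- rowMeans(X[, 1:30]) + 6
  h <- model_hyperparameters(n_filters = 4, kernel_size = 5, dense_units = 8,
                             max_epochs = 5, early_stopping_patience = 5)
  m1 <- train_model(build_cnn(h, seed = 8), X[1:35, ], y[1:35],
                    X[36:50, ], y[36:50], seed = 9)
  m2 <- train_model(build_cnn(h, seed = 8), X[1:35, ], y[1:35],
                    X[36:50, ], y[36:50], seed = 9)
  expect_identical(m1$par, m2$par)
  p1 <- predict_co(m1, X)
  expect_identical(p1, predict_co(m1, X))
  expect_identical(p1, predict_co(m2, X))
})

test_that("models round-trip through save_model/load_model", {
  h <- model_hyperparameters(n_filters = 4, kernel_size = 5, dense_units = 8)
  m <- build_cnn(h, seed = 12)
  f <- tempfile(fileext = ".rds")
  paths <- save_model(m, f)
  expect_true(all(file.exists(paths)))
  m2 <- load_model(f)
  X <- matrix(rnorm(3 * 150), 3, 150)
  expect_identical(predict_co(m, X), predict_co(m2, X))
  sidecar <- jsonlite::read_json(paths[["sidecar"]])
  expect_equal(sidecar$n_parameters, n_parameters(m))
  expect_equal(sidecar$hyperparameters$kernel_size, 5)
  unlink(paths)
})

test_that("the network learns a simple waveform-amplitude relation", {
  # sanity: targets proportional to a local waveform feature are learnable
  set.seed(25)
  n <- 120
  X <- t(replicate(n, {
    a <- runif(1, 0.5, 2)
    a * sin(seq(0, 2 * pi, length.out = 150)) + rnorm(150, 0, 0.02)
  }))
  y <- 4 + 2 * apply(X, 1, max)
  h <- model_hyperparameters(n_filters = 8, kernel_size = 7, dense_units = 16,
                             dropout_rate = 0, max_epochs = 60,
                             early_stopping_patience = 10)
  m <- train_model(build_cnn(h, seed = 10), X[1:80, ], y[1:80],
                   X[81:100, ], y[81:100], seed = 11)
  r <- cor(predict_co(m, X[101:120, ]), y[101:120])
  expect_gt(r, 0.9)
})
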