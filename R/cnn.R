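#' CNN hyperparameter set
#'
#' The tunable hyperparameters of the waveform-to-CO regressor. Defaults
#' are sensible mid-range values; [tune_hyperparameters()] searches the
#' space around them.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param n_filters filters per convolutional layer (both layers share it).
#' @param kernel_size convolution kernel length (points).
#' @param dropout_rate dropout probability after max pooling, in `[0, 1)`.
#' @param dense_units units of the hidden fully connected layer.
#' @param max_epochs training epoch cap.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping (best-epoch weights are restored).
#' @return list of class `model_hyperparameters`.
#' @export
model_hyperparameters <- function(learning_rate = 1e-3, batch_size = 32L,
                                  n_filters = 16L, kernel_size = 9L,
                                  dropout_rate = 0.15, dense_units = 64L,
                                  max_epochs = 200L,
                                  early_stopping_patience = 15L) {
  h <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
            n_filters = as.integer(n_filters),
            kernel_size = as.integer(kernel_size),
            dropout_rate = dropout_rate, dense_units = as.integer(dense_units),
            max_epochs = as.integer(max_epochs),
            early_stopping_patience = as.integer(early_stopping_patience))
  if (any(unlist(h[c("learning_rate", "batch_size", "n_filters",
                     "kernel_size", "dense_units", "max_epochs",
                     "early_stopping_patience")]) <= 0))
    stop("hyperparameters must be positive")
  if (h$dropout_rate < 0 || h$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(h, class = "model_hyperparameters")
}

# --- layer geometry -------------------------------------------------------

cnn_dims <- function(h, input_length = 150L) {
  L1 <- input_length - h$kernel_size + 1L
  L2 <- L1 - h$kernel_size + 1L
  if (L2 < 2L) stop("architecture error: kernel too large for input length")
  L3 <- L2 %/% 2L
  list(input_length = input_length, L1 = L1, L2 = L2, L3 = L3,
       flat = L3 * h$n_filters)
}

#' Build the 1D CNN regressor
#'
#' Constructs (untrained) the fixed layer stack
#' conv(n_filters, kernel) - batch norm - ReLU - conv(n_filters, kernel) -
#' batch norm - ReLU - max pool(2) - dropout - flatten -
#' dense(dense_units, ReLU) - dense(1, linear), mapping a 150-point
#' waveform vector to one cardiac output value (L/min). Convolutions are
#' unpadded; weights are He-initialized. The network is implemented
#' directly on BLAS matrix operations (forward and backward passes), with
#' Adam as the optimizer.
#'
#' @param h a [model_hyperparameters()].
#' @param input_length input vector length (150).
#' @param seed seed for weight initialization.
#' @return object of class `co_cnn` (untrained).
#' @export
build_cnn <- function(h, input_length = 150L, seed = 1L) {
  stopifnot(inherits(h, "model_hyperparameters"))
  d <- cnn_dims(h, as.integer(input_length))
  K <- h$kernel_size; F <- h$n_filters; D <- h$dense_units
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  par <- with_seed(seed, list(
    W1 = he(K, F, K), b1 = numeric(F),
    g1 = rep(1, F), be1 = numeric(F),
    W2 = he(K * F, F, K * F), b2 = numeric(F),
    g2 = rep(1, F), be2 = numeric(F),
    Wd = he(d$flat, D, d$flat), bd = numeric(D),
    Wo = he(D, 1, D), bo = 0
  ))
  structure(list(h = h, dims = d, par = par,
                 bn_stats = list(rm1 = numeric(F), rv1 = rep(1, F),
                                 rm2 = numeric(F), rv2 = rep(1, F)),
                 trained = FALSE, history = NULL, condition = NULL),
            class = "co_cnn")
}

#' Trainable parameter count
#'
#' @param model a `co_cnn`.
#' @return integer: total number of trainable parameters (batch-norm
#'   running statistics excluded).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$par, length, integer(1)))
}

# im2col for rows ordered as (position-1)*B + batch
im2col <- function(A, B, Lin, K) {
  Lout <- Lin - K + 1L
  Cin <- ncol(A)
  out <- matrix(0, B * Lout, K * Cin)
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * B + 1L):((k + Lout - 1L) * B)
    out[, ((k - 1L) * Cin + 1L):(k * Cin)] <- A[rows, , drop = FALSE]
  }
  out
}

col2im_add <- function(dXc, B, Lin, K, Cin) {
  Lout <- Lin - K + 1L
  dA <- matrix(0, B * Lin, Cin)
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * B + 1L):((k + Lout - 1L) * B)
    dA[rows, ] <- dA[rows, ] + dXc[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
  }
  dA
}

bn_forward <- function(Z, gamma, beta, training, rm, rv, eps = 1e-5) {
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    ivar <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(Z, 2, mu), 2, ivar, `*`)
    list(out = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
         xhat = xhat, ivar = ivar, mu = mu, v = v)
  } else {
    ivar <- 1 / sqrt(rv + eps)
    xhat <- sweep(sweep(Z, 2, rm), 2, ivar, `*`)
    list(out = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`))
  }
}

bn_backward <- function(dY, cache, gamma) {
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dXhat <- sweep(dY, 2, gamma, `*`)
  s1 <- colSums(dXhat)
  s2 <- colSums(dXhat * cache$xhat)
  dZ <- sweep(dXhat, 2, s1 / N) - sweep(cache$xhat, 2, s2 / N, `*`)
  dZ <- sweep(dZ, 2, cache$ivar, `*`)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

cnn_forward <- function(model, X, training = FALSE) {
  p <- model$par; d <- model$dims; h <- model$h
  B <- nrow(X); K <- h$kernel_size
  cache <- list(B = B)
  A0 <- matrix(as.vector(X), ncol = 1)                    # (B*Lin) x 1
  cache$Xc1 <- im2col(A0, B, d$input_length, K)
  Z1 <- sweep(cache$Xc1 %*% p$W1, 2, p$b1, `+`)
  cache$bn1 <- bn_forward(Z1, p$g1, p$be1, training,
                          model$bn_stats$rm1, model$bn_stats$rv1)
  A1 <- cache$bn1$out
  cache$relu1 <- A1 > 0
  A1 <- A1 * cache$relu1
  cache$A1 <- A1
  cache$Xc2 <- im2col(A1, B, d$L1, K)
  Z2 <- sweep(cache$Xc2 %*% p$W2, 2, p$b2, `+`)
  cache$bn2 <- bn_forward(Z2, p$g2, p$be2, training,
                          model$bn_stats$rm2, model$bn_stats$rv2)
  A2 <- cache$bn2$out
  cache$relu2 <- A2 > 0
  A2 <- A2 * cache$relu2
  idx_odd <- as.vector(outer(seq_len(B), (2 * seq_len(d$L3) - 2) * B, `+`))
  cache$idx_odd <- idx_odd
  Aodd <- A2[idx_odd, , drop = FALSE]
  Aeven <- A2[idx_odd + B, , drop = FALSE]
  cache$pool_mask <- Aodd >= Aeven
  P <- pmax(Aodd, Aeven)
  if (training && h$dropout_rate > 0) {
    cache$drop <- matrix(stats::rbinom(length(P), 1, 1 - h$dropout_rate),
                         nrow(P), ncol(P)) / (1 - h$dropout_rate)
    P <- P * cache$drop
  }
  Fl <- matrix(as.vector(P), B, d$flat)
  cache$Fl <- Fl
  Zd <- sweep(Fl %*% p$Wd, 2, p$bd, `+`)
  cache$relud <- Zd > 0
  Hd <- Zd * cache$relud
  cache$Hd <- Hd
  out <- as.vector(Hd %*% p$Wo) + p$bo
  list(out = out, cache = cache)
}

cnn_backward <- function(model, X, y, fw) {
  p <- model$par; d <- model$dims; h <- model$h
  cache <- fw$cache; B <- cache$B
  K <- h$kernel_size; nf <- h$n_filters
  dout <- matrix(2 * (fw$out - y) / B, ncol = 1)
  g <- list()
  g$Wo <- t(cache$Hd) %*% dout
  g$bo <- sum(dout)
  dHd <- (dout %*% t(p$Wo)) * cache$relud
  g$Wd <- t(cache$Fl) %*% dHd
  g$bd <- colSums(dHd)
  dFl <- dHd %*% t(p$Wd)
  dP <- matrix(as.vector(dFl), B * d$L3, nf)
  if (!is.null(cache$drop)) dP <- dP * cache$drop
  dA2 <- matrix(0, B * d$L2, nf)
  dA2[cache$idx_odd, ] <- dP * cache$pool_mask
  dA2[cache$idx_odd + B, ] <- dA2[cache$idx_odd + B, ] + dP * (!cache$pool_mask)
  dA2 <- dA2 * cache$relu2
  bb2 <- bn_backward(dA2, cache$bn2, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  g$W2 <- t(cache$Xc2) %*% bb2$dZ
  g$b2 <- colSums(bb2$dZ)
  dA1 <- col2im_add(bb2$dZ %*% t(p$W2), B, d$L1, K, nf)
  dA1 <- dA1 * cache$relu1
  bb1 <- bn_backward(dA1, cache$bn1, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  g$W1 <- t(cache$Xc1) %*% bb1$dZ
  g$b1 <- colSums(bb1$dZ)
  g
}

adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0),
       v = lapply(par, function(x) x * 0), t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

mse_loss <- function(model, X, y, chunk = 512L) {
  pred <- predict_co(model, X, chunk = chunk)
  mean((pred - y)^2)
}

#' Train the CNN on waveform vectors
#'
#' Minimizes MSE with Adam at the configured learning rate, monitoring the
#' validation loss each epoch; training stops when the validation loss has
#' not improved for `early_stopping_patience` epochs (or at `max_epochs`)
#' and the best-epoch weights are restored. Batch-norm inference statistics
#' are tracked as exponential moving averages. Deterministic given `seed`.
#'
#' @param model an untrained `co_cnn` from [build_cnn()].
#' @param x_train,y_train training waveform matrix (subjects x 150) and CO
#'   targets (L/min).
#' @param x_val,y_val validation data (disjoint from training).
#' @param seed seed for shuffling and dropout.
#' @param bn_momentum running-statistics momentum.
#' @param verbose print per-epoch losses.
#' @return the trained `co_cnn`, with `history` (data.frame: epoch,
#'   train_loss, val_loss) and `best_epoch` fields.
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val, seed = 1L,
                        bn_momentum = 0.9, verbose = FALSE) {
  stopifnot(inherits(model, "co_cnn"))
  if (ncol(x_train) != model$dims$input_length)
    stop("architecture error: input length must be ", model$dims$input_length)
  h <- model$h
  n <- nrow(x_train)
  model$par$bo <- mean(y_train)            # start at the target mean
  opt <- adam_init(model$par)
  best <- list(val = Inf, par = model$par, bn = model$bn_stats, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  wait <- 0L
  with_seed(seed, {
    for (epoch in seq_len(h$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = h$batch_size)
      tr_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + h$batch_size - 1, n)]
        if (length(idx) < 2) next
        Xb <- x_train[idx, , drop = FALSE]
        fw <- cnn_forward(model, Xb, training = TRUE)
        tr_loss <- tr_loss + sum((fw$out - y_train[idx])^2)
        # update BN running stats
        mom <- bn_momentum
        bs <- model$bn_stats
        bs$rm1 <- mom * bs$rm1 + (1 - mom) * fw$cache$bn1$mu
        bs$rv1 <- mom * bs$rv1 + (1 - mom) * fw$cache$bn1$v
        bs$rm2 <- mom * bs$rm2 + (1 - mom) * fw$cache$bn2$mu
        bs$rv2 <- mom * bs$rv2 + (1 - mom) * fw$cache$bn2$v
        model$bn_stats <- bs
        grads <- cnn_backward(model, Xb, y_train[idx], fw)
        if (any(!is.finite(unlist(grads))) || !is.finite(tr_loss)) {
          model$history <- hist
          cond <- structure(class = c("pulseco_training_error", "error",
                                      "condition"),
                            list(message = "training error: divergent loss",
                                 call = sys.call(-1), history = hist))
          stop(cond)
        }
        up <- adam_step(model$par, grads, opt, h$learning_rate)
        model$par <- up$par
        opt <- up$state
      }
      val_loss <- mse_loss(model, x_val, y_val)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss / n,
                                     val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d train %.4f val %.4f", epoch,
                        tr_loss / n, val_loss))
      if (val_loss < best$val - 1e-12) {
        best <- list(val = val_loss, par = model$par, bn = model$bn_stats,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= h$early_stopping_patience) break
      }
    }
  })
  model$par <- best$par
  model$bn_stats <- best$bn
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Predict cardiac output from waveform vectors
#'
#' Deterministic inference pass (no dropout; batch-norm uses running
#' statistics).
#'
#' @param model a trained `co_cnn`.
#' @param x waveform matrix (subjects x 150) or a single length-150 vector.
#' @param chunk forward-pass chunk size.
#' @return numeric vector of CO estimates (L/min).
#' @export
predict_co <- function(model, x, chunk = 512L) {
  stopifnot(inherits(model, "co_cnn"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dims$input_length)
    stop("architecture error: input length must be ", model$dims$input_length)
  out <- numeric(nrow(x))
  for (s in seq(1, nrow(x), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(x))
    out[idx] <- cnn_forward(model, x[idx, , drop = FALSE],
                            training = FALSE)$out
  }
  out
}

#' Save / load a trained model
#'
#' `save_model()` writes the model in R's native serialized format (.rds)
#' plus a human-readable JSON sidecar describing the architecture,
#' hyperparameters and training history; `load_model()` restores it.
#'
#' @param model a `co_cnn`.
#' @param path output path for the .rds file; the sidecar is written next
#'   to it as `<path>.json`.
#' @return `save_model()`: invisibly, the paths written; `load_model()`:
#'   the restored `co_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "co_cnn"))
  saveRDS(model, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    class = "co_cnn",
    hyperparameters = unclass(model$h),
    dims = model$dims,
    n_parameters = n_parameters(model),
    trained = model$trained,
    best_epoch = model$best_epoch,
    history = model$history
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(model = path, sidecar = sidecar))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "co_cnn"))
  model
}
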