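#' Default hyperparameter search space
#'
#' The search space explored by [tune_hyperparameters()]: learning rate
#' log-uniform on `[1e-4, 1e-2]`, batch size in {16, 32, 64}, filters in
#' {8, 16, 32, 64}, kernel size in {3, 5, 7, 9}, dropout uniform on
#' `[0.1, 0.5]`, dense units in {16, 32, 64, 128}.
#'
#' @return named list; continuous dimensions are `list(type, range)`,
#'   discrete ones `list(type, levels)`.
#' @export
default_search_space <- function() {
  list(
    learning_rate = list(type = "log", range = c(1e-4, 1e-2)),
    batch_size = list(type = "choice", levels = c(16, 32, 64)),
    n_filters = list(type = "choice", levels = c(8, 16, 32, 64)),
    kernel_size = list(type = "choice", levels = c(3, 5, 7, 9)),
    dropout_rate = list(type = "uniform", range = c(0.1, 0.5)),
    dense_units = list(type = "choice", levels = c(16, 32, 64, 128))
  )
}

space_decode <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    nm <- names(space)[i]
    dim <- space[[nm]]
    out[[nm]] <- switch(dim$type,
      log = exp(log(dim$range[1]) + u[i] * (log(dim$range[2]) - log(dim$range[1]))),
      uniform = dim$range[1] + u[i] * (dim$range[2] - dim$range[1]),
      choice = dim$levels[1 + min(length(dim$levels) - 1,
                                  floor(u[i] * length(dim$levels)))]
    )
  }
  out
}

# Gaussian-process surrogate (squared-exponential kernel, fixed length
# scale on the unit cube) with expected-improvement acquisition.
gp_ei_propose <- function(U, y, n_cand = 500L, lengthscale = 0.35) {
  d <- ncol(U)
  ymu <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ymu) / ysd
  k_fun <- function(A, B) {
    D2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    exp(-0.5 * pmax(D2, 0) / lengthscale^2)
  }
  Kn <- k_fun(U, U) + diag(1e-4, nrow(U))
  alpha <- solve(Kn, ys)
  cand <- matrix(stats::runif(n_cand * d), n_cand, d)
  Ks <- k_fun(cand, U)
  mu <- as.vector(Ks %*% alpha)
  v <- pmax(1 - rowSums((Ks %*% solve(Kn)) * Ks), 1e-10)
  s <- sqrt(v)
  fmin <- min(ys)
  u <- (fmin - mu) / s
  ei <- s * (u * stats::pnorm(u) + stats::dnorm(u))
  cand[which.max(ei), ]
}

#' Cross-validated score of one hyperparameter set
#'
#' Mean validation MSE over stratified k-fold cross validation (every
#' subject validated exactly once); per-fold training uses early stopping.
#'
#' @param h a [model_hyperparameters()].
#' @param x,y waveform matrix and CO targets.
#' @param labels stratification labels.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @return mean validation MSE across folds.
#' @export
cv_score <- function(h, x, y, labels, k = 5L, seed = 1L) {
  fold <- stratified_kfold(labels, k, seed = seed)
  seeds <- child_seeds(seed, k)
  mse <- numeric(k)
  for (j in seq_len(k)) {
    tr <- fold != j
    m <- build_cnn(h, input_length = ncol(x), seed = seeds[j])
    m <- train_model(m, x[tr, , drop = FALSE], y[tr],
                     x[!tr, , drop = FALSE], y[!tr], seed = seeds[j])
    mse[j] <- mean((predict_co(m, x[!tr, , drop = FALSE]) - y[!tr])^2)
  }
  mean(mse)
}

#' Bayesian hyperparameter optimization
#'
#' Sequential model-based search over the hyperparameter space: an initial
#' block of space-filling random trials, then a Gaussian-process surrogate
#' with expected-improvement acquisition proposes each next trial. Every
#' trial is scored by [cv_score()] (stratified 5-fold cross-validated MSE
#' with early stopping). Fully seeded.
#'
#' @param x,y tuning data (train+validation subjects only; the holdout
#'   test set must stay outside).
#' @param labels stratification labels for the CV folds.
#' @param space search space, see [default_search_space()].
#' @param n_trials total number of trials (>= 1).
#' @param seed integer seed.
#' @param k CV folds.
#' @param max_epochs,patience per-fold training budget during tuning.
#' @return the best trial's [model_hyperparameters()], with attributes
#'   `trials` (data.frame of all trials and scores) and `best_score`.
#' @export
tune_hyperparameters <- function(x, y, labels, space = default_search_space(),
                                 n_trials = 20L, seed = 1L, k = 5L,
                                 max_epochs = 60L, patience = 8L) {
  if (n_trials < 1) stop("configuration error: n_trials must be >= 1")
  if (nrow(x) < 50) stop("need >= 50 subjects for tuning")
  if (length(space) == 0) stop("configuration error: empty search space")
  d <- length(space)
  n_init <- min(n_trials, max(4L, d))
  seeds <- child_seeds(seed, n_trials + 1L)
  U <- matrix(NA_real_, n_trials, d)
  scores <- numeric(n_trials)
  hs <- vector("list", n_trials)
  fixed_point <- all(vapply(space, function(dim)
    (dim$type == "choice" && length(dim$levels) == 1) ||
    (dim$type != "choice" && dim$range[1] == dim$range[2]), logical(1)))
  if (fixed_point) n_trials <- 1L
  for (t in seq_len(n_trials)) {
    u <- if (t <= n_init) with_seed(seeds[t], stats::runif(d))
         else with_seed(seeds[t],
                        gp_ei_propose(U[seq_len(t - 1), , drop = FALSE],
                                      scores[seq_len(t - 1)]))
    U[t, ] <- u
    hp <- space_decode(u, space)
    h <- model_hyperparameters(
      learning_rate = hp$learning_rate %||% 1e-3,
      batch_size = hp$batch_size %||% 32L,
      n_filters = hp$n_filters %||% 16L,
      kernel_size = hp$kernel_size %||% 9L,
      dropout_rate = hp$dropout_rate %||% 0.15,
      dense_units = hp$dense_units %||% 64L,
      max_epochs = max_epochs, early_stopping_patience = patience)
    hs[[t]] <- h
    scores[t] <- cv_score(h, x, y, labels, k = k, seed = seeds[n_trials + 1L])
  }
  best <- which.min(scores[seq_len(n_trials)])
  trials <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    data.frame(trial = t, as.data.frame(unclass(hs[[t]])[1:6]),
               cv_mse = scores[t])
  }))
  out <- hs[[best]]
  attr(out, "trials") <- trials
  attr(out, "best_score") <- scores[best]
  out
}
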