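# Log-density of a bivariate (d-variate) Gaussian for rows of X.
mvn_logdens <- function(X, mean, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

gmm_em_once <- function(X, centers, max_iter, tol) {
  n <- nrow(X); d <- ncol(X); k <- nrow(centers)
  w <- rep(1 / k, k)
  mu <- centers
  sig <- replicate(k, stats::cov(X) / k, simplify = FALSE)
  loglik <- -Inf
  ll_trace <- numeric(0)
  resp <- NULL
  for (it in seq_len(max_iter)) {
    # E step
    ld <- vapply(seq_len(k),
                 function(j) log(w[j]) + mvn_logdens(X, mu[j, ], sig[[j]]),
                 numeric(n))
    m <- apply(ld, 1, max)
    lse <- m + log(rowSums(exp(ld - m)))
    resp <- exp(ld - lse)
    new_ll <- sum(lse)
    ll_trace <- c(ll_trace, new_ll)
    if (is.finite(loglik) && new_ll - loglik < tol) { loglik <- new_ll; break }
    loglik <- new_ll
    # M step
    nk <- colSums(resp)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * X) / nk[j]
      Xc <- t(X) - mu[j, ]
      S <- (Xc %*% (resp[, j] * t(Xc))) / nk[j]
      S <- (S + t(S)) / 2
      if (det(S) < 1e-12) {
        S <- S + diag(1e-6 * sum(diag(S)), d)
        if (det(S) < 1e-12) stop("fit error: singular component covariance")
      }
      sig[[j]] <- S
    }
  }
  list(weights = w, means = mu, covariances = sig, responsibilities = resp,
       log_likelihood = loglik, ll_trace = ll_trace, iterations = length(ll_trace))
}

#' Two-component Gaussian mixture on (CO, MAP)
#'
#' Fits a full-covariance two-component Gaussian mixture to cardiac output
#' / mean aortic pressure pairs by expectation-maximization, recovering the
#' normodynamic-hyperdynamic cohort structure. Initialization is
#' k-means-style (seeded restarts of [stats::kmeans()] centers); the best
#' of `n_restarts` EM runs by final log-likelihood is kept. Degenerate
#' covariances are ridge-regularized (`+ 1e-6 * trace` on the diagonal).
#' Components are ordered so that component 2 ("hyperdynamic") has the
#' higher CO mean.
#'
#' @param points matrix or data.frame with two columns (CO in L/min, MAP in
#'   mmHg); >= 4 rows of finite values.
#' @param seed integer seed for the restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol stop when the log-likelihood gain falls below `tol`.
#' @param n_restarts number of seeded restarts.
#' @return object of class `gmm_fit`: `weights` (length 2, sums to 1),
#'   `means` (2 x 2), `covariances` (list of 2), `responsibilities`
#'   (n x 2), `labels` (factor, `normodynamic`/`hyperdynamic` by argmax
#'   responsibility), `log_likelihood`, `ll_trace`, `iterations`.
#' @export
fit_two_component_gmm <- function(points, seed = 1L, max_iter = 200L,
                                  tol = 1e-8, n_restarts = 5L) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  if (nrow(X) < 4) stop("need at least 4 points")
  if (any(!is.finite(X))) stop("points must be finite")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      km <- stats::kmeans(X, centers = 2, nstart = 1)
      fit <- tryCatch(gmm_em_once(X, km$centers, max_iter, tol),
                      error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$log_likelihood > best$log_likelihood))
        best <- fit
    }
  })
  if (is.null(best)) stop("fit error: all EM restarts failed")
  ord <- order(best$means[, 1])     # component 2 = higher CO mean
  best$weights <- best$weights[ord]
  best$means <- best$means[ord, , drop = FALSE]
  best$covariances <- best$covariances[ord]
  best$responsibilities <- best$responsibilities[, ord, drop = FALSE]
  hard <- max.col(best$responsibilities)
  best$labels <- factor(ifelse(hard == 2, "hyperdynamic", "normodynamic"),
                        levels = c("normodynamic", "hyperdynamic"))
  class(best) <- "gmm_fit"
  best
}

#' Group-difference tests for the cohort structure
#'
#' Shapiro-Wilk normality tests per group and variable, and two-sided
#' Mann-Whitney U tests (normal approximation, tie-corrected) comparing
#' cardiac output and mean aortic pressure between the two groups.
#'
#' @param params population parameter table (needs `cardiac_output` and
#'   `target_map`).
#' @param labels group labels (2 levels), e.g. planted groups or
#'   [fit_two_component_gmm()] labels.
#' @return data.frame with columns `test`, `variable`, `group`,
#'   `statistic`, `p_value`, `significant` (alpha = 0.05). The
#'   Mann-Whitney `statistic` is the U of the first group level.
#' @export
group_difference_tests <- function(params, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
  if (min(table(labels)) < 3) stop("test error: group size < 3")
  vars <- c(cardiac_output = "cardiac_output", mean_aortic_pressure = "target_map")
  rows <- list()
  for (v in names(vars)) {
    x <- params[[vars[[v]]]]
    for (g in levels(labels)) {
      xs <- x[labels == g]
      if (length(xs) > 5000) xs <- xs[seq(1, length(xs), length.out = 5000)]
      sw <- stats::shapiro.test(xs)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "shapiro_wilk", variable = v, group = g,
        statistic = unname(sw$statistic), p_value = sw$p.value)
    }
    mw <- stats::wilcox.test(x[labels == levels(labels)[1]],
                             x[labels == levels(labels)[2]],
                             exact = FALSE, correct = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "mann_whitney_u", variable = v, group = "between",
      statistic = unname(mw$statistic), p_value = mw$p.value)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05
  out
}
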