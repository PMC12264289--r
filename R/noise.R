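#' Measurement-noise configuration
#'
#' Parameters of the Gaussian-plus-spike corruption model: every point of a
#' 150-point waveform vector receives additive Gaussian noise
#' `n_i ~ N(mu, sigma^2)`, and a random 20 percent of the indices
#' additionally receive a spike `r_i ~ U(-A, A)` with
#' `A = spike_relative_amplitude * max(x)`. Study defaults:
#' `(mu = 0.7, sigma = 1.0)` for calibrated (mmHg) signals and
#' `(mu = 0, sigma = 0.1)` for uncalibrated ones, spikes at 20 percent of
#' points with 10 percent relative amplitude.
#'
#' @param mu Gaussian mean, signal units.
#' @param sigma Gaussian SD, signal units (>= 0).
#' @param spike_fraction fraction of points spiked, in `[0, 1]`.
#' @param spike_relative_amplitude spike amplitude as a fraction of the
#'   signal maximum (>= 0).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(mu = 0, sigma = 0.1, spike_fraction = 0.2,
                         spike_relative_amplitude = 0.1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (spike_fraction < 0 || spike_fraction > 1)
    stop("spike_fraction must be in [0, 1]")
  if (spike_relative_amplitude < 0)
    stop("spike_relative_amplitude must be >= 0")
  structure(list(mu = mu, sigma = sigma, spike_fraction = spike_fraction,
                 spike_relative_amplitude = spike_relative_amplitude),
            class = "noise_config")
}

#' Study-default noise settings per calibration state
#'
#' @param calibrated logical.
#' @return a [noise_config()]: `(mu = 0.7, sigma = 1.0)` if calibrated,
#'   `(mu = 0, sigma = 0.1)` otherwise, both with 20 percent spikes at 10
#'   percent of the signal maximum.
#' @export
default_noise_config <- function(calibrated) {
  if (calibrated) noise_config(mu = 0.7, sigma = 1.0)
  else noise_config(mu = 0, sigma = 0.1)
}

inject_noise_vector <- function(x, cfg) {
  n <- length(x)
  out <- x + stats::rnorm(n, cfg$mu, cfg$sigma)
  k <- round(cfg$spike_fraction * n)
  if (k > 0) {
    idx <- sample.int(n, k)               # without replacement: distinct
    A <- cfg$spike_relative_amplitude * max(x)
    out[idx] <- out[idx] + stats::runif(k, -A, A)
  }
  out
}

#' Corrupt waveform vectors with Gaussian noise and random spikes
#'
#' Applies `x_i + n_i (+ r_i for i in I)` per the noise model of
#' [noise_config()]. The spike index set `I` (size
#' `round(spike_fraction * length)`, 30 for the default 150-point vector)
#' is drawn uniformly without replacement, afresh for every waveform. The
#' output is deliberately not re-normalized: noisy uncalibrated values may
#' leave `[0, 1]`. Deterministic given `seed`.
#'
#' @param x a numeric vector (one waveform) or matrix (subjects x points).
#' @param cfg a [noise_config()].
#' @param seed integer seed.
#' @return corrupted vector or matrix of the same shape.
#' @export
inject_noise <- function(x, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "noise_config"))
  with_seed(seed, {
    if (is.matrix(x)) {
      out <- t(apply(x, 1, inject_noise_vector, cfg = cfg))
      dimnames(out) <- dimnames(x)
      attributes(out)$calibrated <- attr(x, "calibrated")
      out
    } else {
      y <- inject_noise_vector(as.numeric(x), cfg)
      attributes(y) <- attributes(x)
      y
    }
  })
}
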