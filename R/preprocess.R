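#' Resample a waveform to the fixed model-input length
#'
#' Piecewise-linear interpolation of one cardiac cycle onto `n` uniformly
#' spaced time points covering the half-open cycle `[0, period)` (first
#' point at t = 0, spacing `period/n`); the duplicated cycle endpoint is
#' not included, so a repeated cycle concatenates seamlessly. Values at
#' grid points that coincide with input samples are preserved. Periodicity
#' supplies the value beyond the last input sample.
#'
#' @param wave a [pressure_waveform()] (at least 2 samples).
#' @param n output length (default 150, the model-input size).
#' @return a `wave_vector`: numeric vector of length `n` with attributes
#'   `calibrated = TRUE`, `site`, `period`.
#' @export
resample_to_fixed_length <- function(wave, n = 150L) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (length(wave$pressure) < 2) stop("domain error: need >= 2 samples")
  if (any(diff(wave$time) <= 0)) stop("domain error: non-monotone time base")
  # close the cycle at t = period with the t = 0 value, then interpolate
  tt <- c(wave$time, wave$period)
  pp <- c(wave$pressure, wave$pressure[1])
  grid <- (seq_len(n) - 1) / n * wave$period
  out <- stats::approx(tt, pp, xout = grid, method = "linear")$y
  wave_vector(out, calibrated = TRUE, site = wave$site, period = wave$period)
}

wave_vector <- function(values, calibrated, site = NA_character_,
                        period = NA_real_) {
  structure(as.numeric(values), calibrated = calibrated, site = site,
            period = period, class = "wave_vector")
}

#' Amplitude-normalize a waveform vector
#'
#' Maps a calibrated waveform vector to the unitless "uncalibrated" form
#' `(P - P_min) / (P_max - P_min)`, so the output spans exactly `[0, 1]`.
#' Idempotent, and invariant to affine recalibration of the input.
#'
#' @param vec a `wave_vector` (or plain numeric vector).
#' @return a `wave_vector` with `calibrated = FALSE`, min 0 and max 1.
#' @export
normalize_amplitude <- function(vec) {
  v <- as.numeric(vec)
  rng <- max(v) - min(v)
  if (rng <= 0) stop("degenerate waveform: zero amplitude range")
  wave_vector((v - min(v)) / rng, calibrated = FALSE,
              site = attr(vec, "site") %||% NA_character_,
              period = attr(vec, "period") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the model-input matrix for one site
#'
#' Resamples every subject's single cycle at `site` to `n` points and
#' optionally amplitude-normalizes each row.
#'
#' @param pop a `co_population` from [generate_population()].
#' @param site site name.
#' @param calibrated if `FALSE`, each row is normalized to `[0, 1]`.
#' @param n vector length (default 150).
#' @return numeric matrix (subjects x n) with attribute `calibrated`;
#'   rownames are subject ids.
#' @export
wave_matrix <- function(pop, site, calibrated = TRUE, n = 150L) {
  stopifnot(inherits(pop, "co_population"))
  if (!site %in% names(pop$waveforms)) stop("unknown site: ", site)
  W <- pop$waveforms[[site]]
  S <- ncol(W)
  # the simulation grid is uniform over [0, period): linear interpolation
  # in cycle-fraction space is subject-independent
  frac_in <- c((seq_len(S) - 1) / S, 1)
  frac_out <- (seq_len(n) - 1) / n
  j <- findInterval(frac_out, frac_in)
  w1 <- (frac_out - frac_in[j]) / (frac_in[j + 1] - frac_in[j])
  Wc <- cbind(W, W[, 1])
  M <- Wc[, j, drop = FALSE] * (1 - rep(w1, each = nrow(W))) +
    Wc[, j + 1, drop = FALSE] * rep(w1, each = nrow(W))
  if (!calibrated) {
    lo <- apply(M, 1, min); hi <- apply(M, 1, max)
    if (any(hi - lo <= 0)) stop("degenerate waveform: zero amplitude range")
    M <- (M - lo) / (hi - lo)
  }
  dimnames(M) <- list(pop$params$id, NULL)
  attr(M, "calibrated") <- calibrated
  attr(M, "site") <- site
  M
}

#' Export a model-input matrix as CSV
#'
#' One row per subject-site with metadata columns (`subject_id`, `site`,
#' `calibrated`) followed by the 150 value columns `v1..v150`.
#'
#' @param M matrix from [wave_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_wave_matrix <- function(M, path) {
  df <- data.frame(subject_id = rownames(M),
                   site = attr(M, "site") %||% NA_character_,
                   calibrated = isTRUE(attr(M, "calibrated")))
  vals <- as.data.frame(M)
  names(vals) <- paste0("v", seq_len(ncol(M)))
  utils::write.csv(cbind(df, vals), path, row.names = FALSE)
  invisible(path)
}
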