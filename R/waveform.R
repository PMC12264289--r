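#' Single-cycle pressure waveform
#'
#' Lightweight container for one periodic cardiac cycle of pressure at a
#' named arterial site. Samples span the half-open interval `[0, period)`
#' uniformly; the value at `t = period` equals the value at `t = 0` by
#' periodicity.
#'
#' @param site site name (see [site_specs()]).
#' @param period cycle duration in seconds.
#' @param pressure numeric vector of pressures (mmHg) at uniform times
#'   `(0:(n-1)) / n * period`.
#' @param time optional explicit time base; defaults to the uniform grid.
#' @return object of class `pressure_waveform` with fields `site`, `period`,
#'   `time`, `pressure`.
#' @export
pressure_waveform <- function(site, period, pressure, time = NULL) {
  n <- length(pressure)
  if (n < 2) stop("a waveform needs at least 2 samples")
  if (!is.finite(period) || period <= 0) stop("period must be positive")
  if (any(!is.finite(pressure))) stop("pressure must be finite")
  if (is.null(time)) time <- (seq_len(n) - 1) / n * period
  if (length(time) != n) stop("time and pressure lengths differ")
  if (any(diff(time) <= 0)) stop("non-monotone time base")
  if (time[n] >= period) stop("samples must span [0, period)")
  structure(list(site = site, period = period, time = time,
                 pressure = pressure),
            class = "pressure_waveform")
}

#' Summary pressures of a waveform
#'
#' @param wave a [pressure_waveform()].
#' @return named numeric vector: `mean`, `systolic`, `diastolic`,
#'   `pulse_pressure`, all in mmHg. The mean is the cycle average (a plain
#'   average over the uniform half-open grid).
#' @export
waveform_summary <- function(wave) {
  stopifnot(inherits(wave, "pressure_waveform"))
  p <- wave$pressure
  c(mean = mean(p), systolic = max(p), diastolic = min(p),
    pulse_pressure = max(p) - min(p))
}

#' @export
print.pressure_waveform <- function(x, ...) {
  s <- waveform_summary(x)
  cat(sprintf(
    "<pressure_waveform> %s, period %.3f s, %d samples\n  %0.1f/%0.1f (mean %0.1f, PP %0.1f) mmHg\n",
    x$site, x$period, length(x$pressure),
    s["systolic"], s["diastolic"], s["mean"], s["pulse_pressure"]))
  invisible(x)
}
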