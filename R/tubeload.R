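#' Tube-load transfer function
#'
#' Frequency response of a uniform lossy transmission line of length `L`
#' terminated by a reflection coefficient `gamma`:
#' `H(w) = (1 + gamma) e^{-(jw/c + alpha) L} / (1 + gamma e^{-2 (jw/c + alpha) L})`.
#' This is the classic single tube-load model: a propagation delay `L/c`,
#' exponential attenuation `alpha` per unit length, and a terminal
#' reflection that produces peripheral pulse-pressure amplification near the
#' quarter-wavelength frequency.
#'
#' @param omega angular frequency rad/s (vector).
#' @param path_length cm.
#' @param pwv wave speed, m/s.
#' @param gamma terminal reflection coefficient in `[0, 1)`.
#' @param alpha attenuation per cm.
#' @return complex vector `H(omega)`.
#' @export
tube_load_transfer <- function(omega, path_length, pwv, gamma, alpha) {
  if (gamma >= 1 || gamma < 0) stop("domain error: reflection coefficient must be in [0, 1)")
  c_cm <- pwv * 100
  g <- (1i * omega / c_cm + alpha) * path_length
  e1 <- exp(-g)
  (1 + gamma) * e1 / (1 + gamma * e1^2)
}

# Propagate a batch of aortic cycles (rows of `pressure`) to one site.
# The mean (DC) level is left to the explicit per-cm pressure-drop term;
# the transfer acts on the pulsatile harmonics only, per subject because
# both the cycle period and the pulse wave velocity differ across subjects.
tubeload_propagate_batch <- function(pressure, period, pwv, site_row) {
  n <- nrow(pressure)
  S <- ncol(pressure)
  L <- site_row$path_length
  if (L == 0) {                     # identity site
    out <- pressure
    return(out)
  }
  gamma <- site_row$reflection_coefficient
  alpha <- site_row$attenuation_per_cm
  if (gamma >= 1) stop("domain error: reflection coefficient must be < 1")
  Fh <- stats::mvfft(t(pressure))            # S x n, harmonics in rows
  half <- S %/% 2
  k <- seq_len(half)                         # harmonics 1..S/2
  omega <- 2 * pi * outer(k, 1 / period)     # half x n
  c_cm <- matrix(pwv * 100, length(k), n, byrow = TRUE)
  e1 <- exp(-(1i * omega / c_cm + alpha) * L)
  H <- (1 + gamma) * e1 / (1 + gamma * e1^2)
  H[half, ] <- Re(H[half, ])                 # keep Nyquist bin real
  Fh[2:(half + 1), ] <- Fh[2:(half + 1), ] * H
  if (S > half + 1)
    Fh[S:(half + 2), ] <- Fh[S:(half + 2), ] * Conj(H[seq_len(S - half - 1), ])
  out <- t(Re(stats::mvfft(Fh, inverse = TRUE)) / S)
  out - site_row$mean_pressure_drop_per_cm * L
}

#' Propagate an aortic waveform to a peripheral site
#'
#' Decomposes the pulsatile component of the aortic cycle into its Fourier
#' series, applies the single [tube_load_transfer()] response harmonic by
#' harmonic, reconstructs the time signal, and lowers the mean level by
#' `mean_pressure_drop_per_cm * path_length`.
#'
#' @param aortic a [pressure_waveform()] at the ascending aorta.
#' @param site a site name or one-row data.frame from [site_specs()];
#'   must not be the ascending aorta.
#' @param params subject parameters (needs `pulse_wave_velocity`, m/s).
#' @param sites site table used when `site` is given by name.
#' @return a [pressure_waveform()] at the peripheral site. If the resulting
#'   diastolic pressure is not positive a `simulation-quality` warning is
#'   raised and the attribute `quality_flag` is set on the result.
#' @export
propagate_to_site <- function(aortic, site, params, sites = site_specs()) {
  stopifnot(inherits(aortic, "pressure_waveform"))
  if (is.character(site)) {
    i <- match(site, sites$name)
    if (is.na(i)) stop("unknown site: ", site)
    site <- sites[i, ]
  }
  if (site$name == "ascending_aorta")
    stop("propagation target must be a peripheral site")
  out <- tubeload_propagate_batch(matrix(aortic$pressure, nrow = 1),
                                  aortic$period,
                                  params$pulse_wave_velocity, site)
  wave <- pressure_waveform(site$name, aortic$period, as.vector(out))
  if (min(wave$pressure) <= 0) {
    warning("simulation-quality: non-positive diastolic pressure at ", site$name)
    attr(wave, "quality_flag") <- "nonpositive_diastolic"
  }
  wave
}
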