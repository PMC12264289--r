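#' Half-sine systolic ejection flow
#'
#' Aortic inflow model: `Q(t) = pi*SV/(2*T_ej) * sin(pi*t/T_ej)` during
#' ejection (`t < T_ej`) and zero in diastole. The half-sine integrates
#' exactly to the stroke volume over the ejection window.
#'
#' @param t time in seconds (vector), within `[0, period)`.
#' @param stroke_volume mL.
#' @param t_ej ejection duration, seconds.
#' @return flow in mL/s.
#' @export
ejection_flow <- function(t, stroke_volume, t_ej) {
  ifelse(t < t_ej & t >= 0,
         pi * stroke_volume / (2 * t_ej) * sin(pi * t / t_ej), 0)
}

# Vectorized Windkessel integration for a whole parameter table.
#
# Exponential-Euler stepping (exact for flow held constant over a step,
# sampled at midpoints) of C dP_wk/dt = Q - (P_wk - P_ven)/R, run cycle by
# cycle until |P(0) - P(period)| < tol for every subject, then one recording
# pass. Returns the aortic pressure P_ao = P_wk + Zc*Q on the uniform grid
# t_s = s/S * period, s = 0..S-1.
wk_simulate_batch <- function(params, steps_per_cycle = 512L,
                              max_cycles = 50L, tol = 0.01) {
  n <- nrow(params)
  S <- as.integer(steps_per_cycle)
  hr <- params$heart_rate
  period <- 60 / hr
  dt <- period / S
  sv <- params$stroke_volume
  R <- params$peripheral_resistance
  C <- params$total_compliance
  Zc <- params$characteristic_impedance
  Pven <- params$venous_pressure
  t_ej <- params$ejection_fraction_of_cycle * period
  if (any(R <= 0) || any(C <= 0) || any(sv <= 0))
    stop("domain error: R, C and stroke volume must be positive")

  frac <- (seq_len(S) - 1) / S
  tg <- outer(period, frac)                 # n x S, grid times
  ratio_g <- tg / t_ej                      # t_ej recycles over rows
  amp <- pi * sv / (2 * t_ej)
  Qg <- amp * sin(pi * pmin(ratio_g, 1)) * (ratio_g < 1)
  ratio_m <- (tg + dt / 2) / t_ej
  Qm <- amp * sin(pi * pmin(ratio_m, 1)) * (ratio_m < 1)

  E <- exp(-dt / (R * C))
  RQ <- R * Qm                              # n x S (R recycles over rows)
  Pwk <- params$target_map                  # warm start at the target mean
  converged <- rep(FALSE, n)
  cycles_used <- rep(NA_integer_, n)
  for (cyc in seq_len(max_cycles)) {
    P_start <- Pwk
    for (s in seq_len(S)) {
      Pinf <- Pven + RQ[, s]
      Pwk <- Pinf + (Pwk - Pinf) * E
    }
    newly <- !converged & abs(Pwk - P_start) < tol
    cycles_used[newly] <- cyc
    converged <- converged | newly
    if (all(converged)) break
  }
  if (!all(converged))
    stop("convergence error: ", sum(!converged),
         " subject(s) not periodic after ", max_cycles, " cycles")

  M <- matrix(0, n, S)
  for (s in seq_len(S)) {
    M[, s] <- Pwk
    Pinf <- Pven + RQ[, s]
    Pwk <- Pinf + (Pwk - Pinf) * E
  }
  list(pressure = M + Zc * Qg, flow = Qg, period = period,
       cycles_used = cycles_used)
}

#' Simulate the ascending-aortic pressure waveform of one subject
#'
#' Integrates the three-element Windkessel
#' `C dP_wk/dt = Q(t) - (P_wk - P_ven)/R` with `P_ao = P_wk + Z_c Q(t)`,
#' driven by the half-sine ejection flow of [ejection_flow()], cycle by
#' cycle until periodic steady state (`|P(0) - P(period)| < 0.01` mmHg,
#' at most 50 cycles), and returns the final cycle.
#'
#' @param params a one-row data.frame (or named list) of cardiac parameters
#'   as produced by [sample_parameters()]: `heart_rate`, `stroke_volume`,
#'   `peripheral_resistance`, `total_compliance`,
#'   `characteristic_impedance`, `ejection_fraction_of_cycle`,
#'   `venous_pressure`, `target_map`.
#' @param dt integration step in seconds; must satisfy `dt <= period/300`.
#' @return a [pressure_waveform()] at the ascending aorta.
#' @export
simulate_aortic_pressure <- function(params, dt = NULL) {
  params <- as.data.frame(as.list(unlist(params[c(
    "heart_rate", "stroke_volume", "peripheral_resistance",
    "total_compliance", "characteristic_impedance",
    "ejection_fraction_of_cycle", "venous_pressure", "target_map")])))
  period <- 60 / params$heart_rate
  if (is.null(dt)) dt <- period / 512
  if (dt > period / 300 + 1e-12)
    stop("dt must be <= period/300")
  S <- as.integer(round(period / dt))
  sim <- wk_simulate_batch(params, steps_per_cycle = S)
  pressure_waveform("ascending_aorta", period, as.vector(sim$pressure[1, ]))
}
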