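# Truncated-normal sampling by rejection (the truncation windows used here
# keep the acceptance rate high, so plain rejection is adequate).
rtruncnorm_rej <- function(n, mean, sd, lower = -Inf, upper = Inf,
                           max_rounds = 1000L) {
  if (sd <= 0) stop("configuration error: SD must be positive")
  if (lower > mean + 3 * sd || upper < mean - 3 * sd)
    stop("configuration error: truncation bounds exclude the mean by > 3 SD")
  out <- numeric(0)
  for (i in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need <= 0) break
    draw <- stats::rnorm(ceiling(need * 1.5) + 8L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

sample_group_parameters <- function(gname, gcfg, cfg, n = gcfg$n) {
  pven <- cfg$venous_pressure
  hr <- rtruncnorm_rej(n, gcfg$hr_mean, gcfg$hr_sd,
                       gcfg$hr_bounds[1], gcfg$hr_bounds[2])
  # CO and MAP' = MAP - P_ven jointly lognormal with correlation rho:
  # moment-matched so the marginal mean/SD equal the configured group values.
  sc <- sqrt(log(1 + (gcfg$co_sd / gcfg$co_mean)^2))
  mc <- log(gcfg$co_mean) - sc^2 / 2
  mapp <- gcfg$map_mean - pven
  sm <- sqrt(log(1 + (gcfg$map_sd / mapp)^2))
  mm <- log(mapp) - sm^2 / 2
  z1 <- rtruncnorm_rej(n, 0, 1, -3, 3)
  z2 <- stats::rnorm(n)
  rho <- gcfg$co_map_rho
  co <- exp(mc + sc * z1)
  map_prime <- exp(mm + sm * (rho * z1 + sqrt(1 - rho^2) * z2))
  sv <- 1000 * co / hr
  qbar <- co * 1000 / 60                      # mean flow, mL/s
  zc <- rtruncnorm_rej(n, cfg$zc_mean, cfg$zc_sd,
                       max(1e-3, cfg$zc_mean - 3 * cfg$zc_sd),
                       cfg$zc_mean + 3 * cfg$zc_sd)
  r_total <- map_prime / qbar                 # total input resistance
  rp <- r_total - zc
  bad <- rp <= 0.05
  rp[bad] <- 0.05                             # guard; flagged by plausibility check
  compl <- gcfg$compliance_c0 * exp(stats::rnorm(n, 0, gcfg$compliance_lsd))
  ef <- cfg$ejection_intercept + cfg$ejection_slope * co +
    stats::rnorm(n, 0, cfg$ejection_jitter)
  ef <- pmin(pmax(ef, cfg$ejection_bounds[1]), cfg$ejection_bounds[2])
  pwv <- stats::runif(n, cfg$pwv_range[1], cfg$pwv_range[2])
  data.frame(
    group = gname,
    heart_rate = hr,
    stroke_volume = sv,
    cardiac_output = hr * sv / 1000,          # exact by construction
    target_map = pven + map_prime,
    peripheral_resistance = rp,
    total_compliance = compl,
    characteristic_impedance = zc,
    ejection_fraction_of_cycle = ef,
    venous_pressure = pven,
    pulse_wave_velocity = pwv,
    stringsAsFactors = FALSE
  )
}

#' Sample cohort cardiac/vascular parameters
#'
#' Draws one parameter set per subject for the two-group virtual cohort.
#' Per group: heart rate from a truncated normal at the configured bounds;
#' cardiac output and mean aortic pressure jointly lognormal
#' (moment-matched to the configured group mean/SD, within-group correlation
#' `co_map_rho`); peripheral resistance derived so the steady-state
#' Windkessel mean pressure hits the target MAP
#' (`R = (MAP - P_ven)/Qbar - Z_c`); compliance lognormal around the
#' group's calibrated level so aortic pulse pressure approximates the
#' target ranges; ejection fraction of cycle from the systolic-time
#' relation (rising with CO); pulse wave velocity uniform.
#'
#' @param config a [population_config()].
#' @param seed optional override of `config$seed`.
#' @return data.frame with one row per subject (normodynamic rows first),
#'   columns as in the `CardiacParameters` description above plus `id`.
#' @export
sample_parameters <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "population_config"))
  with_seed(seed, {
    params <- rbind(
      sample_group_parameters("normodynamic", config$groups$normodynamic, config),
      sample_group_parameters("hyperdynamic", config$groups$hyperdynamic, config)
    )
    params$id <- seq_len(nrow(params))
    params[, c("id", setdiff(names(params), "id"))]
  })
}

# Physical-plausibility screen applied to generated subjects.
plausible_subjects <- function(params, waves) {
  ok <- params$peripheral_resistance > 0.05 &
    params$ejection_fraction_of_cycle > 0 &
    params$ejection_fraction_of_cycle <= 0.6
  for (w in waves) ok <- ok & apply(w, 1, min) > 0 & apply(w, 1, max) < 350
  ok
}

simulate_all_sites <- function(params, config) {
  sim <- wk_simulate_batch(params, config$steps_per_cycle)
  waves <- list(ascending_aorta = sim$pressure)
  peripheral <- config$sites[config$sites$name != "ascending_aorta", ]
  for (i in seq_len(nrow(peripheral))) {
    row <- peripheral[i, ]
    waves[[row$name]] <- tubeload_propagate_batch(
      sim$pressure, sim$period, params$pulse_wave_velocity, row)
  }
  list(waves = waves, period = sim$period, cycles_used = sim$cycles_used)
}

#' Generate the virtual cohort
#'
#' Samples parameters ([sample_parameters()]), synthesizes the
#' ascending-aortic cycle for every subject (three-element Windkessel,
#' periodic steady state) and propagates it to the three peripheral sites
#' (tube-load transfer). Subjects failing the physical-plausibility screen
#' (non-positive pressures, implausible resistance or ejection fraction)
#' are resampled; more than 10 percent resampling aborts with a
#' calibration error. Deterministic given `config$seed`.
#'
#' @param config a [population_config()].
#' @return object of class `co_population`: list with `params` (data.frame),
#'   `waveforms` (named list of n x steps matrices, one per site; row i is
#'   subject i's single cycle on the uniform half-open grid), `period`
#'   (vector, s), `config`, and `n_resampled`.
#' @export
generate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  seeds <- child_seeds(config$seed, 12L)
  params <- sample_parameters(config, seed = seeds[1])
  sim <- simulate_all_sites(params, config)
  ok <- plausible_subjects(params, sim$waves)
  n_resampled <- 0L
  round <- 1L
  while (any(!ok) && round < 10L) {
    idx <- which(!ok)
    n_resampled <- n_resampled + length(idx)
    if (n_resampled > 0.1 * config$n_total)
      stop("calibration error: > 10% of subjects required resampling")
    for (g in unique(params$group[idx])) {
      gi <- idx[params$group[idx] == g]
      repl <- with_seed(seeds[1] + round, {
        sample_group_parameters(g, config$groups[[g]], config, n = length(gi))
      })
      repl$id <- params$id[gi]
      params[gi, ] <- repl[, names(params)]
    }
    sim_new <- simulate_all_sites(params[idx, , drop = FALSE], config)
    for (s in names(sim$waves)) sim$waves[[s]][idx, ] <- sim_new$waves[[s]]
    sim$period[idx] <- sim_new$period
    ok2 <- plausible_subjects(params[idx, , drop = FALSE],
                              lapply(sim_new$waves, identity))
    ok[idx] <- ok2
    round <- round + 1L
  }
  if (any(!ok))
    stop("calibration error: subjects still implausible after resampling")
  structure(list(params = params, waveforms = sim$waves,
                 period = sim$period, config = config,
                 n_resampled = n_resampled),
            class = "co_population")
}

#' Extract one subject's waveform from a population
#'
#' @param pop a `co_population`.
#' @param id subject id.
#' @param site site name.
#' @return a [pressure_waveform()].
#' @export
subject_waveform <- function(pop, id, site = "ascending_aorta") {
  stopifnot(inherits(pop, "co_population"))
  i <- match(id, pop$params$id)
  if (is.na(i)) stop("unknown subject id")
  if (!site %in% names(pop$waveforms)) stop("unknown site: ", site)
  pressure_waveform(site, pop$period[i], pop$waveforms[[site]][i, ])
}

#' Summarize cohort pressures per group and site
#'
#' Per group and site, the (min, max, mean, SD) of subject-level mean,
#' systolic, diastolic and pulse pressure — the layout used by the study's
#' descriptive pressure table, for generator calibration checks.
#'
#' @param pop a `co_population`.
#' @return data.frame with columns `group`, `site`, `measure`
#'   (mean/systolic/diastolic/pulse_pressure), `min`, `max`, `mean`, `sd`.
#' @export
summarize_population <- function(pop) {
  stopifnot(inherits(pop, "co_population"))
  if (nrow(pop$params) == 0) stop("empty population")
  rows <- list()
  for (g in unique(pop$params$group)) {
    gi <- pop$params$group == g
    for (s in names(pop$waveforms)) {
      w <- pop$waveforms[[s]][gi, , drop = FALSE]
      vals <- list(mean = rowMeans(w),
                   systolic = apply(w, 1, max),
                   diastolic = apply(w, 1, min))
      vals$pulse_pressure <- vals$systolic - vals$diastolic
      for (m in names(vals)) {
        v <- vals[[m]]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, site = s, measure = m,
          min = min(v), max = max(v), mean = mean(v),
          sd = if (length(v) > 1) stats::sd(v) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Export a population to delimited files
#'
#' Writes `parameters.csv` (wide, one row per subject), `waveforms.csv`
#' (long: subject_id, site, time_s, pressure_mmhg) and `config.json`
#' (including the seed) into `dir`.
#'
#' @param pop a `co_population`.
#' @param dir output directory (created if needed).
#' @param sites which sites to export waveforms for.
#' @param thin keep every `thin`-th waveform sample (1 = all; the long
#'   format is bulky at full resolution).
#' @return invisibly, the paths written.
#' @export
write_population <- function(pop, dir, sites = names(pop$waveforms), thin = 4L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_path <- file.path(dir, "parameters.csv")
  utils::write.csv(pop$params, p_path, row.names = FALSE)
  keep <- seq(1, ncol(pop$waveforms[[1]]), by = thin)
  long <- list()
  for (s in sites) {
    w <- pop$waveforms[[s]][, keep, drop = FALSE]
    nt <- length(keep)
    long[[s]] <- data.frame(
      subject_id = rep(pop$params$id, times = nt),
      site = s,
      time_s = as.vector(outer(pop$period, (keep - 1) / ncol(pop$waveforms[[s]]))),
      pressure_mmhg = as.vector(w))
  }
  w_path <- file.path(dir, "waveforms.csv")
  utils::write.csv(do.call(rbind, long), w_path, row.names = FALSE)
  c_path <- file.path(dir, "config.json")
  cfg <- pop$config
  cfg$sites <- as.list(cfg$sites)
  jsonlite::write_json(cfg, c_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(parameters = p_path, waveforms = w_path, config = c_path))
}
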