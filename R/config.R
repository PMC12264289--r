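#' Arterial site specifications
#'
#' Returns the table of arterial measurement sites used throughout the
#' package: the central ascending aorta plus the three tonometry-ready
#' peripheral arteries (left common carotid, left superficial temporal and
#' left radial). Path lengths and bifurcation counts follow the reference
#' arterial-tree topology (carotid 20 cm / 2 bifurcations, temporal 46 cm /
#' 6, radial 79 cm / 4). Reflection coefficient, attenuation and mean
#' pressure drop parameterize the single-tube transmission-line transfer
#' used by [propagate_to_site()]; the aorta is the identity site (zero path
#' length, zero drop).
#'
#' @param overrides optional named list; each element is a named list of
#'   column overrides for one site, e.g.
#'   `list(left_radial = list(reflection_coefficient = 0.5))`.
#' @return data.frame with columns `name`, `path_length` (cm),
#'   `bifurcation_count`, `reflection_coefficient` (dimensionless, `[0,1)`),
#'   `attenuation_per_cm` (1/cm), `mean_pressure_drop_per_cm` (mmHg/cm).
#' @export
site_specs <- function(overrides = NULL) {
  specs <- data.frame(
    name = c("ascending_aorta", "left_common_carotid",
             "left_superficial_temporal", "left_radial"),
    path_length = c(0, 20, 46, 79),
    bifurcation_count = c(0L, 2L, 6L, 4L),
    reflection_coefficient = c(0, 0.50, 0.45, 0.55),
    attenuation_per_cm = c(0, 0.001, 0.004, 0.0025),
    mean_pressure_drop_per_cm = c(0, 0, 0.14, 0.11),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (site in names(overrides)) {
      i <- match(site, specs$name)
      if (is.na(i)) stop("unknown site in overrides: ", site)
      for (col in names(overrides[[site]])) {
        if (!col %in% names(specs)) stop("unknown site column: ", col)
        specs[i, col] <- overrides[[site]][[col]]
      }
    }
  }
  validate_site_specs(specs)
  specs
}

validate_site_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  if (any(specs$reflection_coefficient < 0 | specs$reflection_coefficient >= 1))
    stop("reflection coefficients must lie in [0, 1): unstable transfer otherwise")
  if (any(specs$attenuation_per_cm < 0) || any(specs$path_length < 0))
    stop("attenuation and path length must be non-negative")
  ao <- specs[specs$name == "ascending_aorta", ]
  if (nrow(ao) == 1 &&
      (ao$path_length != 0 || ao$mean_pressure_drop_per_cm != 0 ||
       ao$reflection_coefficient != 0))
    stop("ascending aorta must be the identity site (zero length, drop and reflection)")
  invisible(specs)
}

default_group_config <- function() {
  list(
    normodynamic = list(
      n = 2620L,
      co_mean = 5.5,  co_sd = 1.0,                 # L/min
      hr_mean = 81.9, hr_sd = 8.3,                 # bpm
      hr_bounds = c(61.1, 101.6),
      map_mean = 108.1, map_sd = 20.2,             # mmHg
      compliance_c0 = 1.82,                        # mL/mmHg, calibrated to PP ~ 33
      compliance_lsd = 0.25,                       # lognormal sd of compliance
      co_map_rho = 0.85                            # within-group log(CO)-log(MAP') corr
    ),
    hyperdynamic = list(
      n = 1198L,
      co_mean = 6.9,  co_sd = 1.0,
      hr_mean = 83.9, hr_sd = 7.7,
      hr_bounds = c(62.5, 101.6),
      map_mean = 85.8, map_sd = 11.8,
      compliance_c0 = 0.95,                        # calibrated to PP ~ 63
      compliance_lsd = 0.25,
      co_map_rho = 0.85
    )
  )
}

#' Virtual-cohort configuration
#'
#' Assembles the configuration object consumed by [sample_parameters()] and
#' [generate_population()]. Defaults reproduce the study cohort: 3818
#' subjects split into a normodynamic group (n = 2620; CO 5.5 +/- 1.0 L/min,
#' mean aortic pressure 108.1 +/- 20.2 mmHg, HR 81.9 +/- 8.3 bpm truncated to
#' [61.1, 101.6]) and a hyperdynamic group (n = 1198; CO 6.9 +/- 1.0 L/min,
#' MAP 85.8 +/- 11.8 mmHg, HR 83.9 +/- 7.7 bpm truncated to [62.5, 101.6]).
#'
#' @param n_normodynamic,n_hyperdynamic group sizes.
#' @param seed integer seed controlling every random draw downstream.
#' @param groups per-group sampling distributions; see
#'   `pulseco:::default_group_config()` for the field list.
#' @param sites site table from [site_specs()].
#' @param venous_pressure mmHg; downstream Windkessel outflow pressure.
#' @param zc_mean,zc_sd characteristic impedance distribution (mmHg s/mL).
#' @param pwv_range uniform sampling range for pulse wave velocity (m/s).
#' @param ejection_intercept,ejection_slope,ejection_jitter coefficients of
#'   the systolic-time relation: ejection fraction of the cycle
#'   `= intercept + slope * CO + N(0, jitter^2)`, clamped to
#'   `ejection_bounds`. The positive slope mirrors the physiological rise of
#'   left-ventricular ejection time with stroke volume and keeps cardiac
#'   output identifiable from cycle-normalized waveform shape.
#' @param ejection_bounds allowed range for the ejection fraction of cycle.
#' @param steps_per_cycle simulation grid resolution (samples per cardiac
#'   cycle; must be >= 300 so that dt <= period/300).
#' @param scale optional overall scaling of the cohort: group sizes are
#'   multiplied by `scale` (rounded, keeping proportions) — convenient for
#'   reduced-size runs.
#' @return list of class `population_config`.
#' @export
population_config <- function(n_normodynamic = 2620L,
                              n_hyperdynamic = 1198L,
                              seed = 1L,
                              groups = default_group_config(),
                              sites = site_specs(),
                              venous_pressure = 5,
                              zc_mean = 0.03, zc_sd = 0.004,
                              pwv_range = c(6, 10),
                              ejection_intercept = 0.10,
                              ejection_slope = 0.04,
                              ejection_jitter = 0.01,
                              ejection_bounds = c(0.15, 0.6),
                              steps_per_cycle = 512L,
                              scale = NULL) {
  if (!is.null(scale)) {
    stopifnot(scale > 0)
    n_normodynamic <- max(1L, as.integer(round(n_normodynamic * scale)))
    n_hyperdynamic <- max(1L, as.integer(round(n_hyperdynamic * scale)))
  }
  n_normodynamic <- as.integer(n_normodynamic)
  n_hyperdynamic <- as.integer(n_hyperdynamic)
  if (n_normodynamic <= 0 || n_hyperdynamic <= 0)
    stop("configuration error: group counts must be positive")
  groups$normodynamic$n <- n_normodynamic
  groups$hyperdynamic$n <- n_hyperdynamic
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (any(c(gr$co_sd, gr$hr_sd, gr$map_sd) <= 0))
      stop("configuration error: sampling SDs must be positive")
    if (gr$hr_bounds[1] > gr$hr_mean + 3 * gr$hr_sd ||
        gr$hr_bounds[2] < gr$hr_mean - 3 * gr$hr_sd)
      stop("configuration error: HR truncation bounds exclude the mean by > 3 SD")
  }
  if (steps_per_cycle < 300L)
    stop("steps_per_cycle must be >= 300 (dt <= period/300)")
  validate_site_specs(sites)
  structure(list(
    n_total = n_normodynamic + n_hyperdynamic,
    n_normodynamic = n_normodynamic,
    n_hyperdynamic = n_hyperdynamic,
    groups = groups,
    sites = sites,
    venous_pressure = venous_pressure,
    zc_mean = zc_mean, zc_sd = zc_sd,
    pwv_range = pwv_range,
    ejection_intercept = ejection_intercept,
    ejection_slope = ejection_slope,
    ejection_jitter = ejection_jitter,
    ejection_bounds = ejection_bounds,
    steps_per_cycle = as.integer(steps_per_cycle),
    seed = as.integer(seed)
  ), class = "population_config")
}

# Run a block with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from a master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
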