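# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

# ~300-subject cohort at the default proportions, fixed seed.
small_pop <- function() {
  cached("small_pop", function() {
    generate_population(population_config(scale = 300 / 3818, seed = 101))
  })
}

# one normodynamic-like parameter row for single-subject simulations
one_params <- function(hr = 75, sv = 70, R = 1.1, C = 1.8, zc = 0.03,
                       ef = 0.32, pven = 5, pwv = 8) {
  data.frame(heart_rate = hr, stroke_volume = sv, peripheral_resistance = R,
             total_compliance = C, characteristic_impedance = zc,
             ejection_fraction_of_cycle = ef, venous_pressure = pven,
             target_map = pven + (R + zc) * sv * hr / 60,
             pulse_wave_velocity = pwv)
}

expect_identical_numeric <- function(a, b, tol = 0) {
  expect_true(isTRUE(all.equal(a, b, tolerance = tol)))
}
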