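test_that("tiny populations keep counts and labels", {
  cfg <- population_config(n_normodynamic = 1, n_hyperdynamic = 1, seed = 3)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$params), 2)
  expect_setequal(pop$params$group, c("normodynamic", "hyperdynamic"))
  expect_equal(length(pop$waveforms), 4)
  # all four site waveforms share the subject's period = 60/HR
  expect_equal(pop$period, 60 / pop$params$heart_rate)
})

test_that("same seed reproduces the population exactly", {
  cfg <- population_config(scale = 40 / 3818, seed = 42)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$params, p2$params)
  expect_identical(p1$waveforms, p2$waveforms)
  p3 <- generate_population(population_config(scale = 40 / 3818, seed = 43))
  expect_false(identical(p1$params$cardiac_output, p3$params$cardiac_output))
})

test_that("degenerate (near-zero-variance) sampling collapses to group means", {
  groups <- pulseco:::default_group_config()
  for (g in names(groups)) {
    groups[[g]]$co_sd <- 1e-9
    groups[[g]]$hr_sd <- 1e-9
    groups[[g]]$map_sd <- 1e-9
    groups[[g]]$compliance_lsd <- 1e-9
  }
  cfg <- population_config(n_normodynamic = 5, n_hyperdynamic = 5,
                           groups = groups, seed = 7, ejection_jitter = 1e-12)
  params <- sample_parameters(cfg)
  for (g in names(groups)) {
    co <- params$cardiac_output[params$group == g]
    expect_equal(co, rep(groups[[g]]$co_mean, 5), tolerance = 1e-6)
    hr <- params$heart_rate[params$group == g]
    expect_equal(hr, rep(groups[[g]]$hr_mean, 5), tolerance = 1e-6)
  }
})

test_that("group sampling approaches the configured means", {
  pop <- small_pop()
  par <- pop$params
  for (g in c("normodynamic", "hyperdynamic")) {
    gc <- pop$config$groups[[g]]
    n <- sum(par$group == g)
    co <- par$cardiac_output[par$group == g]
    expect_lt(abs(mean(co) - gc$co_mean), 3 * gc$co_sd / sqrt(n))
    hr <- par$heart_rate[par$group == g]
    expect_lt(abs(mean(hr) - gc$hr_mean), 3 * gc$hr_sd / sqrt(n) + 0.1)
    expect_true(all(hr >= gc$hr_bounds[1] & hr <= gc$hr_bounds[2]))
  }
  # CO = HR x SV / 1000 exactly by construction
  expect_equal(par$cardiac_output, par$heart_rate * par$stroke_volume / 1000)
})

test_that("invalid configurations are rejected", {
  expect_error(population_config(n_normodynamic = 0), "configuration error")
  groups <- pulseco:::default_group_config()
  groups$normodynamic$co_sd <- -1
  expect_error(population_config(groups = groups), "configuration error")
  groups <- pulseco:::default_group_config()
  groups$normodynamic$hr_bounds <- c(200, 210)
  expect_error(population_config(groups = groups), "3 SD")
})

test_that("every generated subject satisfies the Windkessel DC property", {
  pop <- small_pop()
  ao <- pop$waveforms$ascending_aorta
  dc <- pop$params$venous_pressure +
    (pop$params$peripheral_resistance + pop$params$characteristic_impedance) *
    pop$params$cardiac_output * 1000 / 60
  rel <- abs(rowMeans(ao) - dc) / dc
  expect_lt(max(rel), 0.01)
})

test_that("groups differ strongly in CO (Mann-Whitney)", {
  pop <- small_pop()
  tests <- group_difference_tests(pop$params, pop$params$group)
  p_co <- tests$p_value[tests$test == "mann_whitney_u" &
                          tests$variable == "cardiac_output"]
  expect_lt(p_co, 0.001)
})

test_that("single-subject summaries are degenerate", {
  cfg <- population_config(n_normodynamic = 1, n_hyperdynamic = 1, seed = 9)
  pop <- generate_population(cfg)
  s <- summarize_population(pop)
  expect_true(all(s$sd == 0))
  expect_true(all(s$min == s$mean & s$max == s$mean))
})

test_that("population export writes the documented files", {
  pop <- small_pop()
  dir <- tempfile()
  paths <- write_population(pop, dir, sites = "ascending_aorta", thin = 64)
  expect_true(all(file.exists(paths)))
  par2 <- utils::read.csv(paths["parameters"])
  expect_equal(nrow(par2), nrow(pop$params))
  cfg2 <- jsonlite::read_json(paths["config"])
  expect_equal(cfg2$seed, pop$config$seed)
  unlink(dir, recursive = TRUE)
})
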