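test_that("resampling yields exactly 150 points and preserves lines", {
  period <- 0.8
  S <- 300
  tt <- (seq_len(S) - 1) / S * period
  # linear ramp 80 -> 120 over the cycle; the 150-point grid coincides
  # with every second input point, and linear interpolation is exact on a
  # line, so the closed form holds at machine precision
  ramp <- 80 + 40 * tt / period
  w <- pressure_waveform("ascending_aorta", period, ramp)
  v <- resample_to_fixed_length(w)
  expect_length(v, 150)
  grid <- (0:149) / 150 * period
  expect_equal(as.numeric(v), 80 + 40 * grid / period, tolerance = 1e-9)
  expect_true(attr(v, "calibrated"))
  # constant waveform
  vc <- resample_to_fixed_length(pressure_waveform("x", period, rep(100, 40)))
  expect_equal(as.numeric(vc), rep(100, 150))
})

test_that("resampling at the same length is idempotent", {
  pop <- small_pop()
  w <- subject_waveform(pop, 1, "left_radial")
  v1 <- resample_to_fixed_length(w, 150)
  w2 <- pressure_waveform("left_radial", w$period, as.numeric(v1))
  v2 <- resample_to_fixed_length(w2, 150)
  expect_equal(as.numeric(v2), as.numeric(v1), tolerance = 1e-9)
})

test_that("amplitude normalization maps to [0, 1] exactly", {
  v <- pulseco:::wave_vector(c(90, 95, 105, 110, 96, 92), calibrated = TRUE)
  nv <- normalize_amplitude(v)
  expect_equal(min(nv), 0, tolerance = 1e-12)
  expect_equal(max(nv), 1, tolerance = 1e-12)
  expect_equal(as.numeric(nv), (as.numeric(v) - 90) / 20)
  expect_false(attr(nv, "calibrated"))
  # idempotence
  expect_equal(as.numeric(normalize_amplitude(nv)), as.numeric(nv))
  expect_error(normalize_amplitude(rep(5, 10)), "degenerate")
})

test_that("normalization is invariant to affine recalibration", {
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(150, 100, 15)
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    expect_equal(as.numeric(normalize_amplitude(a * v + b)),
                 as.numeric(normalize_amplitude(v)), tolerance = 1e-10)
  }
})

test_that("wave_matrix matches per-subject resampling and normalizes rows", {
  pop <- small_pop()
  M <- wave_matrix(pop, "left_common_carotid", calibrated = TRUE)
  expect_equal(dim(M), c(nrow(pop$params), 150))
  w5 <- subject_waveform(pop, 5, "left_common_carotid")
  expect_equal(M[5, ], as.numeric(resample_to_fixed_length(w5)),
               tolerance = 1e-9)
  U <- wave_matrix(pop, "left_common_carotid", calibrated = FALSE)
  expect_equal(unname(apply(U, 1, min)), rep(0, nrow(U)), tolerance = 1e-12)
  expect_equal(unname(apply(U, 1, max)), rep(1, nrow(U)), tolerance = 1e-12)
})

test_that("matrix export round-trips", {
  pop <- small_pop()
  M <- wave_matrix(pop, "left_radial", calibrated = FALSE)
  f <- tempfile(fileext = ".csv")
  write_wave_matrix(M[1:5, ], f)
  df <- utils::read.csv(f)
  expect_equal(ncol(df), 153)                # 3 metadata + 150 values
  expect_equal(unname(as.matrix(df[, -(1:3)])), unname(M[1:5, ]),
               tolerance = 1e-12)
  unlink(f)
})
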