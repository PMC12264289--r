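# Independent brute-force evaluation of every agreement statistic, written
# from their definitions with explicit sums (no shared code with the
# implementation).
brute_report <- function(pred, ref) {
  n <- length(pred)
  mx <- sum(pred) / n; my <- sum(ref) / n
  sxy <- sum((pred - mx) * (ref - my))
  sxx <- sum((pred - mx)^2); syy <- sum((ref - my)^2)
  d <- pred - ref
  bias <- sum(d) / n
  sd_d <- sqrt(sum((d - bias)^2) / (n - 1))
  rmse <- sqrt(sum(d^2) / n)
  slope <- sxy / syy
  intercept <- mx - slope * my
  resid <- pred - (intercept + slope * ref)
  se_slope <- sqrt(sum(resid^2) / (n - 2) / syy)
  tval <- slope / se_slope
  list(r = sxy / sqrt(sxx * syy),
       rmse = rmse,
       nrmse = 100 * rmse / (max(ref) - min(ref)),
       mae = sum(abs(d)) / n,
       bias = bias,
       loa_low = bias - 1.96 * sd_d,
       loa_high = bias + 1.96 * sd_d,
       slope = slope, intercept = intercept,
       slope_p = 2 * stats::pt(-abs(tval), n - 2))
}

test_that("perfect agreement yields the degenerate report", {
  ref <- c(4.2, 5.1, 6.3, 7.7, 5.5)
  rep <- agreement_report(ref, ref)
  expect_equal(rep$r, 1)
  expect_equal(rep$nrmse, 0)
  expect_equal(rep$mae, 0)
  expect_equal(rep$bias, 0)
  expect_equal(c(rep$loa_low, rep$loa_high), c(0, 0))
  expect_equal(rep$slope, 1)
  expect_equal(rep$intercept, 0)
})

test_that("worked three-point example matches hand evaluation", {
  rep <- agreement_report(c(5, 6, 7), c(5.5, 6.0, 6.5))
  expect_equal(rep$mae, 1 / 3, tolerance = 1e-9)
  expect_equal(rep$rmse, sqrt(0.5^2 * 2 / 3), tolerance = 1e-9)   # 0.4082
  expect_equal(rep$nrmse, 40.82, tolerance = 1e-3)                # range 1.0
  expect_equal(rep$slope, 2)
})

test_that("Bland-Altman limits use 1.96 sample SDs of the differences", {
  # d = (0.5, -0.5, 0): sd = 0.5, LoA = bias +/- 0.98
  rep <- agreement_report(c(5.5, 5.5, 6.0), c(5.0, 6.0, 6.0))
  expect_equal(rep$bias, 0, tolerance = 1e-12)
  expect_equal(rep$loa_high, 1.96 * 0.5, tolerance = 1e-9)
  expect_equal(rep$loa_low, -1.96 * 0.5, tolerance = 1e-9)
  # bias identity: mean(pred) - mean(ref)
  set.seed(8)
  pred <- rnorm(50, 6, 1); ref <- rnorm(50, 6, 1)
  rep2 <- agreement_report(pred, ref)
  expect_equal(rep2$bias, mean(pred) - mean(ref), tolerance = 1e-12)
})

test_that("all statistics match brute-force evaluation on random inputs", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    ref <- rnorm(n, 6, 1.2)
    pred <- ref + rnorm(n, 0, 0.5)
    if (max(ref) == min(ref)) next
    a <- agreement_report(pred, ref)
    b <- brute_report(pred, ref)
    for (f in names(b))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-9, label = f)
  }
})

test_that("nRMSE is shift-invariant and scale-consistent", {
  set.seed(9)
  ref <- rnorm(30, 6, 1); pred <- ref + rnorm(30, 0, 0.4)
  a <- agreement_report(pred, ref)
  b <- agreement_report(pred + 3, ref + 3)
  expect_equal(a$nrmse, b$nrmse, tolerance = 1e-12)
  c2 <- agreement_report(2 * pred, 2 * ref)
  expect_equal(a$nrmse, c2$nrmse, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(agreement_report(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(agreement_report(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(agreement_report(c(1, 2, 3), c(1, 2)), "unequal")
})

test_that("Fisher-z paired test matches a step-by-step computation", {
  r_clean <- c(0.97, 0.99, 0.97, 0.94, 0.95, 0.93)
  r_noisy <- c(0.94, 0.94, 0.95, 0.84, 0.78, 0.84)
  out <- fisher_z_paired_test(r_clean, r_noisy)
  dz <- atanh(r_clean) - atanh(r_noisy)
  t_hand <- mean(dz) / (sd(dz) / sqrt(length(dz)))
  p_hand <- 2 * pt(-abs(t_hand), length(dz) - 1)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, p_hand, tolerance = 1e-12)
  expect_lt(out$p, 0.05)
  # identical lists: no difference
  same <- fisher_z_paired_test(r_clean, r_clean)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # transform check
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_error(fisher_z_paired_test(c(1, 0.5), c(0.4, 0.5)), "transform")
})

test_that("coefficient of variation uses the sample SD as a percentage", {
  expect_equal(coefficient_of_variation(rep(0.95, 4)), 0)
  expect_equal(round(coefficient_of_variation(c(0.97, 0.99, 0.97)), 1), 1.2)
  expect_equal(round(coefficient_of_variation(c(0.94, 0.95, 0.93)), 1), 1.1)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(1), ">= 2")
})
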