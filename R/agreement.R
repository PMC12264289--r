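#' Method-comparison agreement report
#'
#' Computes the full set of evaluation statistics used to compare
#' predicted against reference cardiac output: Pearson r, RMSE, nRMSE
#' (`100 * RMSE / (y_max - y_min)` with the range taken over the reference
#' values), MAE, Bland-Altman bias and 95 percent limits of agreement
#' (`bias +/- 1.96 * SD` of the differences, sample SD with n-1), and the
#' ordinary least-squares slope/intercept of predicted on reference with
#' the two-sided p-value for slope = 0. The difference sign convention is
#' `d = predicted - reference`.
#'
#' @param pred predicted values (L/min).
#' @param ref reference values (L/min); must not be constant.
#' @return list of class `agreement_report`: `r`, `rmse`, `nrmse`
#'   (percent), `mae`, `bias`, `loa_low`, `loa_high`, `slope`, `intercept`,
#'   `slope_p`, `n`.
#' @export
agreement_report <- function(pred, ref) {
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  if (length(pred) != length(ref)) stop("domain error: unequal lengths")
  n <- length(pred)
  if (n < 3) stop("domain error: need n >= 3")
  rng <- max(ref) - min(ref)
  if (rng <= 0) stop("nRMSE undefined: constant reference")
  d <- pred - ref
  rmse <- sqrt(mean(d^2))
  sd_d <- stats::sd(d)
  fit <- stats::lm(pred ~ ref)
  # summary.lm warns on an exactly perfect fit; the report is still defined
  coefs <- suppressWarnings(summary(fit)$coefficients)
  out <- list(
    r = stats::cor(pred, ref),
    rmse = rmse,
    nrmse = 100 * rmse / rng,
    mae = mean(abs(d)),
    bias = mean(d),
    loa_low = mean(d) - 1.96 * sd_d,
    loa_high = mean(d) + 1.96 * sd_d,
    slope = unname(coefs["ref", "Estimate"]),
    intercept = unname(coefs["(Intercept)", "Estimate"]),
    slope_p = unname(coefs["ref", "Pr(>|t|)"]),
    n = n
  )
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_report> n = %d\n",
           "  r %.3f | nRMSE %.1f%% | MAE %.2f | bias %.2f [LoA %.2f, %.2f]\n",
           "  slope %.2f, intercept %.2f (slope p %.2g)\n"),
    x$n, x$r, x$nrmse, x$mae, x$bias, x$loa_low, x$loa_high,
    x$slope, x$intercept, x$slope_p))
  invisible(x)
}

#' Paired comparison of correlation coefficients via Fisher z
#'
#' Applies the Fisher z-transformation `z = atanh(r)` elementwise to two
#' matched lists of correlation coefficients and runs a two-sided paired
#' t-test on the z pairs — the standard way to compare, e.g., calibrated
#' against uncalibrated model correlations across sites.
#'
#' @param r_a,r_b equal-length vectors of correlations, all `|r| < 1`.
#' @return list with `t`, `p`, `df`.
#' @export
fisher_z_paired_test <- function(r_a, r_b) {
  if (length(r_a) != length(r_b)) stop("unequal lengths")
  if (length(r_a) < 2) stop("need >= 2 pairs")
  if (any(abs(c(r_a, r_b)) >= 1)) stop("transform error: |r| must be < 1")
  dz <- atanh(r_a) - atanh(r_b)
  if (all(abs(dz - dz[1]) < 1e-15) && abs(dz[1]) < 1e-15)
    return(list(t = 0, p = 1, df = length(dz) - 1))
  tt <- stats::t.test(atanh(r_a), atanh(r_b), paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation — the
#' scale-independent measure used to express inter-site variability of a
#' performance metric.
#'
#' @param values numeric vector, n >= 2, non-zero mean.
#' @return percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("domain error: zero mean")
  100 * stats::sd(values) / m
}
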