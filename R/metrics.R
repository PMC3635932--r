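#' Percentage estimation error of the visit-1 harm rate
#'
#' Estimation error is the proxy for precision: half the width of the 95%
#' confidence interval of the visit-1 harm rate, expressed as a percentage.
#' It is computed as `100 * 0.5 * median(CI width)` over the non-failed
#' replicate fits, divided by either the true baseline rate (`"true_rate"`,
#' the default) or the median visit-1 rate estimate (`"median_estimate"`).
#' The two denominators coincide when the estimator is unbiased (low
#' inter-patient variation); under strong heterogeneity the naive estimator
#' is biased upwards and the conventions differ — both are provided.
#'
#' When 10% or more of the fits failed the error is suppressed (returned as
#' `NA`): such scenarios have so few events that the median interval is not
#' meaningful, and they sit far outside the acceptable-precision region
#' anyway. Acceptable precision is an estimation error below ±25%.
#'
#' @param fits Replicate fits: the data frame from
#'   `run_scenario(..., keep_fits = TRUE)` or a list of [fit_rate_model()]
#'   results.
#' @param spec The generating [scenario_spec()] (supplies the true rate).
#' @param denominator `"true_rate"` or `"median_estimate"`.
#' @return Estimation error in percent, or `NA` when suppressed.
#' @export
estimation_error <- function(fits, spec,
                             denominator = c("true_rate", "median_estimate")) {
  denominator <- match.arg(denominator)
  assert_scenario(spec)
  fits <- as_fit_frame(fits)
  if (nrow(fits) == 0) stop("no replicate fits supplied", call. = FALSE)
  if (mean(fits$failed) >= 0.10) return(NA_real_)
  ok <- fits[!fits$failed, , drop = FALSE]
  if (nrow(ok) == 0) return(NA_real_)
  half_width <- 0.5 * stats::median(ok$upper - ok$lower)
  denom <- switch(denominator,
                  true_rate = spec$baseline_rate,
                  median_estimate = stats::median(ok$rate_visit1))
  100 * half_width / denom
}

#' Power to detect a change in the harm rate
#'
#' The percentage of replicates in which the two-sided test of no change was
#' significant at `alpha_level`. Failed fits (too few events to test) count
#' as non-significant and stay in the denominator. Under a null scenario
#' (`reduction = 0`) this is the empirical type-I error rate and should sit
#' near `100 * alpha_level`. Adequate power is >= 80%.
#'
#' @inheritParams estimation_error
#' @param alpha_level Significance threshold, default 0.05.
#' @return Power in percent, over all replicates.
#' @export
detection_power <- function(fits, alpha_level = 0.05) {
  fits <- as_fit_frame(fits)
  if (nrow(fits) == 0) stop("no replicate fits supplied", call. = FALSE)
  sig <- !fits$failed & !is.na(fits$p_change) & fits$p_change < alpha_level
  100 * mean(sig)
}

#' Bias of the visit-1 harm rate estimate
#'
#' Signed relative bias of the typical estimate:
#' `100 * (median(rate_visit1) - baseline_rate) / baseline_rate` over the
#' non-failed fits. The naive Poisson estimator targets the population mean
#' rate, which under lognormal heterogeneity exceeds the median-patient rate
#' by a factor `exp((sd_patient^2 + sd_practice^2) / 2)` — about +30% at
#' patient MRR 2, and negligible at MRR 1.2.
#'
#' @inheritParams estimation_error
#' @return Bias in percent, or `NA` when every fit failed.
#' @export
rate_bias <- function(fits, spec) {
  assert_scenario(spec)
  fits <- as_fit_frame(fits)
  if (nrow(fits) == 0) stop("no replicate fits supplied", call. = FALSE)
  ok <- fits[!fits$failed, , drop = FALSE]
  if (nrow(ok) == 0) return(NA_real_)
  100 * (stats::median(ok$rate_visit1) - spec$baseline_rate) /
    spec$baseline_rate
}

#' Coverage of the visit-1 confidence interval
#'
#' The percentage of non-failed replicates whose visit-1 interval contains
#' the true baseline rate. Nominal coverage is the interval level (95% by
#' default); under strong inter-patient variation the estimator's bias drags
#' coverage materially below nominal.
#'
#' @inheritParams estimation_error
#' @return Coverage in percent, or `NA` when every fit failed.
#' @export
ci_coverage <- function(fits, spec) {
  assert_scenario(spec)
  fits <- as_fit_frame(fits)
  if (nrow(fits) == 0) stop("no replicate fits supplied", call. = FALSE)
  ok <- fits[!fits$failed, , drop = FALSE]
  if (nrow(ok) == 0) return(NA_real_)
  100 * mean(ok$lower <= spec$baseline_rate & spec$baseline_rate <= ok$upper)
}

#' Aggregate replicate fits into a scenario summary
#'
#' Assembles all scenario-level metrics — estimation error, power, bias,
#' coverage, failure fraction, the median visit-1 rate estimate — together
#' with the expected incident counts from the planning formula. Percentages
#' are kept at full precision here; rounding to match tabular presentation is
#' left to the output layer ([run_grid()]).
#'
#' @inheritParams estimation_error
#' @param alpha_level Significance threshold for the change test.
#' @return An object of class `crr_summary` (a list; see [run_scenario()]).
#' @export
summarize_scenario <- function(fits, spec, alpha_level = 0.05,
                               denominator = c("true_rate", "median_estimate")) {
  denominator <- match.arg(denominator)
  assert_scenario(spec)
  fits <- as_fit_frame(fits)
  if (nrow(fits) == 0) stop("no replicate fits supplied", call. = FALSE)
  ok <- fits[!fits$failed, , drop = FALSE]
  plan <- expected_incidents(spec)
  out <- list(
    spec = spec,
    replicates = nrow(fits),
    failed_fraction = mean(fits$failed),
    estimation_error_pct = estimation_error(fits, spec, denominator),
    power_pct = detection_power(fits, alpha_level),
    bias_pct = rate_bias(fits, spec),
    coverage_pct = ci_coverage(fits, spec),
    median_rate_estimate = if (nrow(ok)) stats::median(ok$rate_visit1)
                           else NA_real_,
    expected_incidents_visit1 = plan$expected_incidents_visit1,
    expected_incidents_total = plan$expected_incidents_total,
    alpha_level = alpha_level,
    error_denominator = denominator
  )
  class(out) <- "crr_summary"
  out
}

#' @export
print.crr_summary <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "CRR scenario summary (%d replicates)\n", x$replicates))
  cat(sprintf(
    "  design: %d practices x %d records, rate %g/100 patients/year, reduction %g%%, MRR %g/%g\n",
    s$n_practices, s$records_per_practice, s$baseline_rate,
    100 * s$reduction, s$mrr_patient, s$mrr_practice))
  cat(sprintf("  expected incidents: %.1f (visit 1), %.1f (total)\n",
              x$expected_incidents_visit1, x$expected_incidents_total))
  fmt <- function(v) if (is.na(v)) "suppressed" else sprintf("%.1f", v)
  cat(sprintf("  estimation error: %s%%   power: %.1f%%\n",
              fmt(x$estimation_error_pct), x$power_pct))
  cat(sprintf("  bias: %s%%   coverage: %s%%   failed fits: %.1f%%\n",
              fmt(x$bias_pct), fmt(x$coverage_pct),
              100 * x$failed_fraction))
  cat(sprintf("  median visit-1 rate estimate: %s\n",
              fmt(x$median_rate_estimate)))
  invisible(x)
}
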