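#' Fit the Poisson rate model to a review dataset
#'
#' The analysis model is a log-linear Poisson rate model with an intercept, a
#' visit indicator and the review window as an exposure offset:
#' `count ~ Poisson(exp(offset(log(exposure)) + alpha + beta * visit))`.
#' It deliberately ignores the patient- and practice-level random effects: at
#' the event counts typical of record review, mixed-model variance components
#' are not estimable, so harm rates are estimated with the plain GLM and the
#' resulting upward bias is quantified separately (see [rate_bias()]).
#'
#' Because the model has one parameter per visit, it is saturated on the
#' per-visit event totals and the maximum-likelihood fit has closed form:
#' with `E_k` the total events and `T_k` the total exposure at visit `k`,
#' \deqn{\hat\alpha = \log(E_1/T_1),\quad
#'       \hat\beta = \log(E_2/T_2) - \log(E_1/T_1),}
#' \deqn{se(\hat\alpha) = 1/\sqrt{E_1},\quad
#'       se(\hat\beta) = \sqrt{1/E_1 + 1/E_2}.}
#' An iterative fitter (e.g. `stats::glm`) agrees with these to numerical
#' precision; the closed form is what this function computes.
#'
#' A fit fails when any visit has zero events (the MLE is on the boundary and
#' no interval or test is available): `failed = TRUE` with
#' `failure_reason = "zero_events_visit"`, and no estimates are emitted.
#' Downstream, failed fits count as non-significant for power and are
#' excluded from interval medians.
#'
#' @param data A `crr_dataset` from [simulate_dataset()], or any data frame
#'   with columns `visit`, `exposure_years`, `count`.
#' @param ci_level Confidence level for the Wald intervals, default 0.95.
#'   Intervals are computed on the log scale and back-transformed, so they
#'   are asymmetric on the rate scale.
#' @return An object of class `crr_fit`: a list with `alpha_hat`, `beta_hat`,
#'   `se_alpha`, `se_beta`, `rate_visit1` (incidents/100 patient-years) with
#'   `lower`/`upper` limits, `p_change` (two-sided Wald test of `beta = 0`),
#'   `events` and `exposure` per visit, `ci_level`, `failed`,
#'   `failure_reason` (one of `"none"`, `"zero_events_visit"`,
#'   `"nonconvergence"`).
#' @examples
#' d <- simulate_dataset(scenario_spec(10, 200, 20, reduction = 0.5), seed = 1)
#' fit_rate_model(d)
#' @export
fit_rate_model <- function(data, ci_level = 0.95) {
  stopifnot(is.data.frame(data),
            all(c("visit", "exposure_years", "count") %in% names(data)),
            ci_level > 0, ci_level < 1)
  visits <- sort(unique(data$visit))
  events <- vapply(visits, function(v) sum(data$count[data$visit == v]),
                   numeric(1))
  exposure <- vapply(visits,
                     function(v) sum(data$exposure_years[data$visit == v]),
                     numeric(1))
  fit_from_totals(events, exposure, ci_level = ci_level)
}

# Closed-form MLE from per-visit totals (the sufficient statistics).
fit_from_totals <- function(events, exposure, ci_level = 0.95) {
  stopifnot(length(events) == length(exposure), length(events) %in% 1:2,
            all(exposure > 0))
  two <- length(events) == 2L
  if (any(events == 0)) {
    return(structure(list(
      alpha_hat = NA_real_, beta_hat = NA_real_,
      se_alpha = NA_real_, se_beta = NA_real_,
      rate_visit1 = NA_real_, lower = NA_real_, upper = NA_real_,
      p_change = NA_real_, events = events, exposure = exposure,
      ci_level = ci_level, failed = TRUE,
      failure_reason = "zero_events_visit"), class = "crr_fit"))
  }
  alpha <- log(events[1] / exposure[1])
  se_a <- 1 / sqrt(events[1])
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (two) {
    beta <- log(events[2] / exposure[2]) - alpha
    se_b <- sqrt(1 / events[1] + 1 / events[2])
    p <- 2 * stats::pnorm(-abs(beta / se_b))
    if (p == 0) p <- .Machine$double.xmin  # p_change in (0, 1]
  } else {
    beta <- NA_real_
    se_b <- NA_real_
    p <- NA_real_
  }
  structure(list(
    alpha_hat = alpha, beta_hat = beta, se_alpha = se_a, se_beta = se_b,
    rate_visit1 = 100 * exp(alpha),
    lower = 100 * exp(alpha - z * se_a),
    upper = 100 * exp(alpha + z * se_a),
    p_change = p, events = events, exposure = exposure,
    ci_level = ci_level, failed = FALSE, failure_reason = "none"),
    class = "crr_fit")
}

#' @export
print.crr_fit <- function(x, ...) {
  cat("Poisson rate model fit\n")
  if (x$failed) {
    cat(sprintf("  FAILED (%s); events per visit: %s\n", x$failure_reason,
                paste(x$events, collapse = ", ")))
    return(invisible(x))
  }
  cat(sprintf("  visit-1 rate: %.2f (%g%% CI %.2f-%.2f) incidents/100 patient-years\n",
              x$rate_visit1, 100 * x$ci_level, x$lower, x$upper))
  if (!is.na(x$beta_hat)) {
    cat(sprintf("  change: rate ratio %.3f (beta %.4f, se %.4f), p = %.3g\n",
                exp(x$beta_hat), x$beta_hat, x$se_beta, x$p_change))
  }
  invisible(x)
}

#' Confidence limits for the visit-1 harm rate
#'
#' Extracts the back-transformed Wald limits of the first-visit rate, in
#' incidents per 100 patient-years. The limits are symmetric on the log
#' scale: `upper / estimate = estimate / lower`.
#'
#' @param fit A non-failed [fit_rate_model()] result.
#' @return Numeric vector `c(lower, upper)`.
#' @export
visit1_rate_ci <- function(fit) {
  stopifnot(inherits(fit, "crr_fit"))
  if (fit$failed)
    stop("no estimates: the fit failed (", fit$failure_reason, ")",
         call. = FALSE)
  c(lower = fit$lower, upper = fit$upper)
}

#' Classify the test of no change in the harm rate
#'
#' Two-sided Wald z-test of the visit effect `beta`. A failed fit (too few
#' events to estimate the change) counts as non-significant by rule.
#'
#' @param fit A [fit_rate_model()] result (failed fits allowed).
#' @param alpha_level Significance threshold, default 0.05.
#' @return `TRUE` if the change is significant, `FALSE` otherwise.
#' @export
test_reduction <- function(fit, alpha_level = 0.05) {
  stopifnot(inherits(fit, "crr_fit"), alpha_level > 0, alpha_level < 1)
  !fit$failed && !is.na(fit$p_change) && fit$p_change < alpha_level
}

# Vectorised closed-form fits from matrices of per-replicate totals.
# Returns a data.frame, one row per replicate, used by run_scenario().
fit_totals_frame <- function(events1, events2, exposure1, exposure2,
                             ci_level = 0.95) {
  n <- length(events1)
  two <- !is.null(events2)
  failed <- events1 == 0
  if (two) failed <- failed | events2 == 0
  z <- stats::qnorm(1 - (1 - ci_level) / 2)

  alpha <- ifelse(failed, NA_real_, log(events1 / exposure1))
  se_a <- ifelse(failed, NA_real_, 1 / sqrt(events1))
  if (two) {
    beta <- ifelse(failed, NA_real_, log(events2 / exposure2) - alpha)
    se_b <- ifelse(failed, NA_real_, sqrt(1 / events1 + 1 / events2))
    p <- 2 * stats::pnorm(-abs(beta / se_b))
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  } else {
    beta <- se_b <- p <- rep(NA_real_, n)
  }
  data.frame(
    replicate = seq_len(n),
    events_visit1 = events1,
    events_visit2 = if (two) events2 else NA_integer_,
    alpha_hat = alpha, beta_hat = beta, se_alpha = se_a, se_beta = se_b,
    rate_visit1 = 100 * exp(alpha),
    lower = 100 * exp(alpha - z * se_a),
    upper = 100 * exp(alpha + z * se_a),
    p_change = p,
    failed = failed,
    failure_reason = ifelse(failed, "zero_events_visit", "none")
  )
}

# Normalise fits input for the metrics functions: either the data.frame from
# run_scenario(..., keep_fits = TRUE) or a list of crr_fit objects.
as_fit_frame <- function(fits) {
  if (is.data.frame(fits)) return(fits)
  if (is.list(fits) && all(vapply(fits, inherits, logical(1), "crr_fit"))) {
    if (length(fits) == 0) stop("empty fit list", call. = FALSE)
    return(do.call(rbind, lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      data.frame(replicate = i,
                 events_visit1 = f$events[1],
                 events_visit2 = if (length(f$events) > 1) f$events[2] else NA_integer_,
                 alpha_hat = f$alpha_hat, beta_hat = f$beta_hat,
                 se_alpha = f$se_alpha, se_beta = f$se_beta,
                 rate_visit1 = f$rate_visit1, lower = f$lower, upper = f$upper,
                 p_change = f$p_change, failed = f$failed,
                 failure_reason = f$failure_reason)
    })))
  }
  stop("`fits` must be a data frame of replicate fits or a list of crr_fit objects",
       call. = FALSE)
}
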