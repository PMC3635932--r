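#' Define a clinical record review (CRR) scenario
#'
#' A scenario is one design point for harm-rate monitoring by record review:
#' how many practices take part, how many unique patient records each reviews
#' at each visit, the true baseline harm rate of the sampled population, the
#' real reduction in that rate over the monitoring period, and the amount of
#' between-patient and between-practice heterogeneity.
#'
#' The baseline rate is anchored as the rate of a *median* patient in a
#' *median* practice (both random effects zero), in incidents per 100 patients
#' per year. The fixed effect of time is `beta = log(1 - reduction)`, applied
#' at the second review visit.
#'
#' @param n_practices Number of practices conducting the review (>= 1).
#' @param records_per_practice Number of unique patient records reviewed by
#'   each practice at each visit (>= 1).
#' @param baseline_rate True baseline harm rate, incidents per 100 patients
#'   per year.
#' @param reduction Real fractional reduction in the harm rate over the
#'   monitoring period, in `[0, 1)`. `0` is the null (no-change) scenario.
#' @param mrr_patient Median rate ratio between randomly sampled patients
#'   (>= 1). Default 2, a relatively harm-diverse population.
#' @param mrr_practice Median rate ratio between randomly sampled practices
#'   (>= 1). Default 1.2.
#' @param review_window_years Period of record time reviewed per record at
#'   each visit, in years. Default 0.25 (three calendar months).
#' @param n_visits Number of review visits, 1 or 2. Default 2 (beginning and
#'   end of a 12-month monitoring period).
#' @param same_patients Are the same patient records reviewed at both visits
#'   (shared random effects)? Default `TRUE`.
#' @return An object of class `crr_scenario` (a validated list of the above,
#'   plus the derived random-effect standard deviations `sd_patient`,
#'   `sd_practice` and fixed effect `beta`).
#' @examples
#' scenario_spec(n_practices = 10, records_per_practice = 200,
#'               baseline_rate = 20, reduction = 0.5)
#' @export
scenario_spec <- function(n_practices,
                          records_per_practice,
                          baseline_rate,
                          reduction = 0,
                          mrr_patient = 2,
                          mrr_practice = 1.2,
                          review_window_years = 0.25,
                          n_visits = 2,
                          same_patients = TRUE) {
  stopifnot(is.numeric(n_practices), length(n_practices) == 1L,
            is.numeric(records_per_practice), length(records_per_practice) == 1L,
            is.numeric(baseline_rate), length(baseline_rate) == 1L,
            is.numeric(reduction), length(reduction) == 1L,
            is.numeric(review_window_years), length(review_window_years) == 1L,
            is.logical(same_patients), length(same_patients) == 1L)
  if (n_practices < 1 || n_practices != round(n_practices))
    stop("`n_practices` must be a whole number >= 1", call. = FALSE)
  if (records_per_practice < 1 || records_per_practice != round(records_per_practice))
    stop("`records_per_practice` must be a whole number >= 1", call. = FALSE)
  if (baseline_rate < 0)
    stop("`baseline_rate` must be >= 0", call. = FALSE)
  if (reduction < 0 || reduction >= 1)
    stop("`reduction` must be in [0, 1)", call. = FALSE)
  if (review_window_years <= 0)
    stop("`review_window_years` must be > 0", call. = FALSE)
  if (!n_visits %in% c(1L, 2L))
    stop("`n_visits` must be 1 or 2", call. = FALSE)

  spec <- list(
    n_practices = as.integer(n_practices),
    records_per_practice = as.integer(records_per_practice),
    baseline_rate = as.numeric(baseline_rate),
    reduction = as.numeric(reduction),
    mrr_patient = as.numeric(mrr_patient),
    mrr_practice = as.numeric(mrr_practice),
    review_window_years = as.numeric(review_window_years),
    n_visits = as.integer(n_visits),
    same_patients = same_patients,
    sd_patient = mrr_to_sd(mrr_patient),
    sd_practice = mrr_to_sd(mrr_practice),
    beta = log(1 - reduction)
  )
  class(spec) <- "crr_scenario"
  spec
}

#' @export
print.crr_scenario <- function(x, ...) {
  cat("CRR scenario\n")
  cat(sprintf("  practices: %d, records/practice/visit: %d (total %d records)\n",
              x$n_practices, x$records_per_practice,
              x$n_practices * x$records_per_practice))
  cat(sprintf("  baseline rate: %g incidents/100 patients/year, reduction: %g%%\n",
              x$baseline_rate, 100 * x$reduction))
  cat(sprintf("  MRR patient: %g (sd %.4f), MRR practice: %g (sd %.4f)\n",
              x$mrr_patient, x$sd_patient, x$mrr_practice, x$sd_practice))
  cat(sprintf("  review window: %g years, visits: %d, same patients: %s\n",
              x$review_window_years, x$n_visits, x$same_patients))
  invisible(x)
}

is_crr_scenario <- function(x) inherits(x, "crr_scenario")

assert_scenario <- function(spec) {
  if (!is_crr_scenario(spec))
    stop("expected a `crr_scenario` object; see scenario_spec()", call. = FALSE)
  invisible(spec)
}
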