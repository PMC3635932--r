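#' Expected number of detected harm incidents for a review design
#'
#' The planning formula: the expected number of harm incidents detected at the
#' first review visit is
#' \deqn{E_1 = \frac{rHR}{100} \times w \times nRec \times nPrac,}
#' the baseline harm rate (incidents per 100 patients per year) times the
#' review window in years times the number of records per practice times the
#' number of practices. With a second visit the expectation there is
#' \eqn{E_1 (1 - R)} where `R` is the reduction, so the total over both visits
#' is \eqn{E_1 (2 - R)}. The formula is anchored on the baseline rate as
#' specified (the median-patient rate); no heterogeneity inflation factor is
#' applied.
#'
#' @param spec A [scenario_spec()] object.
#' @param target_incidents Optional planning target; when supplied, the result
#'   records whether the design meets it (on the `basis` scale) and, if not,
#'   how many records per practice would.
#' @param basis Which expectation the target applies to: `"visit1"` (incidents
#'   detected at the first visit) or `"total"` (across all visits).
#' @return An object of class `crr_planning`: a list with
#'   `expected_incidents_visit1`, `expected_incidents_total`, and — when a
#'   target was given — `min_records_per_practice` and `satisfied`.
#' @examples
#' # the benchmark design: 10 practices x 200 records at rate 20 -> 100 incidents
#' expected_incidents(scenario_spec(10, 200, 20))
#' @export
expected_incidents <- function(spec, target_incidents = NULL,
                               basis = c("visit1", "total")) {
  assert_scenario(spec)
  basis <- match.arg(basis)
  v1 <- spec$baseline_rate / 100 * spec$review_window_years *
    spec$records_per_practice * spec$n_practices
  mult <- visit_multiplier(spec$n_visits, spec$reduction)
  out <- list(expected_incidents_visit1 = v1,
              expected_incidents_total = v1 * mult,
              basis = basis)
  if (!is.null(target_incidents)) {
    out$target_incidents <- target_incidents
    out$min_records_per_practice <- plan_min_records(
      baseline_rate = spec$baseline_rate, n_practices = spec$n_practices,
      target_incidents = target_incidents,
      window_years = spec$review_window_years, basis = basis,
      reduction = spec$reduction, n_visits = spec$n_visits)
    achieved <- if (basis == "visit1") v1 else v1 * mult
    out$satisfied <- achieved >= target_incidents
  }
  class(out) <- "crr_planning"
  out
}

# Sum of per-visit rate multipliers: visit 1 contributes 1, visit 2 (1 - R).
visit_multiplier <- function(n_visits, reduction) {
  if (n_visits >= 2L) 1 + (1 - reduction) else 1
}

#' @export
print.crr_planning <- function(x, ...) {
  cat("CRR planning formula\n")
  cat(sprintf("  expected incidents, visit 1: %.2f\n",
              x$expected_incidents_visit1))
  cat(sprintf("  expected incidents, all visits: %.2f\n",
              x$expected_incidents_total))
  if (!is.null(x$target_incidents)) {
    cat(sprintf("  target (%s basis): %g -> %s; minimum records/practice: %s\n",
                x$basis, x$target_incidents,
                if (isTRUE(x$satisfied)) "met" else "NOT met",
                format(x$min_records_per_practice)))
  }
  invisible(x)
}

#' Minimum records per practice needed to reach a target incident count
#'
#' Inverts the planning formula of [expected_incidents()]: the smallest whole
#' number of records each practice must review so that the expected number of
#' detected harm incidents (at the first visit, or in total across visits)
#' reaches the target. Rounds up, since the target is a minimum.
#'
#' @param baseline_rate True baseline harm rate, incidents per 100 patients
#'   per year (> 0 unless the target is 0).
#' @param n_practices Number of practices reviewing records.
#' @param target_incidents Required expected number of detected harm
#'   incidents. Common targets: 100 for acceptable precision (estimation error
#'   below ±25%) and for adequate power against a >= 50% reduction; 500 for
#'   adequate power against a 20% reduction (see [planning_targets()]).
#' @param window_years Review window per record per visit, years.
#' @param basis `"visit1"` or `"total"`; which expectation must reach the
#'   target.
#' @param reduction Fractional rate reduction applied at the second visit
#'   (only used for the `"total"` basis).
#' @param n_visits Number of review visits (1 or 2).
#' @return Smallest integer number of records per practice meeting the target.
#' @examples
#' # a single practice needs 2000 records for 100 expected incidents at rate 20
#' plan_min_records(baseline_rate = 20, n_practices = 1, target_incidents = 100)
#' @export
plan_min_records <- function(baseline_rate, n_practices = 1,
                             target_incidents = 100, window_years = 0.25,
                             basis = c("visit1", "total"), reduction = 0,
                             n_visits = 2) {
  basis <- match.arg(basis)
  stopifnot(n_practices >= 1, target_incidents >= 0, window_years > 0,
            reduction >= 0, reduction < 1)
  if (target_incidents == 0) return(0L)
  if (baseline_rate <= 0)
    stop("infeasible design: zero baseline rate cannot yield incidents",
         call. = FALSE)
  per_record <- baseline_rate / 100 * window_years * n_practices
  if (basis == "total")
    per_record <- per_record * visit_multiplier(n_visits, reduction)
  as.integer(ceiling(target_incidents / per_record - 1e-9))
}

#' Planning targets for expected detected harm incidents
#'
#' Minimum expected numbers of detected harm incidents for a review design to
#' deliver, respectively: acceptable precision (estimation error below ±25%),
#' adequate (>= 80%) power against a reduction of 50% or more, and adequate
#' power against a 20% reduction. The 20%-reduction target is the planning
#' value of 500; simulated power boundaries put it nearer 600, so treat 500 as
#' the optimistic end of that band.
#'
#' @return Named numeric vector with elements `precision`, `reduction_50`,
#'   `reduction_20`.
#' @export
planning_targets <- function() {
  c(precision = 100, reduction_50 = 100, reduction_20 = 500)
}
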