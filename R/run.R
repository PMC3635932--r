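#' Run one CRR scenario: simulate, fit, summarise
#'
#' Generates `replicates` independent datasets from the scenario, fits the
#' Poisson rate model to each, and aggregates the fits with
#' [summarize_scenario()]. Output is fully determined by
#' `(spec, replicates, seed, settings)`.
#'
#' Two simulation engines are available. `method = "totals"` (default) draws
#' the random effects per replicate and then simulates the per-visit *event
#' totals* directly: conditional on the effects the row counts are
#' independent Poissons, so their total is Poisson with the summed mean, and
#' the analysis model depends on the data only through these totals. This is
#' distributionally identical to materialising every row, at a fraction of
#' the cost. `method = "full"` materialises each dataset row by row with
#' [simulate_dataset()] and fits with [fit_rate_model()]; it is the slower
#' reference path the totals engine is validated against.
#'
#' @param spec A [scenario_spec()] object.
#' @param replicates Number of simulated datasets, default 1000.
#' @param seed Integer seed; set once, so the run is reproducible.
#' @param alpha_level Significance threshold for the change test.
#' @param ci_level Confidence level for rate intervals.
#' @param error_denominator Denominator convention for [estimation_error()].
#' @param method `"totals"` or `"full"` (see Details).
#' @param keep_fits Also return the replicate-level fit table (component
#'   `fits` of the result)?
#' @return A `crr_summary` (see [summarize_scenario()]); with
#'   `keep_fits = TRUE` it carries the per-replicate fit data frame in
#'   `$fits`.
#' @examples
#' run_scenario(scenario_spec(10, 50, 20, reduction = 0.5),
#'              replicates = 100, seed = 1)
#' @export
run_scenario <- function(spec, replicates = 1000, seed = NULL,
                         alpha_level = 0.05, ci_level = 0.95,
                         error_denominator = c("true_rate", "median_estimate"),
                         method = c("totals", "full"), keep_fits = FALSE) {
  assert_scenario(spec)
  method <- match.arg(method)
  error_denominator <- match.arg(error_denominator)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)

  exposure <- spec$n_practices * spec$records_per_practice *
    spec$review_window_years
  fits <- if (method == "totals") {
    totals <- simulate_visit_totals(spec, replicates)
    fit_totals_frame(totals[, 1L],
                     if (spec$n_visits == 2L) totals[, 2L] else NULL,
                     exposure, exposure, ci_level = ci_level)
  } else {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      f <- fit_totals_frame_from_fit(
        fit_rate_model(simulate_dataset(spec), ci_level = ci_level))
      f$replicate <- r
      f
    }))
  }
  out <- summarize_scenario(fits, spec, alpha_level = alpha_level,
                            denominator = error_denominator)
  out$seed <- seed
  if (keep_fits) out$fits <- fits
  out
}

# One-row data.frame view of a single crr_fit (keeps run_scenario's two
# engines on one schema).
fit_totals_frame_from_fit <- function(f) {
  data.frame(replicate = 1L,
             events_visit1 = f$events[1],
             events_visit2 = if (length(f$events) > 1) f$events[2] else NA_integer_,
             alpha_hat = f$alpha_hat, beta_hat = f$beta_hat,
             se_alpha = f$se_alpha, se_beta = f$se_beta,
             rate_visit1 = f$rate_visit1, lower = f$lower, upper = f$upper,
             p_change = f$p_change, failed = f$failed,
             failure_reason = f$failure_reason)
}

#' Run a grid of CRR scenarios
#'
#' Runs [run_scenario()] for every scenario in a list or preset and returns
#' one summary row per scenario. Per-scenario seeds are derived
#' deterministically from `seed`, so any row can be reproduced in isolation
#' by re-running its scenario with the seed recorded in its row.
#'
#' @param scenarios A list of [scenario_spec()] objects, or a preset name for
#'   [scenario_grid()].
#' @param replicates Replicates per scenario.
#' @param seed Master seed for the grid.
#' @param out Optional path; when given, the result is also written as a CSV
#'   (header row, UTF-8). Percent columns appear both at full precision and
#'   rounded to integer (`*_rounded`), matching tabular presentation.
#' @param verbose Print a one-line progress log per scenario?
#' @inheritParams run_scenario
#' @return A data frame, one row per scenario, with columns `n_practices`,
#'   `records_per_practice`, `total_reviews`, `rhr`, `reduction_pct`,
#'   `mrr_patient`, `mrr_practice`, `replicates`, `failed_fraction`,
#'   `estimation_error_pct`, `power_pct`, `bias_pct`, `coverage_pct`,
#'   `expected_incidents_visit1`, `expected_incidents_total`, `seed` (plus
#'   rounded variants of the percent columns).
#' @export
run_grid <- function(scenarios, replicates = 1000, seed = 1,
                     alpha_level = 0.05, ci_level = 0.95,
                     error_denominator = c("true_rate", "median_estimate"),
                     out = NULL, verbose = FALSE) {
  if (is.character(scenarios)) scenarios <- scenario_grid(scenarios)
  stopifnot(is.list(scenarios),
            all(vapply(scenarios, is_crr_scenario, logical(1))))
  error_denominator <- match.arg(error_denominator)

  if (!is.null(out)) {
    # fail before computing anything if the path is unwritable
    ok <- tryCatch({ con <- file(out, open = "w"); close(con); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write to output path: ", out, call. = FALSE)
  }

  n <- length(scenarios)
  seeds <- if (n > 0) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  } else integer(0)

  rows <- lapply(seq_len(n), function(i) {
    t0 <- proc.time()[["elapsed"]]
    s <- run_scenario(scenarios[[i]], replicates = replicates,
                      seed = seeds[i], alpha_level = alpha_level,
                      ci_level = ci_level,
                      error_denominator = error_denominator)
    row <- summary_row(s, seeds[i])
    if (verbose) {
      message(sprintf(
        "[%d/%d] %dx%d rhr=%g R=%g%%: error=%s power=%s failed=%.1f%% (%.1fs)",
        i, n, row$n_practices, row$records_per_practice, row$rhr,
        row$reduction_pct,
        ifelse(is.na(row$estimation_error_pct), "NA",
               sprintf("%.1f", row$estimation_error_pct)),
        sprintf("%.1f", row$power_pct), 100 * row$failed_fraction,
        proc.time()[["elapsed"]] - t0))
    }
    row
  })
  res <- if (n > 0) do.call(rbind, rows) else empty_grid_frame()
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE,
                                      fileEncoding = "UTF-8")
  res
}

summary_row <- function(s, seed) {
  sp <- s$spec
  r <- data.frame(
    n_practices = sp$n_practices,
    records_per_practice = sp$records_per_practice,
    total_reviews = sp$n_practices * sp$records_per_practice * sp$n_visits,
    rhr = sp$baseline_rate,
    reduction_pct = 100 * sp$reduction,
    mrr_patient = sp$mrr_patient,
    mrr_practice = sp$mrr_practice,
    replicates = s$replicates,
    failed_fraction = s$failed_fraction,
    estimation_error_pct = s$estimation_error_pct,
    power_pct = s$power_pct,
    bias_pct = s$bias_pct,
    coverage_pct = s$coverage_pct,
    expected_incidents_visit1 = s$expected_incidents_visit1,
    expected_incidents_total = s$expected_incidents_total,
    seed = seed
  )
  r$estimation_error_pct_rounded <- round(r$estimation_error_pct)
  r$power_pct_rounded <- round(r$power_pct)
  r$bias_pct_rounded <- round(r$bias_pct)
  r$coverage_pct_rounded <- round(r$coverage_pct)
  r
}

empty_grid_frame <- function() {
  summary_row(structure(list(
    spec = scenario_spec(1, 1, 1), replicates = 0L, failed_fraction = NA_real_,
    estimation_error_pct = NA_real_, power_pct = NA_real_,
    bias_pct = NA_real_, coverage_pct = NA_real_,
    expected_incidents_visit1 = NA_real_, expected_incidents_total = NA_real_),
    class = "crr_summary"), NA_integer_)[0, ]
}
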