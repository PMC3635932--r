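#' Minimum total records for acceptable precision over a grid
#'
#' Given a grid of scenario summaries (from [run_grid()]), finds the smallest
#' total number of unique patient records (`n_practices x
#' records_per_practice`) among cells whose estimation error meets the
#' acceptable-precision threshold. Suppressed (NA) cells never qualify.
#'
#' @param grid A [run_grid()] data frame.
#' @param rhr Restrict to cells with this baseline rate (NULL = all).
#' @param threshold Acceptable-precision threshold in percent, default 25.
#' @return Smallest qualifying record total, or `NA` if no cell qualifies.
#' @export
min_records_for_precision <- function(grid, rhr = NULL, threshold = 25) {
  stopifnot(is.data.frame(grid),
            all(c("n_practices", "records_per_practice",
                  "estimation_error_pct") %in% names(grid)))
  if (!is.null(rhr)) grid <- grid[grid$rhr == rhr, , drop = FALSE]
  ok <- !is.na(grid$estimation_error_pct) &
    grid$estimation_error_pct <= threshold
  if (!any(ok)) return(NA_real_)
  min(grid$n_practices[ok] * grid$records_per_practice[ok])
}

#' Expected detected incidents at the adequate-power boundary
#'
#' For each baseline rate, sweeps the number of records per practice upward
#' until the simulated power to detect the given reduction first reaches the
#' adequate-power threshold, then converts that boundary design to its
#' expected *total* number of detected harm incidents (both visits, via the
#' planning formula). The minimum of these boundary incident counts across
#' baseline rates is the design rule of thumb: a review that expects at
#' least this many detected incidents has adequate power.
#'
#' Candidate record numbers are spaced about `incident_step` expected total
#' incidents apart between `incident_range[1]` and `incident_range[2]`;
#' since power is monotone in the number of records (up to Monte Carlo
#' noise), the first crossing is located by bisection over the ordered
#' candidates, costing ~log2(#candidates) simulated scenarios per rate.
#'
#' @param rhrs Baseline rates to sweep, incidents/100 patients/year.
#' @param reduction Fractional reduction to detect.
#' @param n_practices Practices in every swept design (the split of a given
#'   record total across practices barely moves power, which tracks expected
#'   incident counts; a fixed, fairly large value keeps the sweep stable).
#' @param replicates Replicates per swept design.
#' @param seed Integer seed.
#' @param power_threshold Adequate power, percent.
#' @param incident_range Range of expected total incidents to scan.
#' @param incident_step Spacing of candidates on the incident scale.
#' @param mrr_patient,mrr_practice Heterogeneity of the swept designs.
#' @param verbose Log each evaluated design?
#' @return A list with `per_rhr` (data frame: rhr, boundary records per
#'   practice, power there, expected total incidents) and `min_incidents`
#'   (minimum boundary incident count across rates; `NA` if the threshold was
#'   never reached inside the scanned range).
#' @export
power_boundary_incidents <- function(rhrs = c(2, 5, 10, 20),
                                     reduction = 0.2,
                                     n_practices = 100,
                                     replicates = 1000,
                                     seed = 1,
                                     power_threshold = 80,
                                     incident_range = c(300, 900),
                                     incident_step = 25,
                                     mrr_patient = 2, mrr_practice = 1.2,
                                     verbose = FALSE) {
  stopifnot(length(incident_range) == 2, incident_range[1] < incident_range[2],
            incident_step > 0)
  set.seed(seed)
  sweep_seeds <- sample.int(.Machine$integer.max - 1L, length(rhrs) * 64L)
  mult <- visit_multiplier(2L, reduction)

  per_rhr <- lapply(seq_along(rhrs), function(ri) {
    rhr <- rhrs[ri]
    per_record <- rhr / 100 * 0.25 * n_practices * mult
    targets <- seq(incident_range[1], incident_range[2], by = incident_step)
    cand <- sort(unique(pmax(1L, as.integer(ceiling(targets / per_record)))))

    eval_power <- function(idx, k) {
      sp <- scenario_spec(n_practices, cand[idx], rhr, reduction = reduction,
                          mrr_patient = mrr_patient,
                          mrr_practice = mrr_practice)
      s <- run_scenario(sp, replicates = replicates,
                        seed = sweep_seeds[(ri - 1L) * 64L + k])
      if (verbose)
        message(sprintf("rhr=%g records=%d power=%.1f%%",
                        rhr, cand[idx], s$power_pct))
      s$power_pct
    }

    # bisection for the first candidate reaching the threshold
    lo <- 1L; hi <- length(cand); k <- 1L
    p_hi <- eval_power(hi, k); k <- k + 1L
    if (p_hi < power_threshold) {
      return(data.frame(rhr = rhr, records_per_practice = NA_integer_,
                        power_pct = p_hi, expected_incidents_total = NA_real_))
    }
    p_lo <- eval_power(lo, k); k <- k + 1L
    if (p_lo >= power_threshold) {
      hi <- lo
      p_hi <- p_lo
    }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      p_mid <- eval_power(mid, k); k <- k + 1L
      if (p_mid >= power_threshold) {
        hi <- mid
        p_hi <- p_mid
      } else {
        lo <- mid
      }
    }
    data.frame(rhr = rhr, records_per_practice = cand[hi], power_pct = p_hi,
               expected_incidents_total = per_record * cand[hi])
  })
  per_rhr <- do.call(rbind, per_rhr)
  list(per_rhr = per_rhr,
       min_incidents = if (all(is.na(per_rhr$expected_incidents_total)))
         NA_real_ else min(per_rhr$expected_incidents_total, na.rm = TRUE))
}
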