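#' Draw patient- and practice-level random effects for a scenario
#'
#' Log-rate offsets: one per practice and one per patient (patients are nested
#' within practices and never shared across them). Effects are independent
#' normals with mean 0 and standard deviations implied by the scenario's
#' median rate ratios via [mrr_to_sd()]; an MRR of exactly 1 gives effects
#' that are exactly zero. With `same_patients = TRUE` (the default design) the
#' same effects apply at every visit.
#'
#' @param spec A [scenario_spec()] object.
#' @return A list of class `crr_effects` with `u_practice` (length
#'   `n_practices`) and `u_patient` (length `n_practices *
#'   records_per_practice`, ordered patient-within-practice).
#' @export
draw_random_effects <- function(spec) {
  assert_scenario(spec)
  n_prac <- spec$n_practices
  n_pat <- n_prac * spec$records_per_practice
  u_practice <- if (spec$sd_practice > 0) {
    stats::rnorm(n_prac, 0, spec$sd_practice)
  } else {
    rep(0, n_prac)
  }
  u_patient <- if (spec$sd_patient > 0) {
    stats::rnorm(n_pat, 0, spec$sd_patient)
  } else {
    rep(0, n_pat)
  }
  structure(list(u_practice = u_practice, u_patient = u_patient),
            class = "crr_effects")
}

#' Simulate one clinical record review dataset
#'
#' Generates harm-incident counts from the Poisson-lognormal model: the count
#' for patient `i` in practice `j` at visit `k` is Poisson with log mean
#' \deqn{\log \lambda_{ijk} = \log w + \alpha + \beta x_k + u_{1i} + u_{2j},}
#' where `w` is the review window (exposure, years),
#' `alpha = log(baseline_rate / 100)` is the log rate of a median patient in a
#' median practice (per patient-year), `beta = log(1 - reduction)` is the
#' fixed effect of time, `x` is 0 at the first visit and 1 at the second, and
#' `u1`, `u2` are the patient- and practice-level random effects. With
#' `same_patients = TRUE` the same records (and so the same random effects)
#' are reviewed at both visits, giving a paired design.
#'
#' @param spec A [scenario_spec()] object.
#' @param seed Optional integer seed, set before any draws for exact
#'   reproducibility.
#' @param effects Optional pre-drawn [draw_random_effects()] result; when
#'   `NULL`, effects are drawn here.
#' @return A data frame of class `crr_dataset` with one row per (practice,
#'   patient, visit): `practice_id`, `patient_id` (unique within practice),
#'   `visit` (0 = first review, 1 = second), `exposure_years`, `count`. The
#'   generating scenario, the seed and the random effects are attached as
#'   attributes `"spec"`, `"seed"`, `"random_effects"`.
#' @examples
#' d <- simulate_dataset(scenario_spec(2, 5, 20, reduction = 0.5), seed = 1)
#' head(d)
#' @export
simulate_dataset <- function(spec, seed = NULL, effects = NULL) {
  assert_scenario(spec)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effects)) effects <- draw_random_effects(spec)

  n_prac <- spec$n_practices
  n_rec <- spec$records_per_practice
  n_pat <- n_prac * n_rec
  w <- spec$review_window_years
  alpha <- log(spec$baseline_rate / 100)

  practice_id <- rep(seq_len(n_prac), each = n_rec)
  patient_id <- rep(seq_len(n_rec), times = n_prac)
  log_mu1 <- log(w) + alpha + effects$u_patient +
    effects$u_practice[practice_id]

  visits <- seq_len(spec$n_visits) - 1L
  rows <- lapply(visits, function(x) {
    eff <- if (x > 0L && !spec$same_patients) {
      e <- draw_random_effects(spec)
      log(w) + alpha + e$u_patient + e$u_practice[practice_id]
    } else {
      log_mu1
    }
    mu <- exp(eff + spec$beta * x)
    data.frame(practice_id = practice_id, patient_id = patient_id,
               visit = x, exposure_years = w,
               count = if (spec$baseline_rate > 0) stats::rpois(n_pat, mu)
                       else integer(n_pat))
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  attr(out, "random_effects") <- effects
  class(out) <- c("crr_dataset", "data.frame")
  out
}

#' Simulate a dataset under the null hypothesis of no change
#'
#' Identical to [simulate_dataset()] with the reduction forced to zero, so the
#' harm rate is the same at both visits. Used to validate the analysis
#' pipeline by checking its type-I error rate and interval coverage.
#'
#' @inheritParams simulate_dataset
#' @return A `crr_dataset`, as for [simulate_dataset()].
#' @export
simulate_null <- function(spec, seed = NULL, effects = NULL) {
  assert_scenario(spec)
  null_spec <- spec
  null_spec$reduction <- 0
  null_spec$beta <- 0
  simulate_dataset(null_spec, seed = seed, effects = effects)
}

# Per-visit total expected counts (conditional on effects) for one replicate
# chunk, vectorised over replicates. Returns a matrix n_reps x n_visits of
# conditional Poisson means for the visit totals. Exploits the nesting:
# Lambda_1 = (rate/100) * w * sum_j exp(u2j) * sum_{i in j} exp(u1i),
# Lambda_2 = Lambda_1 * (1 - reduction)   (same patients at both visits).
conditional_visit_means <- function(spec, n_reps) {
  n_prac <- spec$n_practices
  n_rec <- spec$records_per_practice
  base <- spec$baseline_rate / 100 * spec$review_window_years

  lambda1 <- if (spec$sd_patient > 0 || spec$sd_practice > 0) {
    prac_sums <- if (spec$sd_patient > 0) {
      colSums(matrix(exp(stats::rnorm(n_rec * n_prac * n_reps,
                                      0, spec$sd_patient)),
                     nrow = n_rec))
    } else {
      rep(n_rec, n_prac * n_reps)
    }
    if (spec$sd_practice > 0) {
      prac_sums <- prac_sums * exp(stats::rnorm(n_prac * n_reps,
                                                0, spec$sd_practice))
    }
    base * colSums(matrix(prac_sums, nrow = n_prac))
  } else {
    rep(base * n_rec * n_prac, n_reps)
  }

  if (spec$n_visits == 2L) {
    lambda2 <- if (spec$same_patients) {
      lambda1 * (1 - spec$reduction)
    } else {
      # independent records at visit 2: redraw the effects
      Recall(null_reduction(spec), n_reps)[, 1L] * (1 - spec$reduction)
    }
    cbind(lambda1, lambda2, deparse.level = 0)
  } else {
    cbind(lambda1, deparse.level = 0)
  }
}

null_reduction <- function(spec) {
  spec$reduction <- 0
  spec$beta <- 0
  spec$n_visits <- 1L
  spec
}

# Simulate the per-visit event totals for n_reps replicates in one call.
# The analysis model depends on the data only through these totals, and the
# total of independent Poisson counts is Poisson with the summed mean, so
# this is distributionally identical to summing a fully materialised dataset.
simulate_visit_totals <- function(spec, n_reps, chunk_elements = 2e7) {
  assert_scenario(spec)
  n_pat <- spec$n_practices * spec$records_per_practice
  chunk <- max(1L, as.integer(floor(chunk_elements / n_pat)))
  out <- matrix(0L, nrow = n_reps, ncol = spec$n_visits)
  done <- 0L
  while (done < n_reps) {
    k <- min(chunk, n_reps - done)
    mu <- conditional_visit_means(spec, k)
    for (v in seq_len(spec$n_visits)) {
      out[done + seq_len(k), v] <- stats::rpois(k, mu[, v])
    }
    done <- done + k
  }
  out
}
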