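# Shared fixtures: small scenarios used across test files.

# homogeneous population (no random effects)
spec_homogeneous <- function(...) {
  scenario_spec(n_practices = 10, records_per_practice = 200,
                baseline_rate = 20, mrr_patient = 1, mrr_practice = 1, ...)
}

# the benchmark heterogeneous design: 100 expected visit-1 incidents
spec_benchmark <- function(...) {
  scenario_spec(n_practices = 10, records_per_practice = 200,
                baseline_rate = 20, ...)
}

# build a replicate-fit frame directly (for metric rule tests)
make_fit_frame <- function(rate, lower, upper, p_change, failed = FALSE) {
  n <- max(length(rate), length(failed), length(p_change))
  data.frame(
    replicate = seq_len(n),
    events_visit1 = 100L, events_visit2 = 100L,
    alpha_hat = log(rate / 100), beta_hat = 0,
    se_alpha = 0.1, se_beta = 0.1,
    rate_visit1 = rate, lower = lower, upper = upper,
    p_change = p_change, failed = failed,
    failure_reason = ifelse(failed, "zero_events_visit", "none")
  )
}
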