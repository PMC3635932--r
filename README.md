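# crrsim

Monte Carlo assessment of the precision and statistical power of **clinical
record review (CRR)** designs for measuring and monitoring rates of patient
harm in general practice.

Harm rates in primary care are usually estimated by having clinicians review
samples of patient records (e.g. with trigger tools), and improvement
programmes repeat the review to look for a fall in the rate. Whether a given
design — `nPrac` practices each reviewing `nRec` unique records covering `w`
years of record time per record, twice over a monitoring period — can
deliver a usefully precise rate estimate, and enough power to detect a real
reduction `R`, is the question this package answers. It is aimed at health
services researchers, improvement leads and biostatisticians sizing harm
measurement programmes.

## The model

Harm-incident counts are simulated from a Poisson-lognormal mixed model

```
y_ijk ~ Poisson(lambda_ijk)
log lambda_ijk = log w + alpha + beta * x_ijk + u_1i + u_2j
```

for patient `i` in practice `j` at visit `k` (`x` = 0 first visit, 1
second), with `alpha = log(rHR/100)` anchoring the baseline harm rate `rHR`
(incidents per 100 patients per year) as the median-patient rate,
`beta = log(1 - R)` the fixed effect of time, and normal random effects
`u_1`, `u_2` whose spread is set by patient- and practice-level **median
rate ratios** via `MRR = exp(sqrt(2) * sigma * qnorm(0.75))`.

Each simulated dataset is analysed as a real review would be: a Poisson GLM
with a visit indicator and exposure offset (no random effects — they are not
estimable at review-scale event counts), which is saturated on the per-visit
event totals and so has a closed-form MLE. Replicates are aggregated into
**estimation error** (half the 95% CI width, in %; acceptable precision
< ±25%), **power** (% of replicates with a significant change test at
p < 0.05; adequate ≥ 80%), **bias** and **coverage**. A closed-form
planning formula — expected detected incidents
`= rHR/100 × w × nRec × nPrac` (visit 2 adds a `(1-R)` multiple) — ties the
whole grid together: ~100 expected incidents buys acceptable precision and
adequate power against a ≥ 50% reduction; ~500 buys power against a 20%
reduction.

## Worked example

Ten practices each review the same 200 records at the start and end of a
year, in a harm-prone population (`rHR` = 20/100 patients/year, patient MRR
2, practice MRR 1.2) where harm really halves:

```r
library(crrsim)
sp <- scenario_spec(n_practices = 10, records_per_practice = 200,
                    baseline_rate = 20, reduction = 0.5)
expected_incidents(sp)
#> CRR planning formula
#>   expected incidents, visit 1: 100.00
#>   expected incidents, all visits: 150.00
run_scenario(sp, replicates = 1000, seed = 42)
#> CRR scenario summary (1000 replicates)
#>   design: 10 practices x 200 records, rate 20/100 patients/year, reduction 50%, MRR 2/1.2
#>   expected incidents: 100.0 (visit 1), 150.0 (total)
#>   estimation error: 22.7%   power: 99.7%
#>   bias: 33.0%   coverage: 19.2%   failed fits: 0.0%
#>   median visit-1 rate estimate: 26.6
```

Reading the output: the design expects 100 detected incidents at the first
visit, which is exactly the benchmark for acceptable precision — and indeed
the estimation error is ~23%, under the ±25% bar. Power to detect the 50%
reduction is essentially 100%. But note the bias line: the naive Poisson
estimate of the baseline rate is typically 26.6 rather than 20, the ~33%
upward bias that strong inter-patient variation inflicts on an estimator
that cannot adjust for it — which is also why coverage of the nominal 95%
interval collapses. Precision and power goals can be met while the rate
itself is systematically overstated.

Planning shortcuts, without simulation:

```r
plan_min_records(baseline_rate = 20, n_practices = 1, target_incidents = 100)
#> [1] 2000
plan_min_records(baseline_rate = 5, n_practices = 50, target_incidents = 100)
#> [1] 150
```

Grids of scenarios (precision grid `"table2"`, power grid `"table3"`, full
864-scenario cross `"full"`) run with per-scenario derived seeds and CSV
output via `run_grid()`; a thin command-line front end with `plan`, `run`,
`grid` and `validate` subcommands lives at `inst/cli/crrsim.R`.

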