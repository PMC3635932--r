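---
title: "Precision and power of harm-rate monitoring by clinical record review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision and power of harm-rate monitoring by clinical record review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(crrsim)
```

## The problem

Clinical record review (CRR) — a clinician retrospectively reading a sample
of patient records for unintended harm — is the main way to estimate a harm
rate in general practice and to detect whether that rate falls after an
improvement effort. A review design is characterised by a handful of
parameters: how many practices take part, how many unique records each
reviews, how much record time is read per record, how often reviews are
repeated, and how harm-prone and heterogeneous the sampled population is.
Whether the resulting harm-rate estimate is usefully precise, and whether a
repeat review can statistically distinguish a real reduction from noise, is
a quantitative design question. `crrsim` answers it by Monte Carlo
simulation, and provides a closed-form planning shortcut that summarises the
simulation results.

Two performance definitions are used throughout:

* **Estimation error** (the proxy for precision): half the width of the 95%
  confidence interval of the harm-rate estimate, as a percentage.
  *Acceptable precision* is an estimation error below ±25%.
* **Power**: the probability that the test of "no change" is significant at
  the two-sided 5% level when the reduction is real. *Adequate power* is
  ≥ 80%.

## The generating model

Counts are generated from a Poisson-lognormal mixed model. The number of
harm incidents found in the records of patient $i$ in practice $j$ at visit
$k$ is

$$y_{ijk} \sim \mathrm{Pois}(\lambda_{ijk}), \qquad
  \log \lambda_{ijk} = \log w + \alpha + \beta x_{ijk} + u_{1i} + u_{2j},$$

where $w$ is the review window per record (0.25 years: three calendar
months), $x$ indicates the second visit, and $u_1 \sim N(0, \phi_1^2)$,
$u_2 \sim N(0, \phi_2^2)$ are patient- and practice-level random effects.
With the default paired design (`same_patients = TRUE`) the same records are
re-reviewed at the second visit, so the same effects apply at both visits.

**Heterogeneity is parameterised by median rate ratios (MRR)** — the median
rate ratio between two randomly sampled patients (or practices), always
expressed higher-over-lower so MRR ≥ 1. For lognormal effects the Larsen
identity links the MRR to the log-scale standard deviation:

$$\mathrm{MRR} = \exp\!\big(\sqrt{2}\,\sigma\,\Phi^{-1}(0.75)\big)
  \quad\Longleftrightarrow\quad
  \sigma = \frac{\log \mathrm{MRR}}{\sqrt{2}\,\Phi^{-1}(0.75)}.$$

```{r}
mrr_to_sd(2)    # a diverse patient population
mrr_to_sd(1.2)  # a relatively homogeneous one
```

This identity is verified in the test suite by brute force: the empirical
median of pairwise ratios of a million simulated lognormal rates equals the
nominal MRR.

**Anchoring of the baseline rate.** $\alpha = \log(r_{HR}/100)$, i.e. the
baseline harm rate $r_{HR}$ (incidents per 100 patients per year) is the
rate of a *median* patient in a *median* practice — the mean log harm rate,
with both random effects at zero. The *population mean* rate is higher by
$\exp((\phi_1^2+\phi_2^2)/2)$, about 33% at patient MRR 2 and practice MRR
1.2. This is deliberate and is what makes the naive estimator's bias (below)
an emergent property rather than an input.

**The fixed effect of time** is $\beta = \log(1 - R)$ for a real fractional
reduction $R$; $R = 0$ gives the null model used for type-I calibration.

## The analysis model

Each simulated dataset is analysed the way a real review would be: a Poisson
GLM with log link, intercept, visit indicator and $\log w$ offset —
*without* random effects. (At the event counts a record review yields,
mixed-model variance components are not estimable; the plain GLM is the
practical estimator, and its bias under heterogeneity is part of what the
simulation measures.) Since the model has one parameter per visit it is
saturated on the per-visit event totals $E_k$ (exposure $T_k$), and the MLE
is closed-form:

$$\hat\alpha = \log(E_1/T_1), \quad
  \hat\beta = \log(E_2/T_2) - \log(E_1/T_1), \quad
  \mathrm{se}(\hat\alpha) = 1/\sqrt{E_1}, \quad
  \mathrm{se}(\hat\beta) = \sqrt{1/E_1 + 1/E_2}.$$

`fit_rate_model()` computes exactly this; the test suite checks agreement
with `stats::glm` to 1e-8 on a thousand random inputs. Intervals are Wald
intervals on the log scale, back-transformed (asymmetric on the rate scale);
the change test is the two-sided Wald z-test of $\hat\beta$.

**Failed fits.** A replicate with zero events at either visit has its MLE on
the boundary: it is flagged (`failure_reason = "zero_events_visit"`) and
yields no estimates. For power, failures count as non-significant (they are
real outcomes of a real review that found too little to test); for
estimation error, failed fits are excluded from the median, and if ≥ 10% of
a scenario's fits fail the scenario's error is suppressed entirely (`NA`) —
such designs are far outside the acceptable region regardless.

## Replicate engine

`run_scenario()` simulates `replicates` datasets and aggregates the fits.
Its default engine (`method = "totals"`) draws the random effects for each
replicate and then simulates the per-visit event *totals* directly:
conditional on the effects, the row counts are independent Poissons, so
each visit total is Poisson with mean

$$\Lambda_1 = \frac{r_{HR}}{100}\, w \sum_j e^{u_{2j}} \sum_{i \in j} e^{u_{1i}},
  \qquad \Lambda_2 = (1-R)\,\Lambda_1 .$$

Because the analysis model sees the data only through these totals, the
engine is *distributionally identical* to materialising every row, at a
fraction of the cost — it is what makes a 54-cell grid at 1000 replicates a
one-minute computation. The row-level generator (`simulate_dataset()`,
`method = "full"`) remains the reference path; a test compares the two
engines' replicate distributions.

```{r}
s <- run_scenario(scenario_spec(10, 200, 20, reduction = 0.5),
                  replicates = 1000, seed = 42)
s
```

Note the three headline behaviours in that summary: estimation error ≈ 23%
(this is the 100-expected-incident benchmark design), essentially certain
detection of a 50% reduction, and a median estimate near 26.6 — the ~33%
upward bias of the naive estimator under patient MRR 2, with the coverage
collapse that implies.

## Scenario metrics

`summarize_scenario()` aggregates replicate fits into:

* `estimation_error_pct` = $100 \times 0.5 \times$ median CI width / $D$.
  The denominator $D$ is configurable: `"true_rate"` (the known $r_{HR}$,
  default) or `"median_estimate"` (the median visit-1 estimate). The two
  coincide for unbiased scenarios (MRR 1.2) and differ by the bias factor
  under MRR 2; the tabulated reference values for heterogeneous scenarios
  (23% at 100 expected incidents, 107% at ~6.6) are reproduced by the
  true-rate convention, which is therefore the default. Both ship because
  the two conventions answer slightly different questions ("how wide is the
  interval relative to the truth" vs "relative to what I will actually
  report").
* `power_pct` — share of replicates with a significant change test, failures
  in the denominator. Under the null this is the empirical type-I error.
* `bias_pct` — signed relative difference of the median visit-1 estimate
  from $r_{HR}$.
* `coverage_pct` — share of non-failed visit-1 intervals containing
  $r_{HR}$.

Precision metrics use the **visit-1 fit only** (they describe the baseline
estimate); power uses the joint two-visit fit. Percentages are kept at full
precision internally; `run_grid()` adds rounded companion columns for
table-style presentation. Medians over an even number of replicates use the
midpoint convention.

## The planning formula

Across the whole design grid, precision and power line up on a single
quantity: the expected number of detected harm incidents,

$$\mathbb{E}[\text{incidents, visit 1}] =
  \frac{r_{HR}}{100} \times w \times nRec \times nPrac,$$

with visit 2 contributing a further $(1-R)$ multiple. The working rules of
thumb, encoded in `planning_targets()`:

* ≥ **100** expected incidents → acceptable precision, and adequate power
  for reductions of 50% or more;
* ≥ **500** expected incidents → adequate power for a 20% reduction. (The
  simulated power boundary puts this nearer 600; 500 is the planning value,
  so treat it as the optimistic end of the band.)

The formula deliberately applies **no heterogeneity inflation**: it is
anchored on $r_{HR}$ as stated, matching how the reference values (100
incidents for the 10 × 200 design at $r_{HR}=20$) are quoted.
`plan_min_records()` inverts it, rounding up to whole records:

```{r}
# a single practice at rate 20 needs 2000 records for 100 expected incidents
plan_min_records(baseline_rate = 20, n_practices = 1, target_incidents = 100)
# ten practices share the burden
plan_min_records(baseline_rate = 20, n_practices = 10, target_incidents = 100)
```

`power_boundary_incidents()` closes the loop empirically: for each baseline
rate it sweeps record numbers upward (1000 replicates per design, bisection
over candidates spaced ~25 expected incidents apart between 300 and 900)
until power first reaches 80% for a 20% reduction, then converts the
boundary design to expected total incidents. The sweep fixes 100 practices
for every rate: power tracks the expected incident count, not its split
across practices — with the paired design the practice effects cancel from
the change estimate, so the split genuinely barely matters.

## Scenario grids

`scenario_grid()` builds the standard design spaces: `"table2"` (precision:
9 practice counts × 6 record counts × 4 rates at patient MRR 2, 216
scenarios), `"table3"` (power: the same cross × 2 reductions, with row
labels counting *total* reviews over both visits, so records per practice is
half the label — the convention that makes the single-practice worked
example and the 10-practice × 100-record power values line up), and
`"full"` (adds patient MRR 1.2; 864 scenarios). Grid runs derive
per-scenario seeds from one master seed and record them, so any row is
independently re-runnable.

## What the tests do and do not show

The acceptance-level tests reproduce, at 1000 replicates per scenario: the
~23% estimation error of three equal-incident designs (10 × 200 at rate 20,
50 × 150 at rate 5, 100 × 200 at rate 2); the single-practice power values
(~27% / ~7% for 50% / 20% reductions); ~93% power for 10 × 100 × 2 visits at
rate 20; the ~30% bias and ~26 median estimate at 20 × 100; the
2000-record precision minimum over the rate-20 grid; and a ~500-incident
80%-power boundary for 20% reductions. Monte Carlo tolerances at 1000
replicates are ±2 points for estimation error and ±3 for power and bias.
Problem sizes (1000 replicates, the 54-cell rate-20 grid, the four-rate
boundary sweep) are the package's standard working scale: large enough that
binomial noise is ~1.5 points, small enough to run interactively.

The generator emulates design-driven sampling variation only. Real record
review additionally faces imperfect and variable *detection* (reviewer
sensitivity, record quality), non-preventable harm mixed in with
preventable, drift in the patient panel between visits, and non-lognormal
frailty tails. None of these are modelled (reviewer variation can be
loosely absorbed into the practice MRR); simulated power and precision are
therefore best-case values, and real designs should be sized with margin.

## Known limitations and numerical notes

* At most two visits; trend detection over multiple time points is out of
  scope.
* All records share one review window; no per-patient exposure variation.
* The bias of the naive estimator under strong heterogeneity is reported,
  not corrected: the package's model-implied median bias at patient MRR 2 is
  ~32% against a conventional quoted value of ~30% — both carry
  ~±1-point Monte Carlo error at 1000 replicates, and the discrepancy is a
  property of the estimator, not adjustable without refitting the mixed
  model the data cannot support.
* Ties and even-length medians use R's default midpoint rule; planning
  inversion uses `ceiling` with a 1e-9 guard against floating-point
  boundary misses; p-values are floored at the smallest positive double so
  a valid fit never reports exactly zero.
* Reproducibility is guaranteed per `(scenario, replicates, seed, engine)`;
  the two engines consume randomness differently, so they match in
  distribution, not draw for draw.
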