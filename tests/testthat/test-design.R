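test_that("the planning formula gives the benchmark expected counts", {
  # 10 practices x 200 records x 0.25y at 20/100 patient-years -> 100 incidents
  p <- expected_incidents(spec_benchmark())
  expect_identical(p$expected_incidents_visit1, 100)

  # single practice, 6000 records, 20% reduction: 300 at visit 1, 540 in total
  p <- expected_incidents(scenario_spec(1, 6000, 20, reduction = 0.2))
  expect_equal(p$expected_incidents_visit1, 300)
  expect_equal(p$expected_incidents_total, 540)

  # a zero baseline rate yields no incidents at any visit
  p <- expected_incidents(scenario_spec(5, 100, 0))
  expect_identical(p$expected_incidents_visit1, 0)
  expect_identical(p$expected_incidents_total, 0)
})

test_that("expected incidents are linear in every design factor", {
  base <- scenario_spec(10, 100, 8, review_window_years = 0.25)
  v <- expected_incidents(base)$expected_incidents_visit1
  double <- list(
    scenario_spec(20, 100, 8, review_window_years = 0.25),
    scenario_spec(10, 200, 8, review_window_years = 0.25),
    scenario_spec(10, 100, 16, review_window_years = 0.25),
    scenario_spec(10, 100, 8, review_window_years = 0.5)
  )
  for (sp in double) {
    expect_identical(expected_incidents(sp)$expected_incidents_visit1, 2 * v)
  }
})

test_that("minimum record planning inverts the formula and rounds up", {
  # single practice at rate 20 needs 2000 records for 100 expected incidents
  expect_identical(plan_min_records(20, 1, 100), 2000L)
  expect_identical(plan_min_records(20, 10, 100), 200L)
  expect_identical(plan_min_records(20, 1, 0), 0L)
  expect_error(plan_min_records(0, 1, 100), "infeasible")

  # consistency: the planned count meets the target, one record fewer does not
  set.seed(99)
  for (i in 1:20) {
    rhr <- runif(1, 1, 25)
    npra <- sample(1:50, 1)
    target <- runif(1, 10, 500)
    basis <- sample(c("visit1", "total"), 1)
    red <- runif(1, 0, 0.6)
    n <- plan_min_records(rhr, npra, target, basis = basis, reduction = red)
    at <- function(k) {
      p <- expected_incidents(scenario_spec(npra, max(k, 1), rhr,
                                            reduction = red))
      if (basis == "visit1") p$expected_incidents_visit1
      else p$expected_incidents_total
    }
    expect_gte(at(n), target * (1 - 1e-9))
    if (n > 1) expect_lt(at(n - 1), target)
  }
})

test_that("planning targets carry the precision and power constants", {
  tg <- planning_targets()
  expect_identical(tg[["precision"]], 100)
  expect_identical(tg[["reduction_50"]], 100)
  expect_identical(tg[["reduction_20"]], 500)
})

test_that("scenario grids have the documented shape", {
  g2 <- scenario_grid("table2")
  expect_length(g2, 216)
  expect_true(all(vapply(g2, function(s) s$mrr_patient == 2, logical(1))))
  expect_true(all(vapply(g2, function(s) s$reduction == 0, logical(1))))

  g3 <- scenario_grid("table3")
  expect_length(g3, 432)
  # row labels are total reviews over two visits: half are unique records
  expect_setequal(unique(vapply(g3, function(s)
    s$records_per_practice * s$n_visits, numeric(1))) ,
    c(40, 50, 100, 200, 300, 400))

  expect_length(scenario_grid("full"), 864)
  gc <- scenario_grid("custom", n_practices = 3, records_per_practice = 7,
                      baseline_rate = 9)
  expect_length(gc, 1)
  expect_identical(gc[[1]]$records_per_practice, 7L)
  expect_error(scenario_grid("table9"))
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(scenario_spec(0, 10, 20), "n_practices")
  expect_error(scenario_spec(10, 10, 20, reduction = 1), "reduction")
  expect_error(scenario_spec(10, 10, 20, n_visits = 3), "n_visits")
  expect_error(scenario_spec(10, 10, 20, mrr_patient = 0.5), ">= 1")
})
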