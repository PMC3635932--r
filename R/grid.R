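#' Enumerate a grid of CRR scenarios
#'
#' Builds the standard scenario grids used throughout the package.
#'
#' * `"table2"` — the precision grid: practices \{1, 10, 20, 50, 100, 150,
#'   200, 250, 300\} crossed with records per practice \{20, 25, 50, 100,
#'   150, 200\} and baseline rates \{2, 5, 10, 20\}, at patient MRR 2 and
#'   practice MRR 1.2, no reduction (216 scenarios). Precision metrics use the
#'   first visit only, so the reduction value is immaterial; the null also
#'   makes this grid reusable for type-I calibration.
#' * `"table3"` — the power grid: the same practice counts crossed with
#'   *total* review counts \{40, 50, 100, 200, 300, 400\} (each unique record
#'   is reviewed twice, so records per practice is half the label), baseline
#'   rates \{2, 5, 10, 20\} and reductions \{50%, 20%\} (432 scenarios).
#' * `"full"` — the complete design space: 9 practice counts x 6 record
#'   counts x 4 baseline rates x 2 reductions x 2 patient MRRs \{1.2, 2\}
#'   (864 scenarios).
#' * `"custom"` — a single scenario assembled from `...` overrides to
#'   [scenario_spec()] defaults.
#'
#' @param preset One of `"table2"`, `"table3"`, `"full"`, `"custom"`.
#' @param ... Overrides passed to [scenario_spec()]. For the named presets,
#'   overrides replace the preset's fixed (non-crossed) parameters, e.g.
#'   `mrr_patient = 1.2` to build the low-heterogeneity variant of the
#'   precision grid.
#' @return A list of [scenario_spec()] objects.
#' @examples
#' length(scenario_grid("table2"))  # 216
#' length(scenario_grid("full"))    # 864
#' @export
scenario_grid <- function(preset = c("table2", "table3", "full", "custom"),
                          ...) {
  preset <- match.arg(preset)
  practices <- c(1, 10, 20, 50, 100, 150, 200, 250, 300)
  records <- c(20, 25, 50, 100, 150, 200)
  rates <- c(2, 5, 10, 20)
  overrides <- list(...)

  build <- function(grid_df, fixed) {
    lapply(seq_len(nrow(grid_df)), function(i) {
      args <- utils::modifyList(fixed, as.list(grid_df[i, , drop = FALSE]))
      do.call(scenario_spec, args)
    })
  }

  switch(preset,
    table2 = {
      grid_df <- expand.grid(n_practices = practices,
                             records_per_practice = records,
                             baseline_rate = rates)
      fixed <- utils::modifyList(
        list(reduction = 0, mrr_patient = 2, mrr_practice = 1.2), overrides)
      build(grid_df, fixed)
    },
    table3 = {
      grid_df <- expand.grid(n_practices = practices,
                             records_per_practice = records,
                             baseline_rate = rates,
                             reduction = c(0.5, 0.2))
      fixed <- utils::modifyList(
        list(mrr_patient = 2, mrr_practice = 1.2), overrides)
      build(grid_df, fixed)
    },
    full = {
      grid_df <- expand.grid(n_practices = practices,
                             records_per_practice = records,
                             baseline_rate = rates,
                             reduction = c(0.5, 0.2),
                             mrr_patient = c(1.2, 2))
      fixed <- utils::modifyList(list(mrr_practice = 1.2), overrides)
      build(grid_df, fixed)
    },
    custom = list(do.call(scenario_spec, overrides))
  )
}
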