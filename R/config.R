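#' Load and validate a run configuration
#'
#' Reads a JSON (or YAML, if the `yaml` package is available) configuration
#' describing what to run: either a `preset` name for [scenario_grid()] or an
#' explicit list of `scenarios` (each a set of [scenario_spec()] arguments),
#' plus run settings. Missing settings get defaults; unknown keys are
#' rejected so typos fail loudly.
#'
#' Recognised keys: `preset`, `scenarios`, `replicates` (default 1000),
#' `seed` (default 1), `alpha_level` (default 0.05), `ci_level` (default
#' 0.95), `error_denominator` (`"true_rate"` or `"median_estimate"`),
#' `output_path`.
#'
#' @param path Path to the configuration file.
#' @return A validated list of class `crr_config` with `scenarios` resolved
#'   to a list of `crr_scenario` objects and all settings filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the `yaml` package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(raw)
}

scenario_keys <- c("n_practices", "records_per_practice", "baseline_rate",
                   "reduction", "mrr_patient", "mrr_practice",
                   "review_window_years", "n_visits", "same_patients")
config_keys <- c("preset", "scenarios", "replicates", "seed", "alpha_level",
                 "ci_level", "error_denominator", "output_path")

validate_config <- function(raw) {
  stopifnot(is.list(raw))
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(
    list(replicates = 1000L, seed = 1L, alpha_level = 0.05, ci_level = 0.95,
         error_denominator = "true_rate", output_path = NULL),
    raw)

  num1 <- function(key, lo, hi, open = TRUE) {
    v <- cfg[[key]]
    bad <- !is.numeric(v) || length(v) != 1 || is.na(v) ||
      if (open) (v <= lo || v >= hi) else (v < lo || v > hi)
    if (bad) stop(sprintf("config field `%s` invalid: must be a number in %s%g, %g%s",
                          key, if (open) "(" else "[", lo, hi,
                          if (open) ")" else "]"), call. = FALSE)
    v
  }
  cfg$alpha_level <- num1("alpha_level", 0, 1)
  cfg$ci_level <- num1("ci_level", 0, 1)
  if (!is.numeric(cfg$replicates) || cfg$replicates < 1)
    stop("config field `replicates` invalid: must be >= 1", call. = FALSE)
  cfg$replicates <- as.integer(cfg$replicates)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config field `seed` invalid: must be an integer", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$error_denominator %in% c("true_rate", "median_estimate"))
    stop("config field `error_denominator` invalid: use \"true_rate\" or \"median_estimate\"",
         call. = FALSE)

  if (!is.null(raw$scenarios)) {
    scen_list <- raw$scenarios
    if (is.data.frame(scen_list))
      scen_list <- lapply(seq_len(nrow(scen_list)),
                          function(i) as.list(scen_list[i, , drop = FALSE]))
    cfg$scenarios <- lapply(scen_list, function(s) {
      unknown <- setdiff(names(s), scenario_keys)
      if (length(unknown) > 0)
        stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      do.call(scenario_spec, s[!vapply(s, is.null, logical(1))])
    })
    cfg$preset <- NULL
  } else if (!is.null(raw$preset)) {
    if (!raw$preset %in% c("table2", "table3", "full", "null"))
      stop("config field `preset` invalid: ", raw$preset, call. = FALSE)
    cfg$scenarios <- if (raw$preset == "null") {
      lapply(scenario_grid("table2"), function(s) {
        s$reduction <- 0; s$beta <- 0; s
      })
    } else {
      scenario_grid(raw$preset)
    }
  } else {
    stop("config must supply either `preset` or `scenarios`", call. = FALSE)
  }
  class(cfg) <- "crr_config"
  cfg
}

#' Execute a run configuration
#'
#' Convenience wrapper: [load_config()] (or an already-validated config)
#' followed by [run_grid()].
#'
#' @param config Path to a config file or a `crr_config` object.
#' @param verbose Per-scenario progress log?
#' @return The [run_grid()] data frame.
#' @export
run_config <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "crr_config"))
  run_grid(config$scenarios, replicates = config$replicates,
           seed = config$seed, alpha_level = config$alpha_level,
           ci_level = config$ci_level,
           error_denominator = config$error_denominator,
           out = config$output_path, verbose = verbose)
}
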