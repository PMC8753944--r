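# Reference results of the motivating case study, bundled as plain-text
# fixtures: the per-scenario optimization solutions (single- and
# multi-objective), the unoptimized benchmark, and the Tukey-grouped
# comparison of all scenarios and cases. They feed the consistency replay of
# the fuzzy weighted max-min arithmetic, the decision-guideline examples and
# the case-selection procedure.

frontflow_extdata <- function(file) {
  path <- system.file("extdata", file, package = "frontflow")
  if (path == "") {
    # during in-source development (pkgload), inst/ is not yet installed
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("bundled fixture not found: ", file, call. = FALSE)
  path
}

#' Reference optimization solutions per scenario
#'
#' For each routing scenario (1 dedicated, 2 one-stop, 3 partially shared):
#' the two single-objective solutions (cases 1-2) and the five
#' multi-objective solutions (cases 3-7), with their weights, reported
#' achievement level, operating cost (Baht/day) and mean satisfaction
#' (percent).
#'
#' @return data.frame with `scenario`, `case`, `w_cost`, `w_sat`, `lambda`,
#'   `z_cost`, `z_sat`.
#' @export
printed_optimization_results <- function() {
  utils::read.csv(frontflow_extdata("optimization_results.csv"))
}

#' Reference scenario comparison with Tukey grouping
#'
#' The full comparison of all scenarios and cases: per-row scenario, case,
#' satisfaction-objective weight, operating cost, replication count, mean
#' satisfaction and Tukey compact-letter group. Scenario 9 is the
#' unoptimized current situation used as the benchmark.
#'
#' @return data.frame with `nos`, `scenario`, `case`, `weight`, `cost`, `n`,
#'   `mean`, `letters`.
#' @export
printed_scenario_comparison <- function() {
  utils::read.csv(frontflow_extdata("scenario_comparison.csv"),
                  colClasses = c(letters = "character"))
}

#' The unoptimized benchmark operating point
#'
#' @return list with `cost` (Baht/day) and `sat` (percent).
#' @export
printed_benchmark <- function() {
  list(cost = 5296.5, sat = 85.81)
}

#' Replay the fuzzy weighted max-min arithmetic on the reference solutions
#'
#' For each scenario, takes the single-objective extremes as the fuzzy
#' normalization bounds, recomputes both memberships and the achievement
#' level for every multi-objective solution, and compares with the reported
#' level. One solution (scenario 2 with weights 0.8/0.2) is a known
#' inconsistency in the reference results: its satisfaction membership falls
#' below its weight, so the reported level of 1 cannot hold.
#'
#' @param results reference solutions, as from
#'   [printed_optimization_results()].
#' @param tol tolerance on the membership/level comparison (default 0.02,
#'   covering the rounding of the printed objective values).
#' @return data.frame with one row per multi-objective solution: memberships,
#'   recomputed `lambda`, reported `lambda_reported` and a `consistent` flag.
#' @export
fuzzy_replay <- function(results = printed_optimization_results(), tol = 0.02) {
  out <- list()
  for (sc in unique(results$scenario)) {
    rows <- results[results$scenario == sc, ]
    cost_run <- rows[rows$w_cost == 1, ]
    sat_run <- rows[rows$w_sat == 1, ]
    bounds <- bounds_from_single_objective(
      list(z_cost = cost_run$z_cost, z_sat = cost_run$z_sat),
      list(z_cost = sat_run$z_cost, z_sat = sat_run$z_sat))
    multi <- rows[rows$w_cost < 1 & rows$w_sat < 1, ]
    for (i in seq_len(nrow(multi))) {
      r <- multi[i, ]
      f_cost <- membership(r$z_cost, bounds$cost)
      f_sat <- membership(r$z_sat, bounds$sat)
      lam <- lambda_level(c(f_cost, f_sat), c(r$w_cost, r$w_sat))
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, case = r$case, w_cost = r$w_cost, w_sat = r$w_sat,
        f_cost = f_cost, f_sat = f_sat, lambda = lam,
        lambda_reported = r$lambda,
        consistent = abs(lam - r$lambda) <= tol)
    }
  }
  do.call(rbind, out)
}

#' Headline relative changes versus the benchmark
#'
#' The three summary percentages of the case study, recomputed from the
#' bundled comparison table: the cost saving of the cheapest case whose
#' satisfaction is statistically unchanged from the benchmark (shares a
#' Tukey letter), the maximum cost saving over all cases, and the maximum
#' satisfaction drop over all cases.
#'
#' @param comparison comparison table, as from
#'   [printed_scenario_comparison()].
#' @param benchmark benchmark point, as from [printed_benchmark()].
#' @return list with `same_sat_cost_saving_pct`, `max_cost_saving_pct`,
#'   `max_sat_drop_pct`.
#' @export
headline_changes <- function(comparison = printed_scenario_comparison(),
                             benchmark = printed_benchmark()) {
  rows <- comparison[comparison$scenario != 9, ]
  bletters <- strsplit(comparison$letters[comparison$scenario == 9], "")[[1]]
  shares <- vapply(rows$letters, function(l) {
    any(strsplit(l, "")[[1]] %in% bletters)
  }, logical(1))
  same_sat_cheaper <- rows[shares & rows$cost < benchmark$cost, ]
  list(
    same_sat_cost_saving_pct =
      100 * (benchmark$cost - min(same_sat_cheaper$cost)) / benchmark$cost,
    max_cost_saving_pct =
      100 * (benchmark$cost - min(rows$cost)) / benchmark$cost,
    max_sat_drop_pct =
      100 * (benchmark$sat - min(rows$mean)) / benchmark$sat
  )
}
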