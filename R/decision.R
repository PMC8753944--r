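# Decision guidelines: map the change in mean satisfaction and operating
# cost relative to the unoptimized benchmark onto one of nine
# recommendations, and the case-selection procedure over a Tukey-grouped
# comparison table.

#' Classify a scenario against the decision guidelines
#'
#' A total, deterministic lookup over the nine combinations of satisfaction
#' change and cost change versus the benchmark. Satisfaction "unchanged"
#' means sharing at least one Tukey letter with the benchmark row; cost is
#' deterministic, so its change is an exact comparison.
#'
#' @param sat_change `"higher"`, `"unchanged"` or `"lower"`.
#' @param cost_change `"higher"`, `"unchanged"` or `"lower"`.
#' @return list with `sat_change`, `cost_change`, `suggestion` (one of
#'   `"recommended"`, `"not_recommended"`, `"depends_on_decision_maker"`)
#'   and a `remark`.
#' @export
#' @examples
#' classify_decision("higher", "lower")$suggestion   # recommended
classify_decision <- function(sat_change, cost_change) {
  sat_change <- match.arg(sat_change, c("higher", "unchanged", "lower"))
  cost_change <- match.arg(cost_change, c("higher", "unchanged", "lower"))
  g <- decision_guidelines()
  row <- g[g$sat_change == sat_change & g$cost_change == cost_change, ]
  list(sat_change = sat_change, cost_change = cost_change,
       suggestion = row$suggestion, remark = row$remark)
}

#' The nine decision guidelines
#'
#' @return data.frame with `sat_change`, `cost_change`, `suggestion`,
#'   `remark`.
#' @export
decision_guidelines <- function() {
  data.frame(
    sat_change = rep(c("higher", "unchanged", "lower"), each = 3),
    cost_change = rep(c("higher", "unchanged", "lower"), times = 3),
    suggestion = c(
      "depends_on_decision_maker", "recommended", "recommended",
      "not_recommended", "depends_on_decision_maker", "recommended",
      "not_recommended", "not_recommended", "depends_on_decision_maker"
    ),
    remark = c(
      "Higher satisfaction; the extra cost may be acceptable",
      "Higher satisfaction at the same cost",
      "Higher satisfaction and a lower cost",
      "No change in satisfaction but the cost increases",
      "No change in either factor; consider other criteria (e.g. staff satisfaction)",
      "Same satisfaction at a lower cost",
      "Lower satisfaction and a higher cost",
      "Same cost but lower satisfaction",
      "Cheaper, but satisfaction drops; acceptable only within the decision-maker's tolerance"
    )
  )
}

#' Classify every row of a comparison table against the benchmark
#'
#' @param comparison data.frame with `scenario`, `case`, `cost`, `mean`,
#'   `letters` (a Tukey comparison table, e.g.
#'   [printed_scenario_comparison()]).
#' @param benchmark_scenario scenario id of the benchmark row.
#' @return `comparison` with `sat_change`, `cost_change` and `suggestion`
#'   columns added (benchmark row dropped).
#' @export
compare_to_benchmark <- function(comparison, benchmark_scenario = 9) {
  bench <- comparison[comparison$scenario == benchmark_scenario, ]
  if (nrow(bench) != 1L) {
    stop("compare_to_benchmark: need exactly one benchmark row", call. = FALSE)
  }
  rows <- comparison[comparison$scenario != benchmark_scenario, ]
  bletters <- strsplit(bench$letters, "")[[1]]
  rows$sat_change <- vapply(seq_len(nrow(rows)), function(i) {
    shared <- any(strsplit(rows$letters[i], "")[[1]] %in% bletters)
    if (shared) "unchanged" else if (rows$mean[i] > bench$mean) "higher" else "lower"
  }, character(1))
  rows$cost_change <- ifelse(rows$cost == bench$cost, "unchanged",
                             ifelse(rows$cost > bench$cost, "higher", "lower"))
  rows$suggestion <- vapply(seq_len(nrow(rows)), function(i) {
    classify_decision(rows$sat_change[i], rows$cost_change[i])$suggestion
  }, character(1))
  rows
}

#' Select the cheapest acceptable case
#'
#' The case-selection procedure over a Tukey-grouped comparison table:
#' locate the letter group whose range of means contains the decision-maker's
#' minimum acceptable score (or, if none does, the group with the nearest
#' greater score); take the cheapest case in that group; then, if any case
#' in a higher-scoring group is cheaper still, take the cheapest of those
#' instead.
#'
#' @param min_score minimum acceptable mean satisfaction, percent.
#' @param comparison comparison table with `scenario`, `case`, `cost`,
#'   `mean`, `letters`; a benchmark row (`scenario == benchmark_scenario`)
#'   is excluded from selection.
#' @param benchmark_scenario scenario id of the benchmark row (default 9).
#' @return the selected row of `comparison`, with a `via_group` attribute
#'   naming the anchor letter group.
#' @export
select_case <- function(min_score, comparison, benchmark_scenario = 9) {
  rows <- comparison[comparison$scenario != benchmark_scenario, ]
  if (min_score > max(rows$mean)) {
    stop("select_case: no feasible case; the minimum acceptable score ",
         min_score, " exceeds every mean satisfaction", call. = FALSE)
  }
  letters_used <- sort(unique(unlist(strsplit(rows$letters, ""))))
  ranges <- lapply(letters_used, function(L) {
    members <- grepl(L, rows$letters, fixed = TRUE)
    range(rows$mean[members])
  })
  names(ranges) <- letters_used
  containing <- letters_used[vapply(ranges, function(r) {
    r[1] <= min_score && min_score <= r[2]
  }, logical(1))]
  anchor <- if (length(containing) > 0) {
    # the lowest-scoring group containing the threshold
    containing[which.min(vapply(ranges[containing], min, numeric(1)))]
  } else {
    above <- letters_used[vapply(ranges, function(r) r[1] >= min_score, logical(1))]
    above[which.min(vapply(ranges[above], min, numeric(1)))]
  }
  members <- rows[grepl(anchor, rows$letters, fixed = TRUE), ]
  pick <- members[which.min(members$cost), ]
  higher <- rows[rows$mean > max(members$mean) &
                   !grepl(anchor, rows$letters, fixed = TRUE), ]
  cheaper <- higher[higher$cost < pick$cost, ]
  if (nrow(cheaper) > 0) pick <- cheaper[which.min(cheaper$cost), ]
  attr(pick, "via_group") <- anchor
  pick
}
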