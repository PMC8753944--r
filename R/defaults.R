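# Default model parameters for the motivating case study: the front-end
# department (triage + medical-record department, MRD) of a large Thai public
# university hospital. The queue-ticket machine opens at 05:00 and closes at
# 14:50; all clock times are stored internally as minutes since 05:00.

#' Clock-time helpers
#'
#' Configuration files give clock times as `"HH:MM"` strings; internally the
#' package uses minutes since the 05:00 ticket opening.
#'
#' @param x `"HH:MM"` string(s), or minutes for the inverse.
#' @return minutes since 05:00 (`clock_to_min`) or `"HH:MM"` (`min_to_clock`).
#' @export
clock_to_min <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("clock times must be 'HH:MM', got ", paste(p, collapse = ":"))
    as.numeric(p[1]) * 60 + as.numeric(p[2]) - 300
  }, numeric(1))
}

#' @rdname clock_to_min
#' @export
min_to_clock <- function(x) {
  m <- x + 300
  sprintf("%02d:%02d", m %/% 60, round(m %% 60))
}

#' Default arrival segments
#'
#' Interarrival-time model for the working day: an early trickle, a morning
#' peak, and a declining afternoon. Times are minutes since 05:00; the
#' interarrival law is `shift + Exponential(mean)`.
#'
#' @return data.frame with `start`, `end`, `shift`, `mean` (minutes).
#' @export
arrival_segments_default <- function() {
  data.frame(
    start = c(0, 60, 330),
    end   = c(60, 330, 600),
    shift = c(0, 0.5, 0),
    mean  = c(10, 1.24, 2.67)
  )
}

#' Default patient-type mix by time window
#'
#' Four patient types: (1) walk-ins without appointment, (2) university staff
#' and students, (3) non-registered privilege holders or profile changes,
#' (4) government-privilege patients (e.g. universal health coverage).
#' Types 1-2 pass blood pressure and triage before the medical-record
#' counter; types 3-4 go straight to the counter.
#'
#' @return data.frame with `start`, `end` (minutes since 05:00) and
#'   `p1`..`p4` summing to 1 per row.
#' @export
type_mix_default <- function() {
  data.frame(
    start = c(0, 120, 240, 360, 480),
    end   = c(120, 240, 360, 480, 600),
    p1 = c(0.36, 0.35, 0.27, 0.26, 0.26),
    p2 = c(0.10, 0.10, 0.09, 0.10, 0.10),
    p3 = c(0.08, 0.11, 0.10, 0.10, 0.10),
    p4 = c(0.46, 0.44, 0.54, 0.54, 0.54)
  )
}

#' Default station service-time specifications
#'
#' All parameters in seconds. Blood pressure measurement and the new-patient
#' information form are untimed self-service steps (constant duration, no
#' staffed server); triage is a staffed nurse station; the medical-record
#' counters have type-specific service laws.
#'
#' @return named list of [service_spec()] objects with elements
#'   `blood_pressure`, `triage`, `fill_info`, `mr_type1`..`mr_type4`.
#' @export
service_specs_default <- function() {
  list(
    blood_pressure = service_spec("blood_pressure", "constant", value = 49),
    triage = service_spec("triage", "shifted_exponential",
                          shift = 25, mean = 71.2),
    fill_info = service_spec("fill_info", "constant", value = 300),
    mr_type1 = service_spec("mr_type1", "shifted_weibull",
                            shift = 14, scale = 47.4, shape = 0.94),
    mr_type2 = service_spec("mr_type2", "shifted_weibull",
                            shift = 14, scale = 47.4, shape = 0.94),
    mr_type3 = service_spec("mr_type3", "triangular",
                            min = 84, mode = 146.8, max = 251),
    mr_type4 = service_spec("mr_type4", "triangular",
                            min = 59, mode = 72.8, max = 197)
  )
}

#' Default satisfaction profiles
#'
#' Expert-elicited triangular profiles relating length of stay (minutes) to a
#' satisfaction score (percent): optimistic / most-likely / pessimistic
#' values per patient type, elicited from the department chief and senior
#' nurses. LOS triples are increasing; score triples are decreasing (longer
#' stays mean lower satisfaction).
#'
#' @return list indexed by patient type, each with `los = c(opt, ml, pess)`
#'   minutes and `score = c(opt, ml, pess)` percent.
#' @export
satisfaction_profiles_default <- function() {
  score <- c(100, 75, 50)
  list(
    `1` = list(los = c(55, 90, 120), score = score),
    `2` = list(los = c(15, 30, 60), score = score),
    `3` = list(los = c(45, 70, 90), score = score),
    `4` = list(los = c(45, 70, 90), score = score)
  )
}

#' Default objective weight settings
#'
#' The five (cost weight, satisfaction weight) pairs used for the
#' multi-objective staffing optimization sensitivity analysis.
#'
#' @return data.frame with `w_cost`, `w_sat` (each pair sums to 1).
#' @export
weight_sets_default <- function() {
  data.frame(
    w_cost = c(0.8, 0.2, 0.6, 0.4, 0.5),
    w_sat  = c(0.2, 0.8, 0.4, 0.6, 0.5)
  )
}

# Resource kinds understood by schedules. N / N2 are triage nurses for
# patient types 1 / 2; M1..M4 are per-type medical-record counters; M12 is a
# counter kind shared by types 1-2 (appears in schedule accounting only);
# M is the pooled counter bank used by the one-stop policy.
resource_kinds <- function() c("N", "N2", "M", "M1", "M12", "M2", "M3", "M4")

mr_kinds <- function() c("M", "M1", "M12", "M2", "M3", "M4")

#' Default staffing schedule
#'
#' Staffing is scheduled over four two-hour periods (07-09, 09-11, 11-13,
#' 13-15); the 07-09 levels also apply to the 05:00-07:00 opening lull unless
#' a `05-07` column is supplied. The default levels are the one published
#' staffing row of the case study (six type-1 triage nurses, three type-2
#' nurses, counters 3/3/2/10 for types 1-4), held constant across periods.
#' Under the one-stop policy the per-type counters are pooled into a single
#' bank of equal total size.
#'
#' @param policy routing policy the schedule will serve.
#' @return integer matrix, rows = resource kinds, columns = periods.
#' @export
schedule_default <- function(policy = c("dedicated", "partial_shared", "one_stop")) {
  policy <- match.arg(policy)
  periods <- c("07-09", "09-11", "11-13", "13-15")
  kinds <- resource_kinds()
  n <- matrix(0L, nrow = length(kinds), ncol = length(periods),
              dimnames = list(kinds, periods))
  n["N", ] <- 6L
  n["N2", ] <- 3L
  if (policy == "one_stop") {
    n["M", ] <- 18L
  } else {
    n["M1", ] <- 3L
    n["M2", ] <- 3L
    n["M3", ] <- 2L
    n["M4", ] <- 10L
  }
  n
}

#' Default full model configuration
#'
#' Bundles the default arrival segments, type mix, service specifications,
#' satisfaction profiles, weight sets, policy, staffing schedule and run
#' parameters into one validated configuration object.
#'
#' @param policy medical-record routing policy.
#' @param p_new probability that a type-1/2 patient is new (fills the
#'   information form). Default 0: the verification anchor excludes the
#'   form-filling step, and the case study does not publish the new-patient
#'   share.
#' @return a validated `frontflow_config` object.
#' @export
default_config <- function(policy = c("dedicated", "one_stop", "partial_shared"),
                           p_new = 0) {
  policy <- match.arg(policy)
  cfg <- structure(list(
    arrivals = arrival_segments_default(),
    type_mix = type_mix_default(),
    services = service_specs_default(),
    satisfaction = satisfaction_profiles_default(),
    weights = weight_sets_default(),
    policy = policy,
    p_new = p_new,
    schedule = schedule_default(policy),
    ticket_close = 590,       # 14:50, minutes since 05:00
    min_run_length = 600,     # terminating check starts at 10 h
    hard_cap = 2000           # stuck-system diagnostic threshold, minutes
  ), class = "frontflow_config")
  validate_config(cfg)
}

#' @export
print.frontflow_config <- function(x, ...) {
  cat("<frontflow_config>\n")
  cat("  policy:", x$policy, "  p_new:", x$p_new, "\n")
  cat("  arrival segments:", nrow(x$arrivals),
      " | type-mix windows:", nrow(x$type_mix), "\n")
  cat("  schedule periods:", paste(colnames(x$schedule), collapse = ", "), "\n")
  active <- x$schedule[rowSums(x$schedule) > 0, , drop = FALSE]
  for (k in rownames(active)) {
    cat(sprintf("    %-4s %s\n", k, paste(active[k, ], collapse = " ")))
  }
  invisible(x)
}
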