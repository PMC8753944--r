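#' Station sequence for a patient
#'
#' Types 1 and 2 check blood pressure, are triaged by a nurse, fill the
#' information form if new, and then contact a medical-record counter; types
#' 3 and 4 contact the counter directly.
#'
#' @param type patient type in 1..4.
#' @param is_new logical; new patients (types 1-2 only) fill the information
#'   form.
#' @return character vector of station names, in visit order.
#' @export
#' @examples
#' flow_path(1, is_new = FALSE) # blood_pressure, triage, mr
#' flow_path(4, is_new = FALSE) # mr only
flow_path <- function(type, is_new = FALSE) {
  stopifnot(type %in% 1:4)
  if (type <= 2) {
    c("blood_pressure", "triage", if (is_new) "fill_info", "mr")
  } else {
    "mr"
  }
}

#' Route a patient to a medical-record pool
#'
#' Implements the three routing scenarios at the medical-record department
#' entrance:
#' * `dedicated` - the counter bank matching the patient's type, always;
#' * `one_stop` - the single pooled counter bank serving every type;
#' * `partial_shared` - the own-type bank if any of its servers is idle;
#'   otherwise the other counter type with an idle server and the lowest
#'   utilization (ties broken by lowest type index); if no allowed counter is
#'   idle, the patient queues at the own-type bank.
#'
#' @param policy `"dedicated"`, `"one_stop"` or `"partial_shared"`.
#' @param type patient type in 1..4.
#' @param pools named list of [resource_pool()] objects (`M` for one_stop,
#'   `M1`..`M4` otherwise).
#' @param now clock time, minutes (utilization is evaluated at the routing
#'   instant).
#' @return the chosen pool id, e.g. `"M3"`.
#' @export
route_mrd <- function(policy, type, pools, now) {
  policy <- match.arg(policy, c("dedicated", "one_stop", "partial_shared"))
  if (policy == "one_stop") {
    if (is.null(pools$M)) stop("one_stop policy needs pool 'M'", call. = FALSE)
    return("M")
  }
  own <- paste0("M", type)
  if (is.null(pools[[own]])) {
    stop("policy '", policy, "': no pool configured for patient type ", type,
         call. = FALSE)
  }
  if (policy == "dedicated") return(own)
  # partial_shared
  if (pools[[own]]$busy < current_capacity(pools[[own]], now)) return(own)
  others <- setdiff(paste0("M", 1:4), own)
  others <- others[vapply(others, function(k) !is.null(pools[[k]]), logical(1))]
  idle <- others[vapply(others, function(k) {
    pools[[k]]$busy < current_capacity(pools[[k]], now)
  }, logical(1))]
  if (length(idle) == 0L) return(own)
  util <- vapply(idle, function(k) pool_utilization(pools[[k]], now), numeric(1))
  idle[which.min(util)]  # which.min takes the first (lowest index) on ties
}

# Parse schedule period labels like "07-09" into start minutes since 05:00,
# and return the (breaks, capacity-columns) pair used by the pools. When the
# schedule has no 05-07 column, the first scheduled period's staffing applies
# from opening.
schedule_breaks <- function(schedule) {
  labs <- colnames(schedule)
  starts <- vapply(strsplit(labs, "-", fixed = TRUE), function(p) {
    as.numeric(p[1]) * 60 - 300
  }, numeric(1))
  o <- order(starts)
  starts <- starts[o]
  cols <- seq_along(labs)[o]
  if (starts[1] > 0) {
    starts <- c(0, starts)
    cols <- c(cols[1], cols)
  }
  list(breaks = starts, cols = cols)
}

# Build the staffed pools for a policy from a schedule matrix.
build_pools <- function(schedule, policy) {
  sb <- schedule_breaks(schedule)
  mk <- function(kind) {
    resource_pool(kind, capacity = schedule[kind, sb$cols], breaks = sb$breaks)
  }
  kinds <- c("N", "N2",
             if (policy == "one_stop") "M" else paste0("M", 1:4))
  pools <- lapply(kinds, mk)
  names(pools) <- kinds
  pools
}

#' Generate one day's arrivals
#'
#' Walks the clock from opening, drawing each interarrival time from the
#' segment containing the previous arrival instant; generation stops at the
#' ticket-close time, so no ticket is issued after it.
#'
#' @param cfg a `frontflow_config`.
#' @param streams substreams from [rng_substreams()] (uses `arrival`, `type`,
#'   `new`).
#' @return data.frame with `ticket_time` (minutes), `type`, `is_new`.
#' @export
generate_arrivals <- function(cfg, streams) {
  a <- cfg$arrivals[order(cfg$arrivals$start), ]
  t <- 0
  times <- numeric(0)
  repeat {
    seg <- a[findInterval(t, a$start), ]
    ia <- stream_eval(streams$arrival, function() sample_interarrival(seg, 1L))
    t <- t + ia
    if (t > cfg$ticket_close) break
    times[length(times) + 1L] <- t
  }
  if (length(times) == 0L) {
    return(data.frame(ticket_time = numeric(0), type = integer(0),
                      is_new = logical(0)))
  }
  types <- stream_eval(streams$type,
                       function() assign_patient_type(cfg$type_mix, times))
  is_new <- stream_eval(streams$new,
                        function() stats::runif(length(times)) < cfg$p_new)
  is_new <- is_new & types <= 2     # only types 1-2 have the form step
  data.frame(ticket_time = times, type = types, is_new = is_new)
}
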