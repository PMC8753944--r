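# Discrete-event simulation kernel: an event calendar ordered by
# (time, insertion sequence), and capacity-scheduled resource pools with FIFO
# waiting queues. State lives in environments so the pools and calendar have
# reference semantics inside the replication loop.

#' Create an empty event calendar
#'
#' Events are ordered by time, with insertion order breaking ties, so a
#' replication is a deterministic function of its seed.
#'
#' @return an `event_calendar` object (clock starts at 0 = 05:00).
#' @export
event_calendar <- function() {
  cal <- new.env(parent = emptyenv())
  cal$time <- numeric(0)
  cal$seq <- integer(0)
  cal$kind <- character(0)
  cal$payload <- list()
  cal$counter <- 0L
  cal$now <- 0
  class(cal) <- "event_calendar"
  cal
}

#' @export
print.event_calendar <- function(x, ...) {
  cat(sprintf("<event_calendar> now=%.3f min, %d pending event(s)\n",
              x$now, length(x$time)))
  invisible(x)
}

#' Schedule an event
#'
#' @param cal an [event_calendar()].
#' @param time event time, minutes; must not precede the clock (an event in
#'   the past signals a model bug).
#' @param kind event kind string.
#' @param payload arbitrary payload (e.g. a patient id).
#' @return the calendar, invisibly.
#' @export
push_event <- function(cal, time, kind, payload = NULL) {
  if (time < cal$now - 1e-12) {
    stop("push_event: event at t=", time, " is in the past (clock at ",
         cal$now, ") - model bug", call. = FALSE)
  }
  cal$counter <- cal$counter + 1L
  n <- length(cal$time) + 1L
  cal$time[n] <- time
  cal$seq[n] <- cal$counter
  cal$kind[n] <- kind
  cal$payload[[n]] <- if (is.null(payload)) NA else payload
  invisible(cal)
}

#' Pop the next event and advance the clock
#'
#' Returns the minimum-(time, seq) event and removes it from the calendar;
#' the clock advances to the event time. An empty calendar means the
#' simulation has ended.
#'
#' @param cal an [event_calendar()].
#' @return a list with `time`, `seq`, `kind`, `payload`, or `NULL` when the
#'   calendar is empty.
#' @export
pop_next <- function(cal) {
  if (length(cal$time) == 0L) return(NULL)
  cand <- which(cal$time == min(cal$time))
  i <- cand[which.min(cal$seq[cand])]
  ev <- list(time = cal$time[i], seq = cal$seq[i], kind = cal$kind[i],
             payload = cal$payload[[i]])
  cal$time <- cal$time[-i]
  cal$seq <- cal$seq[-i]
  cal$kind <- cal$kind[-i]
  cal$payload[i] <- NULL
  cal$now <- ev$time
  ev
}

#' Create a capacity-scheduled resource pool
#'
#' A pool holds an integer number of interchangeable servers whose capacity
#' changes at staffing-period boundaries. Capacity changes are
#' non-preemptive: a capacity drop never interrupts a patient in service; the
#' excess busy servers drain as services complete. Waiting patients are
#' served first-in-first-out.
#'
#' @param id pool identifier (e.g. `"M3"`).
#' @param capacity integer vector of servers per staffing period.
#' @param breaks start minute of each period (first entry 0); after the last
#'   period the final capacity persists until the system empties.
#' @return a `resource_pool` object.
#' @export
resource_pool <- function(id, capacity, breaks) {
  stopifnot(length(capacity) == length(breaks), breaks[1] == 0,
            !is.unsorted(breaks), all(capacity >= 0))
  p <- new.env(parent = emptyenv())
  p$id <- id
  p$capacity <- as.integer(capacity)
  p$breaks <- as.numeric(breaks)
  p$busy <- 0L
  p$queue <- integer(0)          # FIFO patient ids
  p$cum_busy <- 0                # minutes of completed service
  p$in_service_start <- numeric(0)
  p$served <- 0L
  class(p) <- "resource_pool"
  p
}

#' @export
print.resource_pool <- function(x, ...) {
  cat(sprintf("<resource_pool %s> busy=%d queue=%d served=%d\n",
              x$id, x$busy, length(x$queue), x$served))
  invisible(x)
}

#' Current capacity of a pool
#'
#' @param pool a [resource_pool()].
#' @param now clock time, minutes.
#' @return integer number of servers scheduled at `now`.
#' @export
current_capacity <- function(pool, now) {
  pool$capacity[findInterval(now, pool$breaks)]
}

#' Request a server for a patient
#'
#' If a server is idle the patient enters service immediately; otherwise the
#' patient joins the tail of the FIFO queue.
#'
#' @param pool a [resource_pool()].
#' @param pid patient id.
#' @param now clock time, minutes.
#' @return `"in_service"` or `"queued"`.
#' @export
pool_seize <- function(pool, pid, now) {
  if (pool$busy < current_capacity(pool, now)) {
    pool$busy <- pool$busy + 1L
    pool$in_service_start <- c(pool$in_service_start, now)
    "in_service"
  } else {
    pool$queue <- c(pool$queue, pid)
    "queued"
  }
}

#' Release a server at service completion
#'
#' Accrues the finished service duration into the pool's cumulative busy
#' time. Starting the next queued patient is the caller's job (via
#' [pool_next_from_queue()]), because the caller must sample a service time
#' and schedule the completion event.
#'
#' @param pool a [resource_pool()].
#' @param now clock time, minutes.
#' @param service_start when the completing service began, minutes.
#' @return the pool, invisibly.
#' @export
pool_release <- function(pool, now, service_start) {
  if (pool$busy < 1L) {
    stop("pool_release('", pool$id, "'): release without seize", call. = FALSE)
  }
  pool$busy <- pool$busy - 1L
  pool$cum_busy <- pool$cum_busy + (now - service_start)
  pool$served <- pool$served + 1L
  i <- which(abs(pool$in_service_start - service_start) < 1e-12)[1]
  if (!is.na(i)) pool$in_service_start <- pool$in_service_start[-i]
  invisible(pool)
}

#' Start the next queued patient if a server is free
#'
#' Respects the current (possibly reduced) capacity: after a staffing drop no
#' new service starts until the busy count falls below the new capacity.
#'
#' @param pool a [resource_pool()].
#' @param now clock time, minutes.
#' @return the patient id entering service, or `NULL`.
#' @export
pool_next_from_queue <- function(pool, now) {
  if (length(pool$queue) == 0L || pool$busy >= current_capacity(pool, now)) {
    return(NULL)
  }
  pid <- pool$queue[1L]
  pool$queue <- pool$queue[-1L]
  pool$busy <- pool$busy + 1L
  pool$in_service_start <- c(pool$in_service_start, now)
  pid
}

#' Pool utilization at an instant
#'
#' Cumulative busy server-time (completed services plus the elapsed part of
#' services in progress) divided by the scheduled server-time available from
#' opening to `now`. This is the quantity the partially-shared routing policy
#' minimizes when overflowing a patient to another counter type.
#'
#' @param pool a [resource_pool()].
#' @param now clock time, minutes.
#' @return utilization in `[0, 1]` (0 for a pool that has had no capacity).
#' @export
pool_utilization <- function(pool, now) {
  busy_time <- pool$cum_busy + sum(now - pool$in_service_start)
  ends <- c(pool$breaks[-1L], max(now, pool$breaks[length(pool$breaks)]))
  open_time <- sum(pool$capacity * pmax(0, pmin(now, ends) - pmin(now, pool$breaks)))
  if (open_time <= 0) return(0)
  busy_time / open_time
}
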