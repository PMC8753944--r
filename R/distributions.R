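#' Triangular distribution sampler (inverse CDF)
#'
#' Service times at the type-3 and type-4 medical-record counters are modelled
#' as triangular distributions elicited from timestamp data; the satisfaction
#' profiles use the same family. Inverse-CDF sampling keeps draws reproducible
#' from a single uniform stream.
#'
#' @param n number of draws.
#' @param a,m,b minimum, mode and maximum (`a <= m <= b`).
#' @return numeric vector of draws in `[a, b]`.
#' @export
#' @examples
#' set.seed(1)
#' range(rtri(1000, 84, 146.8, 251))
rtri <- function(n, a, m, b) {
  stopifnot(a <= m, m <= b)
  if (a == b) return(rep(a, n))
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Construct a station service-time specification
#'
#' @param station station label, e.g. `"triage"` or `"mr_type3"`.
#' @param family one of `"constant"`, `"shifted_exponential"`,
#'   `"shifted_weibull"`, `"triangular"`.
#' @param ... family parameters in seconds: `value` (constant);
#'   `shift`, `mean` (shifted exponential); `shift`, `scale`, `shape`
#'   (shifted Weibull); `min`, `mode`, `max` (triangular).
#' @return an object of class `service_spec`.
#' @export
service_spec <- function(station, family, ...) {
  params <- list(...)
  family <- match.arg(family,
                      c("constant", "shifted_exponential", "shifted_weibull",
                        "triangular"))
  need <- switch(family,
                 constant = "value",
                 shifted_exponential = c("shift", "mean"),
                 shifted_weibull = c("shift", "scale", "shape"),
                 triangular = c("min", "mode", "max"))
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("service_spec('", station, "'): missing parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(params[need])
  if (any(vals < 0)) {
    stop("service_spec('", station, "'): parameters must be nonnegative",
         call. = FALSE)
  }
  if (family == "triangular" &&
      !(params$min <= params$mode && params$mode <= params$max)) {
    stop("service_spec('", station, "'): requires min <= mode <= max",
         call. = FALSE)
  }
  structure(list(station = station, family = family, params = params[need]),
            class = "service_spec")
}

#' @export
print.service_spec <- function(x, ...) {
  cat(sprintf("<service_spec> %s: %s(%s) [seconds]\n", x$station, x$family,
              paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Closed-form mean service time, in seconds
#'
#' Used both for the deterministic verification runs (one patient per type,
#' constant service, no queueing) and for manual length-of-stay sums.
#'
#' @param spec a [service_spec()].
#' @return mean of the service-time distribution, seconds.
#' @export
#' @examples
#' mean_service(service_spec("mr_type4", "triangular",
#'                           min = 59, mode = 72.8, max = 197)) # 109.6
mean_service <- function(spec) {
  stopifnot(inherits(spec, "service_spec"))
  p <- spec$params
  switch(spec$family,
         constant = p$value,
         shifted_exponential = p$shift + p$mean,
         shifted_weibull = p$shift + p$scale * gamma(1 + 1 / p$shape),
         triangular = (p$min + p$mode + p$max) / 3)
}

#' Sample service times, in seconds
#'
#' @param spec a [service_spec()].
#' @param n number of draws.
#' @param deterministic if `TRUE`, return the distribution mean (used by the
#'   verification procedure).
#' @return numeric vector of service times, seconds.
#' @export
sample_service <- function(spec, n = 1L, deterministic = FALSE) {
  stopifnot(inherits(spec, "service_spec"))
  if (deterministic) return(rep(mean_service(spec), n))
  p <- spec$params
  switch(spec$family,
         constant = rep(p$value, n),
         shifted_exponential = p$shift + stats::rexp(n, rate = 1 / p$mean),
         shifted_weibull = p$shift +
           stats::rweibull(n, shape = p$shape, scale = p$scale),
         triangular = rtri(n, p$min, p$mode, p$max))
}

#' Sample patient interarrival times for one arrival segment
#'
#' Interarrival times are (possibly shifted) exponential, with the segment in
#' force determined by the clock time of the previous arrival. A draw that
#' crosses a segment boundary is kept as drawn.
#'
#' @param segment one row of the arrival-segment table: a list or one-row
#'   data.frame with `shift` and `mean` (minutes).
#' @param n number of draws.
#' @return interarrival times, minutes (each `> shift`).
#' @export
sample_interarrival <- function(segment, n = 1L) {
  stopifnot(segment$mean > 0, segment$shift >= 0)
  segment$shift + stats::rexp(n, rate = 1 / segment$mean)
}

#' Assign a patient type from the time-of-day mix
#'
#' The share of each of the four patient types varies over the day in
#' two-hour windows; the type is drawn from the window containing the
#' patient's queue-ticket time.
#'
#' @param windows type-mix table: data.frame with `start`, `end` (minutes
#'   since opening) and `p1`..`p4`.
#' @param ticket_time queue-ticket time(s), minutes since opening.
#' @return integer vector of patient types in 1..4.
#' @export
assign_patient_type <- function(windows, ticket_time) {
  vapply(ticket_time, function(tt) {
    row <- which(windows$start <= tt & tt < windows$end)
    if (length(row) == 0L) {
      # the last window is closed on the right (ticket close boundary)
      if (tt == max(windows$end)) row <- which.max(windows$end) else
        stop("ticket time ", tt, " min is outside every type-mix window",
             call. = FALSE)
    }
    probs <- as.numeric(windows[row[1L], c("p1", "p2", "p3", "p4")])
    sample.int(4L, 1L, prob = probs)
  }, integer(1))
}
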