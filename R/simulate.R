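#' Run one simulated working day
#'
#' Executes one terminating replication of the front-end department: arrivals
#' are generated from opening (05:00) until ticket close (14:50 by default),
#' and the simulation keeps running past the 600-minute day until every
#' patient who entered has left, so the count of entering and leaving
#' patients is equal at termination. No warm-up period is discarded: the
#' department starts the day empty and the whole day is the object of study.
#'
#' @param cfg a `frontflow_config`.
#' @param seed integer replication seed; identical `(cfg, seed)` give an
#'   identical event trace.
#' @param deterministic if `TRUE`, every service time equals its
#'   distribution mean (the verification setting).
#' @param arrivals optional data.frame with `ticket_time`, `type`, `is_new`
#'   overriding arrival generation (used for verification and degenerate
#'   cases).
#' @return a `replication_record`: list with `patients` (one row per
#'   completed patient), `entered`, `left`, `end_time` (minutes), and
#'   `pools` (per-pool served counts and utilization).
#' @export
run_replication <- function(cfg, seed = 1L, deterministic = FALSE,
                            arrivals = NULL) {
  cfg <- validate_config(cfg)
  service_names <- c("blood_pressure", "triage", "fill_info",
                     paste0("mr_type", 1:4))
  streams <- rng_substreams(seed, c("arrival", "type", "new", service_names))
  if (is.null(arrivals)) arrivals <- generate_arrivals(cfg, streams)
  n <- nrow(arrivals)

  pools <- build_pools(cfg$schedule, cfg$policy)
  cal <- event_calendar()

  patients <- vector("list", n)
  for (pid in seq_len(n)) {
    p <- new.env(parent = emptyenv())
    p$type <- as.integer(arrivals$type[pid])
    p$is_new <- isTRUE(arrivals$is_new[pid])
    p$ticket <- arrivals$ticket_time[pid]
    p$path <- flow_path(p$type, p$is_new)
    p$i <- 1L
    k <- length(p$path)
    p$arrive <- p$start <- p$depart <- rep(NA_real_, k)
    p$pool <- rep(NA_character_, k)
    p$service_start <- NA_real_
    p$done <- NA_real_
    patients[[pid]] <- p
    push_event(cal, p$ticket, "arrival", pid)
  }
  for (b in pools[[1]]$breaks[-1]) push_event(cal, b, "period_change")

  completed <- 0L

  draw_service <- function(p) {
    st <- p$path[p$i]
    spec_name <- if (st == "mr") paste0("mr_type", p$type) else st
    spec <- cfg$services[[spec_name]]
    stream_eval(streams[[spec_name]],
                function() sample_service(spec, 1L, deterministic)) / 60
  }
  begin_service <- function(pid, now) {
    p <- patients[[pid]]
    p$start[p$i] <- now
    p$service_start <- now
    push_event(cal, now + draw_service(p), "service_end", pid)
  }
  station_enter <- function(pid, now) {
    p <- patients[[pid]]
    st <- p$path[p$i]
    p$arrive[p$i] <- now
    if (st %in% c("blood_pressure", "fill_info")) {   # self-service steps
      begin_service(pid, now)
    } else {
      pool_id <- if (st == "triage") {
        if (p$type == 1L) "N" else "N2"
      } else {
        route_mrd(cfg$policy, p$type, pools, now)
      }
      p$pool[p$i] <- pool_id
      if (pool_seize(pools[[pool_id]], pid, now) == "in_service") {
        begin_service(pid, now)
      }
    }
  }
  drain_queue <- function(pool, now) {
    repeat {
      pid2 <- pool_next_from_queue(pool, now)
      if (is.null(pid2)) break
      begin_service(pid2, now)
    }
  }

  repeat {
    ev <- pop_next(cal)
    if (is.null(ev)) break
    now <- ev$time
    if (now > cfg$hard_cap) {
      stop("stuck system: clock passed ", cfg$hard_cap, " min with ",
           n - completed, " patient(s) still in the system; ",
           "check for a required station with zero capacity", call. = FALSE)
    }
    if (ev$kind == "arrival") {
      station_enter(ev$payload, now)
    } else if (ev$kind == "service_end") {
      pid <- ev$payload
      p <- patients[[pid]]
      p$depart[p$i] <- now
      pool_id <- p$pool[p$i]
      if (!is.na(pool_id)) {
        pool <- pools[[pool_id]]
        pool_release(pool, now, p$service_start)
        pid2 <- pool_next_from_queue(pool, now)
        if (!is.null(pid2)) begin_service(pid2, now)
      }
      if (p$i < length(p$path)) {
        p$i <- p$i + 1L
        station_enter(pid, now)
      } else {
        p$done <- now
        completed <- completed + 1L
      }
    } else if (ev$kind == "period_change") {
      for (pool in pools) drain_queue(pool, now)
    }
  }

  if (completed < n) {
    waiting <- sum(vapply(pools, function(p) length(p$queue), integer(1)))
    stop("stuck system: calendar empty but ", n - completed,
         " patient(s) never left (", waiting, " still queued); ",
         "a required station has no capacity", call. = FALSE)
  }

  end_time <- max(cfg$min_run_length,
                  if (n > 0) max(vapply(patients, function(p) p$done, numeric(1))) else 0)

  grab <- function(p, st, field) {
    i <- match(st, p$path)
    if (is.na(i)) NA_real_ else p[[field]][i]
  }
  pdf <- data.frame(
    id = seq_len(n),
    type = vapply(patients, function(p) p$type, integer(1)),
    is_new = vapply(patients, function(p) p$is_new, logical(1)),
    ticket_time = vapply(patients, function(p) p$ticket, numeric(1))
  )
  for (st in c("blood_pressure", "triage", "fill_info", "mr")) {
    for (f in c("arrive", "start", "depart")) {
      pdf[[paste(st, f, sep = "_")]] <-
        vapply(patients, grab, numeric(1), st = st, field = f)
    }
  }
  pdf$mr_pool <- vapply(patients, function(p) {
    i <- match("mr", p$path)
    if (is.na(i)) NA_character_ else p$pool[i]
  }, character(1))
  pdf$depart_time <- vapply(patients, function(p) p$done, numeric(1))
  pdf$los <- pdf$depart_time - pdf$ticket_time

  pool_df <- data.frame(
    pool = names(pools),
    served = vapply(pools, function(p) p$served, integer(1)),
    busy_min = vapply(pools, function(p) p$cum_busy, numeric(1)),
    utilization = vapply(pools, pool_utilization, numeric(1), now = end_time),
    row.names = NULL
  )

  structure(list(patients = pdf, entered = n, left = completed,
                 end_time = end_time, pools = pool_df, seed = seed),
            class = "replication_record")
}

#' @export
print.replication_record <- function(x, ...) {
  cat(sprintf("<replication_record> %d patients, day ended at %.1f min (%s)\n",
              x$entered, x$end_time, min_to_clock(x$end_time)))
  if (x$entered > 0) {
    cat(sprintf("  mean LOS %.2f min", mean(x$patients$los)))
    if (!is.null(x$patients$score)) {
      cat(sprintf(", mean satisfaction %.1f%%", mean(x$patients$score)))
    }
    cat("\n")
  }
  invisible(x)
}

#' Simulate one day and attach satisfaction scores
#'
#' Runs [run_replication()] and converts each patient's length of stay into a
#' satisfaction score with the type's expert-elicited profile (see
#' [los_to_score()]).
#'
#' @inheritParams run_replication
#' @return a `replication_record` whose `patients` table has a `score`
#'   column (percent).
#' @export
simulate_day <- function(cfg, seed = 1L, deterministic = FALSE,
                         arrivals = NULL) {
  rec <- run_replication(cfg, seed, deterministic, arrivals)
  mappings <- lapply(cfg$satisfaction, score_mapping)
  rec$patients$score <- score_patients(rec$patients, mappings)
  rec
}

score_patients <- function(patients, mappings) {
  out <- numeric(nrow(patients))
  for (ty in 1:4) {
    idx <- patients$type == ty
    if (any(idx)) {
      out[idx] <- los_to_score(mappings[[as.character(ty)]], patients$los[idx])
    }
  }
  out
}

#' Write a per-patient event log
#'
#' One row per patient with ticket time, per-station arrive/start/depart
#' times, the counter that served the patient, length of stay and
#' satisfaction score.
#'
#' @param rec a `replication_record` (from [simulate_day()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(rec, path) {
  utils::write.csv(rec$patients, path, row.names = FALSE)
  invisible(path)
}

#' Summarize a replication
#'
#' @param rec a `replication_record`.
#' @return data.frame with per-type and overall patient counts, mean LOS and
#'   mean satisfaction.
#' @export
summarize_replication <- function(rec) {
  p <- rec$patients
  groups <- c(as.character(1:4), "all")
  do.call(rbind, lapply(groups, function(g) {
    rows <- if (g == "all") p else p[p$type == as.integer(g), ]
    data.frame(type = g, n = nrow(rows),
               mean_los = if (nrow(rows)) mean(rows$los) else NA_real_,
               mean_score = if (nrow(rows) && !is.null(rows$score)) {
                 mean(rows$score)
               } else NA_real_)
  }))
}
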