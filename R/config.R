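#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration: arrival segments
#' partition the opening hours with positive means, type-mix rows sum to one,
#' triangular parameters are ordered, schedule entries are nonnegative
#' integers, and the policy has the counter kinds it needs.
#'
#' @param cfg a `frontflow_config` list.
#' @return the validated configuration (invisibly classed).
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("config validation: ", ..., call. = FALSE)

  a <- cfg$arrivals
  if (!all(c("start", "end", "shift", "mean") %in% names(a)))
    fail("arrival segments need start/end/shift/mean")
  if (any(a$start >= a$end)) fail("arrival segment with start >= end")
  if (any(a$mean <= 0)) fail("arrival segment with nonpositive mean")
  if (any(a$shift < 0)) fail("arrival segment with negative shift")
  o <- order(a$start)
  if (any(abs(a$end[o][-nrow(a)] - a$start[o][-1]) > 1e-9))
    fail("arrival segments must partition the day without gaps")

  w <- cfg$type_mix
  probs <- as.matrix(w[, c("p1", "p2", "p3", "p4")])
  if (any(probs < 0)) fail("negative type-mix probability")
  bad <- abs(rowSums(probs) - 1) > 1e-9
  if (any(bad))
    fail("type-mix window ", which(bad)[1], " probabilities sum to ",
         rowSums(probs)[bad][1], ", not 1")

  needed <- c("blood_pressure", "triage", "fill_info",
              paste0("mr_type", 1:4))
  if (!all(needed %in% names(cfg$services)))
    fail("missing service spec(s): ",
         paste(setdiff(needed, names(cfg$services)), collapse = ", "))
  for (s in cfg$services) {
    if (!inherits(s, "service_spec")) fail("services must be service_spec objects")
  }

  for (ty in as.character(1:4)) {
    prof <- cfg$satisfaction[[ty]]
    if (is.null(prof)) fail("missing satisfaction profile for type ", ty)
    if (!(all(diff(prof$los) >= 0)))
      fail("type ", ty, " LOS triple must be nondecreasing (optimistic <= most likely <= pessimistic)")
    if (!(all(diff(prof$score) <= 0)))
      fail("type ", ty, " score triple must be nonincreasing")
    if (any(prof$score < 0 | prof$score > 100))
      fail("type ", ty, " scores must lie in [0, 100]")
  }

  if (!cfg$policy %in% c("dedicated", "one_stop", "partial_shared"))
    fail("unknown policy '", cfg$policy, "'")
  if (cfg$p_new < 0 || cfg$p_new > 1) fail("p_new must be in [0, 1]")

  n <- cfg$schedule
  if (is.null(rownames(n)) || !all(rownames(n) %in% resource_kinds()))
    fail("schedule rows must be named among ",
         paste(resource_kinds(), collapse = ", "))
  if (any(n < 0) || any(n != round(n))) fail("schedule entries must be nonnegative integers")
  if (cfg$policy == "one_stop") {
    if (!"M" %in% rownames(n) || any(n["M", ] <= 0))
      fail("one_stop policy needs a positive pooled counter row 'M'")
  } else {
    for (k in paste0("M", 1:4)) {
      if (!k %in% rownames(n)) fail("policy '", cfg$policy, "' needs counter row ", k)
    }
    if ("M12" %in% rownames(n) && any(n["M12", ] > 0))
      fail("M12 counters are schedule-accounting only and cannot be simulated; ",
           "fold them into M1/M2 for a run")
  }
  if (!is.null(cfg$weights)) {
    if (any(abs(rowSums(cfg$weights) - 1) > 1e-9))
      fail("each weight pair must sum to 1")
  }
  structure(cfg, class = "frontflow_config")
}

#' Load a model configuration
#'
#' Reads a YAML (or JSON) configuration file; any missing section falls back
#' to the built-in case-study default, so an empty file yields
#' [default_config()]. Clock times are `"HH:MM"` strings, converted to
#' minutes since the 05:00 ticket opening on load.
#'
#' @param path file path, or `NULL` for the full default configuration.
#' @param policy,p_new defaults used when the file does not set them.
#' @return a validated `frontflow_config`.
#' @export
load_config <- function(path = NULL, policy = "dedicated", p_new = 0) {
  if (is.null(path)) return(default_config(policy, p_new))
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  cfg <- default_config(policy = raw$policy %||% policy,
                        p_new = raw$p_new %||% p_new)

  if (!is.null(raw$arrivals)) {
    cfg$arrivals <- do.call(rbind, lapply(raw$arrivals, function(s) {
      data.frame(start = clock_to_min(s$start), end = clock_to_min(s$end),
                 shift = s$shift_min %||% 0, mean = s$mean_min)
    }))
  }
  if (!is.null(raw$type_mix)) {
    cfg$type_mix <- do.call(rbind, lapply(raw$type_mix, function(wdw) {
      p <- as.numeric(unlist(wdw$probs))
      data.frame(start = clock_to_min(wdw$start), end = clock_to_min(wdw$end),
                 p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4])
    }))
  }
  if (!is.null(raw$services)) {
    for (nm in names(raw$services)) {
      s <- raw$services[[nm]]
      cfg$services[[nm]] <- do.call(service_spec,
                                    c(list(station = nm, family = s$family),
                                      s[setdiff(names(s), "family")]))
    }
  }
  if (!is.null(raw$satisfaction)) {
    for (ty in names(raw$satisfaction)) {
      prof <- raw$satisfaction[[ty]]
      cfg$satisfaction[[ty]] <- list(los = as.numeric(unlist(prof$los)),
                                     score = as.numeric(unlist(prof$score)))
    }
  }
  if (!is.null(raw$weights)) {
    wm <- do.call(rbind, lapply(raw$weights, function(p) as.numeric(unlist(p))))
    cfg$weights <- data.frame(w_cost = wm[, 1], w_sat = wm[, 2])
  }
  if (!is.null(raw$schedule)) {
    cfg$schedule <- schedule_from_list(raw$schedule)
  }
  if (!is.null(raw$ticket_close)) cfg$ticket_close <- clock_to_min(raw$ticket_close)
  validate_config(cfg)
}

schedule_from_list <- function(sch) {
  periods <- as.character(unlist(sch$periods))
  rows <- sch$rows
  n <- matrix(0L, nrow = length(rows), ncol = length(periods),
              dimnames = list(names(rows), periods))
  for (k in names(rows)) n[k, ] <- as.integer(unlist(rows[[k]]))
  n
}

#' Write a configuration back to YAML
#'
#' The written file round-trips: loading it reproduces the same validated
#' configuration object.
#'
#' @param cfg a `frontflow_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- list(
    policy = cfg$policy,
    p_new = cfg$p_new,
    ticket_close = min_to_clock(cfg$ticket_close),
    arrivals = lapply(seq_len(nrow(cfg$arrivals)), function(i) {
      r <- cfg$arrivals[i, ]
      list(start = min_to_clock(r$start), end = min_to_clock(r$end),
           shift_min = r$shift, mean_min = r$mean)
    }),
    type_mix = lapply(seq_len(nrow(cfg$type_mix)), function(i) {
      r <- cfg$type_mix[i, ]
      list(start = min_to_clock(r$start), end = min_to_clock(r$end),
           probs = as.numeric(r[c("p1", "p2", "p3", "p4")]))
    }),
    services = lapply(cfg$services, function(s) c(list(family = s$family), s$params)),
    satisfaction = lapply(cfg$satisfaction, function(p)
      list(los = p$los, score = p$score)),
    weights = lapply(seq_len(nrow(cfg$weights)), function(i)
      as.numeric(cfg$weights[i, ])),
    schedule = list(periods = as.list(colnames(cfg$schedule)),
                    rows = lapply(rownames(cfg$schedule), function(k)
                      as.integer(cfg$schedule[k, ])))
  )
  names(out$schedule$rows) <- rownames(cfg$schedule)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Every command-line run records the inputs that produced its artifacts so
#' the run can be reproduced exactly.
#'
#' @param dir output directory (created if needed).
#' @param command command name.
#' @param args named list of arguments (seed, config path, ...).
#' @return path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, command, args) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(command = command,
                     tool = "frontflow",
                     version = as.character(utils::packageVersion("frontflow")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                args)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
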