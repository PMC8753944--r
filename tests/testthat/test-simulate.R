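test_that("every entering patient leaves and timestamps are monotone", {
  for (seed in c(1, 17, 202)) {
    rec <- run_replication(tight_config("partial_shared"), seed = seed)
    expect_equal(rec$entered, rec$left)
    expect_equal(rec$entered, nrow(rec$patients))
    expect_gte(rec$end_time, 600)
    p <- rec$patients
    stamps <- cbind(p$ticket_time,
                    p$blood_pressure_arrive, p$blood_pressure_depart,
                    p$triage_arrive, p$triage_depart,
                    p$mr_arrive, p$mr_start, p$mr_depart, p$depart_time)
    for (i in seq_len(nrow(stamps))) {
      s <- stamps[i, !is.na(stamps[i, ])]
      expect_true(all(diff(s) >= -1e-9))
    }
    expect_true(all(p$los >= 0))
  }
})

test_that("identical config and seed give identical patient tables", {
  cfg <- tight_config("dedicated")
  a <- run_replication(cfg, seed = 5)
  b <- run_replication(cfg, seed = 5)
  expect_identical(a$patients, b$patients)
  c <- run_replication(cfg, seed = 6)
  expect_false(identical(a$patients, c$patients))
})

test_that("dedicated queues are served first-in-first-out", {
  cfg <- tight_config("dedicated")
  rec <- run_replication(cfg, seed = 12)
  p <- rec$patients
  for (pool in paste0("M", 1:4)) {
    rows <- p[!is.na(p$mr_pool) & p$mr_pool == pool, ]
    rows <- rows[order(rows$mr_arrive), ]
    expect_true(all(diff(rows$mr_start) >= -1e-9))
  }
})

test_that("no arrivals yield an empty day ending at the minimum run length", {
  cfg <- default_config()
  rec <- run_replication(cfg, seed = 1,
                         arrivals = data.frame(ticket_time = numeric(0),
                                               type = integer(0),
                                               is_new = logical(0)))
  expect_equal(rec$entered, 0L)
  expect_equal(rec$end_time, 600)
})

test_that("a required station with zero capacity raises the stuck-system diagnostic", {
  cfg <- default_config()
  s <- cfg$schedule
  s["N", ] <- 0L
  cfg$schedule <- s
  expect_error(
    run_replication(cfg, seed = 1,
                    arrivals = data.frame(ticket_time = 0, type = 1,
                                          is_new = FALSE)),
    "stuck system")
})

test_that("satisfaction scores are attached per type and logged", {
  cfg <- tight_config("one_stop")
  rec <- simulate_day(cfg, seed = 3)
  expect_true(all(rec$patients$score >= 0 & rec$patients$score <= 100))
  expect_equal(average_satisfaction(rec), mean(rec$patients$score))
  # same seed -> same satisfaction mean
  rec2 <- simulate_day(cfg, seed = 3)
  expect_equal(average_satisfaction(rec), average_satisfaction(rec2))
  log_path <- tempfile(fileext = ".csv")
  write_event_log(rec, log_path)
  back <- read.csv(log_path)
  expect_equal(nrow(back), rec$entered)
  expect_true(all(c("id", "type", "ticket_time", "los", "score") %in% names(back)))
})

test_that("the one-stop bank never underperforms dedicated counters on mean LOS", {
  ded <- tight_config("dedicated")
  pool <- tight_config("one_stop")
  n <- 30
  d <- vapply(seq_len(n), function(r) {
    mean(run_replication(ded, seed = 400 + r)$patients$los)
  }, numeric(1))
  p <- vapply(seq_len(n), function(r) {
    mean(run_replication(pool, seed = 400 + r)$patients$los)
  }, numeric(1))
  diff <- d - p   # paired by common random numbers
  hw <- stats::qt(0.975, n - 1) * stats::sd(diff) / sqrt(n)
  expect_gte(mean(diff) + hw, 0)
})
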