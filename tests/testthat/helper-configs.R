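# Shared test fixtures, built in code.

# Default-parameter configuration with deliberately tight counter staffing so
# queues actually form; used for the pooling and monotonicity properties.
tight_config <- function(policy = "dedicated") {
  cfg <- default_config(policy)
  s <- cfg$schedule
  if (policy == "one_stop") {
    s["M", ] <- 5L
  } else {
    s["M1", ] <- 1L; s["M2", ] <- 1L; s["M3", ] <- 1L; s["M4", ] <- 2L
  }
  cfg$schedule <- s
  validate_config(cfg)
}

# Toy staffing lattice: two counter kinds over two periods, levels 1..2,
# counter capacity 3 per period -> 9 feasible schedules out of 16.
toy_bounds <- function() {
  dn <- list(c("M3", "M4"), c("07-09", "09-11"))
  list(lower = matrix(1L, 2, 2, dimnames = dn),
       upper = matrix(2L, 2, 2, dimnames = dn),
       A = 3L)
}

# Deterministic surrogate objective over toy schedules: cost is linear in
# total staffing; satisfaction rewards early-period counters most.
toy_evaluator <- function(sched) {
  list(z_cost = 100 * sum(sched),
       z_sat = 50 + 10 * sched[1, 1] + 6 * sched[2, 1] +
         4 * sched[1, 2] + 2 * sched[2, 2])
}

# Brute-force optimum of an objective over the toy lattice.
toy_brute_force <- function(value_fn) {
  cands <- enumerate_schedules(toy_bounds()$lower, toy_bounds()$upper,
                               toy_bounds()$A)
  vals <- vapply(cands, function(s) {
    e <- toy_evaluator(s)
    value_fn(e$z_cost, e$z_sat)
  }, numeric(1))
  list(schedule = cands[[which.max(vals)]], value = max(vals),
       evaluations = length(cands))
}

# A sample of size n with exactly the requested mean and sd (for checking
# summary-statistic formulas against stats::t.test on raw data).
sample_with_moments <- function(n, mean, sd) {
  x <- stats::rnorm(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}
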