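test_that("operating cost is linear in staffing", {
  sched <- matrix(c(1, 2, 0, 3), 2, 2, byrow = TRUE,
                  dimnames = list(c("N", "M3"), c("07-09", "09-11")))
  cm <- unit_cost_model(sched, 100)
  expect_equal(operating_cost(sched, cm), 600)
  expect_equal(operating_cost(sched * 0, cm), 0)
  expect_equal(operating_cost(sched * 2, cm), 2 * operating_cost(sched, cm))
  expect_error(operating_cost(sched, cm[, 1, drop = FALSE]), "dimensions")
})

test_that("feasibility checks counter capacity, integrality and sign", {
  dn <- list(c("M1", "M2", "M3", "M4"), paste0("p", 1:4))
  sched <- matrix(c(3, 3, 3, 3,
                    2, 3, 3, 2,
                    2, 2, 2, 1,
                    2, 2, 2, 2), 4, 4, byrow = TRUE, dimnames = dn)
  expect_true(feasible(sched, 10))          # sums 9, 10, 10, 8
  sched2 <- sched; sched2["M1", 2] <- 4     # one period sums 11
  expect_false(feasible(sched2, 10))
  sched3 <- sched; sched3["M2", 1] <- -1
  expect_false(feasible(sched3, 10))
  sched4 <- sched; sched4["M2", 1] <- 1.5
  expect_false(feasible(sched4, 10))
  # nurses do not count against the counter capacity
  nurses <- matrix(50, 1, 4, dimnames = list("N", dn[[2]]))
  expect_true(feasible(nurses, 1))
})

test_that("membership normalizes between the extremes and clips outside them", {
  cost_b <- objective_bounds(z_plus = 6864, z_minus = 4521, sense = "min")
  expect_equal(membership(4521, cost_b), 1)   # optimistic extreme
  expect_equal(membership(6864, cost_b), 0)
  expect_equal(membership(4966.5, cost_b), 0.810, tolerance = 1e-3)
  expect_equal(membership(4000, cost_b), 1)   # clipped
  sat_b <- objective_bounds(z_plus = 89.95, z_minus = 45.9, sense = "max")
  expect_equal(membership(45.9, sat_b), 0)
  expect_equal(membership(89.95, sat_b), 1)
  expect_error(objective_bounds(5, 5, "min"), "degenerate")
})

test_that("the achievement level is the bounded weighted min ratio", {
  expect_equal(lambda_level(c(0.810, 0.483), c(0.8, 0.2)), 1)
  expect_equal(lambda_level(c(0.843, 0.157), c(0.8, 0.2)),
               0.157 / 0.2, tolerance = 1e-12)
  expect_equal(lambda_level(c(0.3, 0.7), c(0.3, 0.7)), 1)  # f_k == w_k
  # zero weight drops the constraint
  expect_equal(lambda_level(c(0.0, 0.9), c(0, 1)), 0.9)
})

test_that("single-objective extremes define the fuzzy bounds", {
  b <- bounds_from_single_objective(list(z_cost = 4521, z_sat = 45.9),
                                    list(z_cost = 6864, z_sat = 89.95))
  expect_equal(b$cost$z_minus, 4521)
  expect_equal(b$cost$z_plus, 6864)
  expect_equal(b$sat$z_plus, 89.95)
  expect_equal(b$sat$z_minus, 45.9)
  expect_error(bounds_from_single_objective(list(z_cost = 1, z_sat = 2),
                                            list(z_cost = 1, z_sat = 2)),
               "degenerate")
})

test_that("exhaustive search equals brute-force enumeration on the toy lattice", {
  tb <- toy_bounds()
  cands <- enumerate_schedules(tb$lower, tb$upper, tb$A)
  expect_equal(length(cands), 9L)   # 3 feasible columns squared

  sc <- c(tb, list(stop_after_non_improving = 200L, seed = 1L,
                   proposal = "exhaustive"))
  # single objective: cost -> the all-lower-bounds corner
  res_cost <- search_schedules(objective_spec("cost"), sc,
                               evaluator = toy_evaluator)
  oracle_cost <- toy_brute_force(function(zc, zs) -zc)
  expect_equal(res_cost$best_schedule, tb$lower)
  expect_equal(res_cost$z_cost, -oracle_cost$value)

  # single objective: satisfaction
  res_sat <- search_schedules(objective_spec("satisfaction"), sc,
                              evaluator = toy_evaluator)
  oracle_sat <- toy_brute_force(function(zc, zs) zs)
  expect_equal(res_sat$best_schedule, oracle_sat$schedule)

  # multi objective at equal weights
  bounds <- bounds_from_single_objective(
    toy_evaluator(res_cost$best_schedule),
    toy_evaluator(res_sat$best_schedule))
  obj <- objective_spec("multi", weights = c(0.5, 0.5), bounds = bounds)
  res_multi <- search_schedules(obj, sc, evaluator = toy_evaluator)
  oracle_multi <- toy_brute_force(function(zc, zs) {
    lambda_level(c(membership(zc, bounds$cost), membership(zs, bounds$sat)),
                 c(0.5, 0.5))
  })
  expect_equal(res_multi$lambda, oracle_multi$value)
  expect_equal(res_multi$best_schedule, oracle_multi$schedule)
  expect_equal(res_multi$evaluations, 9L)
})

test_that("neighborhood search finds the enumerated optimum on the toy lattice", {
  tb <- toy_bounds()
  sc <- c(tb, list(stop_after_non_improving = 100L, seed = 3L,
                   proposal = "neighborhood"))
  res <- search_schedules(objective_spec("satisfaction"), sc,
                          evaluator = toy_evaluator)
  expect_equal(res$z_sat, toy_brute_force(function(zc, zs) zs)$value)
  # reproducible given the seed
  res2 <- search_schedules(objective_spec("satisfaction"), sc,
                           evaluator = toy_evaluator)
  expect_identical(res$trace, res2$trace)
})

test_that("raising the satisfaction weight never lowers the optimal satisfaction", {
  tb <- toy_bounds()
  bounds <- bounds_from_single_objective(
    toy_evaluator(tb$lower),
    toy_brute_force(function(zc, zs) zs)$schedule |> toy_evaluator())
  w <- weight_sets_default()
  w <- w[order(w$w_sat), ]
  zsat <- vapply(seq_len(nrow(w)), function(i) {
    oracle <- toy_brute_force(function(zc, zs) {
      lambda_level(c(membership(zc, bounds$cost), membership(zs, bounds$sat)),
                   c(w$w_cost[i], w$w_sat[i]))
    })
    toy_evaluator(oracle$schedule)$z_sat
  }, numeric(1))
  expect_true(all(diff(zsat) >= 0))
})

test_that("infeasible schedules are rejected without simulation and logged", {
  tb <- toy_bounds()
  bad <- tb$upper   # column sums 4 > A = 3
  expect_error(evaluate_schedule(bad, default_config(), unit_cost_model(bad),
                                 replications = 1, A = tb$A),
               "rejected without simulation")
  expect_error(search_schedules(objective_spec("cost"),
                                list(lower = bad, upper = bad, A = tb$A),
                                evaluator = toy_evaluator),
               "empty feasible region")
  # exhaustive proposal pre-filters the lattice: only feasible points scored
  sc <- c(tb, list(proposal = "exhaustive", stop_after_non_improving = 200L))
  res <- search_schedules(objective_spec("cost"), sc, evaluator = toy_evaluator)
  expect_equal(nrow(res$trace), 9L)
  expect_true(all(res$trace$feasible))
  # neighborhood proposal logs infeasible candidates as rejected, unscored
  scn <- c(tb, list(proposal = "neighborhood", stop_after_non_improving = 50L,
                    seed = 8L, restart_every = 2L))
  resn <- search_schedules(objective_spec("cost"), scn, evaluator = toy_evaluator)
  rejected <- resn$trace[!resn$trace$feasible, ]
  expect_gt(nrow(rejected), 0L)
  expect_true(all(is.na(rejected$objective)))
  expect_equal(sum(resn$trace$feasible), resn$evaluations)
})

test_that("simulation evaluation is seed-reproducible and uses common random numbers", {
  cfg <- tight_config("dedicated")
  cm <- unit_cost_model(cfg$schedule, 100)
  a <- evaluate_schedule(cfg$schedule, cfg, cm, replications = 2L, seed = 9L)
  b <- evaluate_schedule(cfg$schedule, cfg, cm, replications = 2L, seed = 9L)
  expect_identical(a, b)
  expect_equal(a$z_cost, operating_cost(cfg$schedule, cm))
  # zero-cost model: cost objective vanishes regardless of schedule
  expect_equal(evaluate_schedule(cfg$schedule, cfg, unit_cost_model(cfg$schedule, 0),
                                 replications = 1L, seed = 1L)$z_cost, 0)
})

test_that("adding a counter to a congested pool does not increase mean LOS", {
  base <- tight_config("dedicated")
  more <- base
  s <- more$schedule
  s["M4", ] <- s["M4", ] + 1L
  more$schedule <- s
  n <- 30
  los_base <- vapply(seq_len(n), function(r) {
    mean(run_replication(base, seed = 700 + r)$patients$los)
  }, numeric(1))
  los_more <- vapply(seq_len(n), function(r) {
    mean(run_replication(more, seed = 700 + r)$patients$los)
  }, numeric(1))
  diff <- los_base - los_more
  hw <- stats::qt(0.975, n - 1) * stats::sd(diff) / sqrt(n)
  expect_gte(mean(diff) + hw, 0)
})
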