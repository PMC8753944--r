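test_that("verification reproduces the manual no-queue LOS for every type", {
  rep <- verify_model(default_config())
  expect_true(all(rep$equal))
  expect_equal(round(rep$simulated_min[rep$type == 1], 2), 3.47)
  expect_equal(round(rep$simulated_min[rep$type == 2], 2), 3.47)
  expect_equal(round(rep$simulated_min[rep$type == 4], 2), 1.83)
  expect_equal(rep$simulated_min[rep$type == 3], (84 + 146.8 + 251) / 3 / 60)
})

test_that("Welch t from summary statistics matches t.test on raw data", {
  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    m1 <- runif(1, 10, 100); m2 <- runif(1, 10, 100)
    s1 <- runif(1, 1, 30); s2 <- runif(1, 1, 30)
    x <- sample_with_moments(n1, m1, s1)
    y <- sample_with_moments(n2, m2, s2)
    ours <- welch_t(list(mean = m1, sd = s1, n = n1),
                    list(mean = m2, sd = s2, n = n2))
    ref <- stats::t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Welch t edge cases follow the stated conventions", {
  same <- list(mean = 10, sd = 2, n = 20)
  expect_equal(welch_t(same, same)$p_value, 1)
  expect_false(welch_t(same, same)$reject_at_95)
  sep <- welch_t(list(mean = 10, sd = 0.01, n = 20),
                 list(mean = 1000, sd = 0.01, n = 20))
  expect_lt(sep$p_value, 0.05)
  flat <- welch_t(list(mean = 5, sd = 0, n = 5), list(mean = 5, sd = 0, n = 5))
  expect_equal(flat$p_value, 1)
})

test_that("replication sizing projects the half-width as 1/sqrt(n)", {
  # pilot already inside the target: keep the pilot count
  m <- 100; n0 <- 10
  sd_for <- function(rel) rel * m * sqrt(n0) / stats::qt(0.975, n0 - 1)
  pilot <- sample_with_moments(n0, m, sd_for(0.02))
  out <- required_replications(pilot, target = 0.05)
  expect_equal(out$relative_error, 0.02, tolerance = 1e-9)
  expect_equal(out$required_n, 10)
  # relative error 10% against a 5% target: four-fold replication count
  pilot <- sample_with_moments(n0, m, sd_for(0.10))
  out <- required_replications(pilot, target = 0.05)
  expect_equal(out$required_n, 40)
  expect_error(required_replications(pilot, target = 0), "positive")
  expect_error(required_replications(rep(0, 5), target = 0.05), "zero mean")
})

test_that("blocked ANOVA has the crossed-layout degrees of freedom", {
  set.seed(31)
  d <- expand.grid(case = 1:7, scenario = 1:4, replication = 1:10)
  d$satisfaction <- 70 + rnorm(nrow(d), sd = 2)
  tab <- anova_blocked(d)
  df <- function(term) tab$df[tab$term == term]
  expect_equal(df("Total"), 279)
  expect_equal(df("Case"), 6)
  expect_equal(df("Scenario"), 3)
  expect_equal(df("Replication"), 9)
  expect_equal(df("Case:Scenario"), 18)
  expect_equal(df("Error"), 243)
  expect_equal(sum(tab$df[tab$term != "Total"]), df("Total"))
  # incomplete layout is rejected
  expect_error(anova_blocked(d[-1, ]), "crossed")
})

test_that("an injected interaction is detected and a constant response is not", {
  set.seed(32)
  d <- expand.grid(case = 1:4, scenario = 1:3, replication = 1:8)
  d$satisfaction <- 60 + 2 * (d$case == 2 & d$scenario == 3) * 10 +
    rnorm(nrow(d), sd = 1)
  tab <- anova_blocked(d)
  expect_lt(tab$p[tab$term == "Case:Scenario"], 0.01)

  d$satisfaction <- 55
  flat <- anova_blocked(d)
  expect_true(all(is.na(flat$f[flat$term != "Total"])))
  expect_equal(flat$p[flat$term == "Case"], 1)
})

test_that("letter display separates clear means and merges equal ones", {
  two <- data.frame(group = c("a", "b"), mean = c(10, 50), n = 10)
  out <- tukey_letters(two, ms_error = 1, df_error = 18)
  expect_equal(sort(out$letters), c("A", "B"))
  three <- data.frame(group = c("a", "b", "c"), mean = c(20, 20, 20), n = 10)
  out3 <- tukey_letters(three, ms_error = 4, df_error = 27)
  expect_true(all(out3$letters == "A"))
  one <- data.frame(group = "solo", mean = 5, n = 4)
  expect_equal(tukey_letters(one, 1, 3)$letters, "A")
})

test_that("sharing a letter is equivalent to a non-significant pairwise HSD", {
  set.seed(33)
  for (trial in 1:20) {
    k <- sample(3:8, 1)
    g <- data.frame(group = paste0("g", seq_len(k)),
                    mean = round(runif(k, 0, 20), 1),
                    n = sample(5:15, 1))
    ms <- runif(1, 0.5, 25)
    dfe <- sum(g$n) - k
    out <- tukey_letters(g, ms, dfe)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        se <- sqrt(ms / 2 * (1 / out$n[i] + 1 / out$n[j]))
        q <- abs(out$mean[i] - out$mean[j]) / se
        p <- stats::ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE)
        share <- any(strsplit(out$letters[i], "")[[1]] %in%
                       strsplit(out$letters[j], "")[[1]])
        expect_equal(share, p >= 0.05,
                     info = sprintf("trial %d pair (%d,%d)", trial, i, j))
      }
    }
  }
})

test_that("validation compares simulated LOS with the observed statistics", {
  out <- validate_model(tight_config("dedicated"), replications = 2L, seed = 1L)
  expect_equal(out$type, 1:4)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_equal(out$valid, out$p_value >= 0.05)
})
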