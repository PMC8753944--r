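test_that("closed-form service means match the published station parameters", {
  specs <- service_specs_default()
  expect_equal(mean_service(specs$blood_pressure), 49)
  expect_equal(mean_service(specs$triage), 25 + 71.2)
  expect_equal(mean_service(specs$fill_info), 300)
  expect_equal(mean_service(specs$mr_type1), 14 + 47.4 * gamma(1 + 1 / 0.94))
  expect_equal(mean_service(specs$mr_type1), 62.8, tolerance = 1e-3)
  expect_equal(mean_service(specs$mr_type3), (84 + 146.8 + 251) / 3)
  expect_equal(mean_service(specs$mr_type4), 109.6)
})

test_that("deterministic sampling returns the mean; stochastic draws respect support", {
  specs <- service_specs_default()
  expect_equal(sample_service(specs$triage, 3, deterministic = TRUE),
               rep(96.2, 3))
  set.seed(1)
  tri <- sample_service(specs$mr_type3, 1e4)
  expect_true(all(tri >= 84 & tri <= 251))
  wb <- sample_service(specs$mr_type1, 1e4)
  expect_true(all(wb >= 14))
  ex <- sample_service(specs$triage, 1e4)
  expect_true(all(ex >= 25))
})

test_that("sample means converge to the closed-form means", {
  set.seed(7)
  n <- 1e5
  for (nm in names(service_specs_default())) {
    spec <- service_specs_default()[[nm]]
    x <- sample_service(spec, n)
    se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - mean_service(spec)), max(3 * se, 1e-9))
  }
})

test_that("interarrival draws carry the segment shift", {
  segs <- arrival_segments_default()
  set.seed(3)
  x <- sample_interarrival(segs[2, ], 1e5)   # 0.5 + EXPO(1.24)
  expect_true(all(x > 0.5))
  expect_lt(abs(mean(x) - (0.5 + 1.24)), 3 * stats::sd(x) / sqrt(1e5))
  y <- sample_interarrival(segs[3, ], 1e5)   # EXPO(2.67)
  expect_lt(abs(mean(y) - 2.67), 0.03)
})

test_that("triangular sampler matches closed-form moments", {
  set.seed(11)
  x <- rtri(1e6, 59, 72.8, 197)
  expect_lt(abs(mean(x) - tri_mean(c(59, 72.8, 197))) / tri_mean(c(59, 72.8, 197)),
            0.005)
  expect_lt(abs(stats::sd(x) - tri_sd(c(59, 72.8, 197))) / tri_sd(c(59, 72.8, 197)),
            0.005)
})

test_that("patient types follow the window mix", {
  windows <- type_mix_default()
  set.seed(5)
  # degenerate window: all mass on type 1
  w1 <- data.frame(start = 0, end = 600, p1 = 1, p2 = 0, p3 = 0, p4 = 0)
  expect_true(all(assign_patient_type(w1, runif(100, 0, 600)) == 1L))
  # ticket time outside every window errors
  expect_error(assign_patient_type(windows, 650), "outside")
  # law of large numbers per window
  n <- 2e4
  for (w in seq_len(nrow(windows))) {
    tt <- runif(n, windows$start[w], windows$end[w] - 1e-6)
    ty <- assign_patient_type(windows, tt)
    for (k in 1:4) {
      p <- windows[[paste0("p", k)]][w]
      sigma <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(ty == k) - p), 3.5 * sigma + 1e-12)
    }
  }
})

test_that("service spec validation rejects malformed parameters", {
  expect_error(service_spec("x", "triangular", min = 100, mode = 50, max = 120),
               "min <= mode <= max")
  expect_error(service_spec("x", "shifted_exponential", shift = 5), "missing")
})
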