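test_that("endpoint exponential rate matches closed forms", {
  s <- count_series("m", "p", "control", c(0, 5), c(100, 100 * exp(1)))
  expect_equal(exponential_growth_rate(s)$value, 0.2)

  flat <- count_series("m", "p", "control", c(0, 2, 4), rep(500, 3))
  expect_equal(exponential_growth_rate(flat)$value, 0)

  # ~100-fold rise over 20 days
  rise <- count_series("m", "p", "control", c(0, 20), c(200, 20000))
  expect_equal(exponential_growth_rate(rise)$value, log(100) / 20)
  expect_equal(exponential_growth_rate(rise)$value, 0.2302585, tolerance = 1e-6)

  zero <- count_series("m", "p", "control", c(0, 2), c(100, 0))
  expect_error(exponential_growth_rate(zero), class = "gk_domain_error")
})

test_that("exponential rate uses only the requested window endpoints", {
  s <- count_series("m", "p", "control", c(0, 2, 4, 6), c(100, 900, 400, 800))
  est <- exponential_growth_rate(s, window = c(2, 6))
  expect_equal(est$value, (log(800) - log(900)) / 4)
  expect_equal(est$window, c(2, 6))
  expect_error(exponential_growth_rate(s, window = c(1, 6)),
               class = "gk_domain_error")
})

test_that("regression rate is exact on geometric series and matches lm", {
  s <- count_series("m", "p", "control", 0:3, 1000 * 1.1^(0:3))
  est <- linear_growth_rate(s)
  expect_equal(est$value, 0.1)
  expect_equal(est$fit_r2, 1)

  flat <- count_series("m", "p", "control", c(0, 2, 4), rep(800, 3))
  expect_equal(linear_growth_rate(flat)$value, 0)

  # noisy series: slope agrees with an independent lm fit
  set.seed(5)
  conc <- 1000 * exp(0.1 * seq(0, 20, 2)) * exp(rnorm(11, 0, 0.2))
  sn <- count_series("m", "p", "control", seq(0, 20, 2), conc)
  est2 <- linear_growth_rate(sn)
  expect_equal(est2$value, exp(oracle_log_slope(seq(0, 20, 2), conc)) - 1)
  expect_equal(est2$fit_r2, oracle_log_r2(seq(0, 20, 2), conc))

  # two-point series reduces to the endpoint estimator, transformed
  two <- count_series("m", "p", "control", c(0, 4), c(1000, 1500))
  mu3 <- exponential_growth_rate(two)$value
  expect_equal(linear_growth_rate(two)$value, exp(mu3) - 1)
})

test_that("zero counts are excluded from log fits and flagged", {
  s <- count_series("m", "p", "control", c(0, 2, 4, 6), c(1000, 0, 400, 200))
  est <- linear_growth_rate(s)
  expect_true("zero_count_interval" %in% est$flags)
  expect_equal(est$n_points, 3L)
  keep <- c(1, 3, 4)
  expect_equal(est$value,
               exp(oracle_log_slope(c(0, 4, 6), c(1000, 400, 200))) - 1)
  allzero <- count_series("m", "p", "control", c(0, 2, 4), c(1000, 0, 0))
  expect_error(linear_growth_rate(allzero), class = "gk_domain_error")
})

test_that("logarithmic mean: hand value, limit, bounds", {
  expect_equal(log_mean_concentration(1000, 100), 900 / log(10))
  expect_equal(log_mean_concentration(1000, 100), 390.865, tolerance = 1e-5)
  expect_equal(log_mean_concentration(500, 500), 500)
  # near-equal endpoints take the continuous limit
  expect_equal(log_mean_concentration(500, 500 * (1 + 1e-12)), 500)
  expect_error(log_mean_concentration(0, 10), class = "gk_domain_error")
  set.seed(7)
  for (i in 1:200) {
    b <- exp(runif(2, log(1e-3), log(1e6)))
    lm_ <- log_mean_concentration(b[1], b[2])
    expect_gte(lm_, min(b) - 1e-12 * min(b))
    expect_lte(lm_, max(b) + 1e-12 * max(b))
  }
})

test_that("clearance and ingestion follow their defining formulas", {
  expect_equal(clearance_rate(0.1, 0.1, 500), 0)
  expect_equal(as.numeric(clearance_rate(0.074, -0.126, 2000)), 1e-4)
  neg <- clearance_rate(0.05, 0.2, 1000)
  expect_lt(as.numeric(neg), 0)
  expect_identical(attr(neg, "flags"), "negative_clearance")
  expect_error(clearance_rate(0.1, 0, 0), class = "gk_domain_error")

  expect_equal(ingestion_rate(390.865, 1e-4), 0.0390865)
  expect_equal(ingestion_rate(1234, 0), 0)
  expect_equal(ingestion_rate(0, 5), 0)
})

test_that("decline-window detector agrees with a brute-force oracle", {
  oracle_window <- function(s, r2_min = 0.9, min_run = 3) {
    n <- length(s$days); best <- NULL; best_len <- 0
    for (i in 1:(n - 1)) for (j in i:n) {
      if (j - i + 1 < min_run) next
      prey <- s$prey_conc[i:j]
      if (any(prey <= 0) || any(diff(prey) >= 0)) next
      if (oracle_log_r2(s$days[i:j], prey) < r2_min) next
      if (j - i + 1 > best_len) { best <- c(s$days[i], s$days[j]); best_len <- j - i + 1 }
    }
    best
  }
  clean <- make_grazed(days = seq(0, 8, 2), prey = c(1000, 800, 400, 150, 40),
                       pred = rep(200, 5))
  expect_equal(detect_decline_window(clean), c(0, 8))
  expect_equal(detect_decline_window(clean), oracle_window(clean))

  up <- make_control(days = seq(0, 8, 2), prey = c(100, 200, 400, 800, 1600))
  expect_null(detect_decline_window(up))

  # growth first, clean decline afterwards
  days <- seq(0, 20, 2)
  prey <- c(1000, 1500, 2200, 2000, 1400, 950, 640, 430, 290, 195, 130)
  mix <- make_grazed(days = days, prey = prey, pred = rep(200, 11))
  expect_equal(detect_decline_window(mix), c(4, 20))
  expect_equal(detect_decline_window(mix), oracle_window(mix))

  # randomized series: always agree with the oracle
  set.seed(13)
  for (i in 1:25) {
    pr <- exp(cumsum(rnorm(9, -0.1, 0.5))) * 1000
    s <- make_grazed(days = seq(0, 16, 2), prey = pr, pred = rep(100, 9))
    expect_equal(detect_decline_window(s), oracle_window(s))
  }
})

test_that("a noisy but monotone wiggle fails the R2 criterion", {
  # strictly decreasing but strongly convex in log space: R2 below 0.9
  prey <- c(1000, 420, 400, 395, 393)
  s <- make_grazed(days = seq(0, 8, 2), prey = prey, pred = rep(100, 5))
  expect_lt(oracle_log_r2(seq(4, 8, 2), prey[3:5]), 0.99)
  w_strict <- detect_decline_window(s, r2_min = 0.995)
  expect_null(w_strict)
  expect_equal(detect_decline_window(s, r2_min = 0.5), c(0, 8))
})
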