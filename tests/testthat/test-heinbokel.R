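test_that("one-interval toy reproduces the hand-computed estimator chain", {
  ctrl <- make_control(days = c(0, 2), prey = c(1000, 1160))
  gr <- make_grazed(days = c(0, 2), prey = c(1000, 700), pred = c(200, 200))
  fit <- heinbokel(experiment(list(ctrl, gr)))
  r <- fit$rates
  expect_equal(nrow(r), 1)
  expect_equal(r$k, log(1.16) / 2)
  expect_equal(r$g, log(0.7) / 2)
  expect_equal(r$P, 200)
  expect_equal(r$F, (log(1.16) - log(0.7)) / (2 * 200))
  expect_equal(r$F, 1.262737e-3, tolerance = 1e-6)
  expect_equal(r$B_avg, 300 / log(10 / 7))
  expect_equal(r$B_avg, 841.102, tolerance = 1e-6)
  expect_equal(r$I, 1.062091, tolerance = 1e-6)
})

test_that("grazed identical to control gives zero clearance and ingestion", {
  days <- seq(0, 8, 2); prey <- c(1000, 1100, 1210, 1331, 1464.1)
  ctrl <- make_control(days = days, prey = prey)
  gr <- make_grazed(days = days, prey = prey, pred = rep(250, 5))
  fit <- heinbokel(experiment(list(ctrl, gr)))
  expect_equal(fit$rates$F, rep(0, 4))
  expect_equal(fit$rates$I, rep(0, 4))
})

test_that("noiseless constant-predator simulation recovers F_true exactly", {
  F_true <- 1e-4
  ctrl <- simulate_monoculture(k = 0.074, flask_id = "c", prey_strain = "p")
  gr <- simulate_grazing(
    sim_params(k = 0.074, F_true = F_true, C0 = 2000, mu_c = 0, noise = "none"),
    flask_id = "g", prey_strain = "p")
  fit <- heinbokel(experiment(list(ctrl, gr)))
  expect_equal(fit$rates$F, rep(F_true, 10), tolerance = 1e-12)
  expect_equal(fit$rates$P, rep(2000, 10), tolerance = 1e-12)
})

test_that("clearance recovery stays within 10% under predator growth (mu_c * dt <= 0.5)", {
  for (mu_c in c(0.05, 0.1, 0.15, 0.2, 0.25)) {
    for (F_true in c(2e-5, 5e-5, 1e-4)) {
      ctrl <- simulate_monoculture(k = 0.074, flask_id = "c", prey_strain = "p")
      gr <- simulate_grazing(
        sim_params(k = 0.074, F_true = F_true, C0 = 200, mu_c = mu_c, noise = "none"),
        flask_id = "g", prey_strain = "p")
      fit <- heinbokel(experiment(list(ctrl, gr)))
      expect_lt(max(abs(fit$rates$F - F_true) / F_true), 0.10)
    }
  }
})

test_that("I = B_avg * F holds for every emitted row and B_avg, P are endpoint-bounded", {
  fx <- make_fixture_experiment("strong_grazer", seed = 4)
  r <- grazing_table(fx$experiment)
  ok <- !is.na(r$F)
  expect_equal(r$I[ok], r$B_avg[ok] * r$F[ok])
  for (i in which(ok)) {
    s <- fx$experiment$series[[r$flask_id[i]]]
    j <- match(c(r$t_start[i], r$t_end[i]), s$days)
    expect_gte(r$B_avg[i], min(s$prey_conc[j]) * (1 - 1e-12))
    expect_lte(r$B_avg[i], max(s$prey_conc[j]) * (1 + 1e-12))
    expect_gte(r$P[i], min(s$predator_conc[j]) * (1 - 1e-12))
    expect_lte(r$P[i], max(s$predator_conc[j]) * (1 + 1e-12))
  }
})

test_that("mean recovered F is within 15% of truth under lognormal noise (20 replicates)", {
  F_true <- 1e-4
  set.seed(2024)
  Fhat <- replicate(20, {
    seeds <- sample.int(1e6, 2)
    ctrl <- simulate_monoculture(k = 0.074, noise = "lognormal", sigma = 0.1,
                                 seed = seeds[1], flask_id = "c", prey_strain = "p")
    gr <- simulate_grazing(
      sim_params(k = 0.074, F_true = F_true, C0 = 2000, mu_c = 0,
                 noise = "lognormal", sigma = 0.1, seed = seeds[2]),
      flask_id = "g", prey_strain = "p")
    mean(heinbokel(experiment(list(ctrl, gr)))$rates$F)
  })
  expect_lt(abs(mean(Fhat) - F_true) / F_true, 0.15)
})

test_that("decline_window mode flags intervals outside the window or with shrinking predator", {
  days <- seq(0, 12, 2)
  # prey grows to day 4 then declines cleanly; predator grows except the last step
  gr <- make_grazed(days = days, prey = c(1000, 1400, 1900, 1200, 700, 400, 230),
                    pred = c(200, 300, 450, 700, 1100, 1700, 1500))
  ctrl <- make_control(days = days, prey = 1000 * exp(0.07 * days))
  fit <- heinbokel(experiment(list(ctrl, gr)), mode = "decline_window")
  expect_equal(fit$windows[[gr$flask_id]], c(4, 12))
  flags <- fit$rates$flags
  outside <- grepl("outside_decline_window", flags)
  # intervals 0-2 and 2-4 are before the window; 10-12 has a shrinking predator
  expect_equal(fit$rates$t_start[outside], c(0, 2, 10))
  # summary averages only the in-window, predator-growing intervals
  kept <- fit$rates[!outside, ]
  expect_equal(fit$summary$mean_I, mean(kept$I))
  expect_equal(fit$summary$n_intervals, 3L)
})

test_that("zero-count intervals are flagged, NA-rated and excluded from summaries", {
  days <- seq(0, 6, 2)
  gr <- make_grazed(days = days, prey = c(1000, 400, 0, 0), pred = c(200, 400, 800, 1600))
  ctrl <- make_control(days = days, prey = c(1000, 1100, 1210, 1331))
  fit <- heinbokel(experiment(list(ctrl, gr)))
  r <- fit$rates
  expect_true(all(grepl("zero_count_interval", r$flags[2:3])))
  expect_true(all(is.na(r$F[2:3])))
  expect_false(anyNA(fit$summary$mean_F))
  expect_equal(fit$summary$n_intervals, 1L)
})

test_that("global_k uses the control's full-series rate for every interval", {
  days <- seq(0, 6, 2)
  ctrl <- make_control(days = days, prey = c(1000, 1000, 1200, 1500))
  gr <- make_grazed(days = days, prey = c(1000, 900, 800, 700), pred = rep(300, 4))
  fit <- heinbokel(experiment(list(ctrl, gr)), global_k = TRUE)
  k_global <- (log(1500) - log(1000)) / 6
  expect_equal(fit$rates$k, rep(k_global, 3))
  per <- heinbokel(experiment(list(ctrl, gr)))
  expect_false(all(per$rates$k == k_global))
})

test_that("missing control match raises a configuration error", {
  gr <- make_grazed()
  ctrl_other <- make_control(strain = "preyB")
  ex <- experiment(list(ctrl_other, gr), check_controls = FALSE)
  expect_error(heinbokel(ex), class = "gk_config_error")
  expect_error(heinbokel(toy_experiment(), predator_strain = "nope"),
               class = "gk_config_error")
})

test_that("fit object methods work", {
  fx <- make_fixture_experiment("strong_grazer", seed = 1)
  fit <- heinbokel(fx$experiment, mode = "decline_window")
  expect_output(print(fit), "Heinbokel")
  expect_output(print(summary(fit)), "decline windows")
  cf <- coef(fit)
  expect_true(is.matrix(cf) && all(colnames(cf) == c("k", "g", "F", "I")))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
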