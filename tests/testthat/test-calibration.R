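test_that("normalized RMSE matches its definition", {
  expect_equal(normalized_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(normalized_rmse(c(1, 3), c(1, 1)), sqrt(2) / 2)
  obs <- c(2, 5, 9)
  expect_equal(normalized_rmse(obs, 2 * obs),
               sqrt(mean(obs^2)) / mean(obs))
  expect_warning(nr <- normalized_rmse(c(0, 0), c(1, 1)), "zero")
  expect_true(is.na(nr))
})

test_that("observation sets validate their invariants", {
  expect_error(gdm_observations(c(3, 2), c(1, 1), c(1, 2), 0, 10, 10),
               "increasing")
  expect_error(gdm_observations(c(3, 7), c(1, 1), c(2, 1), 0, 10, 10),
               "nondecreasing")
  expect_error(gdm_observations(c(3, 7), c(1, -1), c(1, 2), 0, 10, 10),
               ">= 0")
  obs <- gdm_observations(c(3, 7), c(1, 1), c(1, 2), c(0, 7), c(10, 9),
                          c(20, 18))
  expect_s3_class(obs, "gdm_observations")
  expect_output(print(obs), "observation")
})

test_that("objective is zero exactly at the generating parameters", {
  p <- test_params()
  obs <- generate_observations(p, noise_cv = 0, seed = 1)
  expect_equal(gdm_objective(c(lci_t = 0.42, k_b22 = 29), p, obs), 0,
               tolerance = 1e-10)
  # any perturbation on noise-free data increases the objective
  expect_gt(gdm_objective(c(lci_t = 0.42, k_b22 = 34), p, obs), 0)
  expect_gt(gdm_objective(c(lci_t = 0.47, k_b22 = 29), p, obs), 1e-8)
  # local-minimum grid: truth beats its neighbours
  at <- function(l, k) gdm_objective(c(lci_t = l, k_b22 = k), p, obs)
  f0 <- at(0.42, 29)
  for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 5), c(0, -5)))
    expect_lte(f0, at(0.42 + d[1], 29 + d[2]))
  # invalid values give the penalty, not an error
  expect_equal(gdm_objective(c(lci_t = 2, k_b22 = 29), p, obs), 1e6)
})

test_that("calibration recovers generating parameters on noise-free data", {
  p <- test_params()
  obs <- generate_observations(p, noise_cv = 0, seed = 1)
  # start the search away from the truth
  pstart <- update_params(p, lci_t = 0.55, k_b22 = 60)
  fit <- gdm_calibrate(obs, pstart, n_starts = 2, seed = 1)
  expect_s3_class(fit, "gdm_fit")
  expect_lt(abs(coef(fit)[["k_b22"]] - 29) / 29, 0.01)
  expect_lt(abs(coef(fit)[["lci_t"]] - 0.42) / 0.42, 0.01)
  expect_lt(fit$objective, 1e-4)
  expect_equal(fit$convergence, 0)
  # best-fit within bounds
  expect_true(all(coef(fit) >= fit$bounds$lower - 1e-12))
  expect_true(all(coef(fit) <= fit$bounds$upper + 1e-12))
  # starting at the truth stays there
  fit0 <- gdm_calibrate(obs, p, n_starts = 1)
  expect_lt(fit0$objective, 1e-5)
})

test_that("fit methods expose streams, residuals and simulations", {
  p <- test_params()
  obs <- generate_observations(p, noise_cv = 0, seed = 2)
  fit <- gdm_calibrate(obs, p, n_starts = 1)
  expect_output(print(fit), "best-fit")
  expect_output(print(summary(fit)), "normalized RMSE")
  sim <- predict(fit)
  expect_named(sim, c("co2_rate", "cum_co2", "c1", "c2"))
  expect_equal(length(sim$co2_rate), length(obs$co2_days))
  res <- residuals(fit)
  expect_lt(max(abs(unlist(res))), 1e-4)
  tr <- predict(fit, "trajectory")
  expect_s3_class(tr, "gdm_trajectory")
  sims <- simulate(fit, nsim = 2, seed = 9, noise_cv = 0.05)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "gdm_observations")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  stats <- gdm_fit_statistics(fit, obs)
  expect_true(all(stats$r2 > 0.999))
  expect_true(all(abs(stats$final_rel_diff) < 1e-3))
})

test_that("k_b22 recovery degrades monotonically with measurement noise", {
  p <- test_params()
  pstart <- update_params(p, k_b22 = 60)
  med <- vapply(c(0, 0.02, 0.05, 0.10), function(cv) {
    errs <- vapply(1:9, function(k) {
      obs <- generate_observations(p, noise_cv = cv, seed = 300 + k)
      fit <- gdm_calibrate(obs, pstart, free = "k_b22", n_starts = 2,
                           seed = k)
      abs(coef(fit)[["k_b22"]] - 29) / 29
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) >= -1e-6))
})

test_that("calibration bound handling rejects impossible problems", {
  p <- test_params()
  obs <- generate_observations(p, noise_cv = 0, seed = 3)
  expect_error(gdm_calibrate(obs, p, lower = list(lci_t = 0.6),
                             upper = list(lci_t = 0.5), n_starts = 1),
               "bounds")
  expect_error(gdm_calibrate(obs, p, free = c("lci_t", "e2"), n_starts = 1),
               "finite bounds")
})
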