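test_that("derived indices follow their definitions and scale invariance", {
  ch <- litter_chemistry(kl = 397, glu = 700, ara = 90, xyl = 380,
                         gal = 40, uronic = 28, c_sol = 364)
  idx <- derive_indices(ch)
  expect_equal(idx$sum_sug, 1238)
  expect_equal(round(idx$lci, 4), 0.2428)
  expect_equal(idx$ax, 90 / 380)
  expect_equal(idx$kl_ax, 397 / (90 / 380))
  expect_true(is.na(idx$cn))
  # zero arabinan gives A:X of 0; zero lignin gives LCI of 0
  expect_equal(derive_indices(litter_chemistry(kl = 397, glu = 1, ara = 0,
                                               xyl = 1, gal = 0,
                                               uronic = 0))$ax, 0)
  expect_equal(derive_indices(litter_chemistry(kl = 0, glu = 700, ara = 90,
                                               xyl = 380, gal = 40,
                                               uronic = 28))$lci, 0)
  expect_error(derive_indices(litter_chemistry(kl = 1, glu = 1, ara = 1,
                                               xyl = 0, gal = 0,
                                               uronic = 0)), "A:X")
  # ratios unchanged under rescaling of all concentrations
  ch2 <- litter_chemistry(kl = 3.97, glu = 7, ara = 0.9, xyl = 3.8,
                          gal = 0.4, uronic = 0.28, c_sol = 3.64)
  idx2 <- derive_indices(ch2)
  expect_equal(idx2$ax, idx$ax)
  expect_equal(idx2$lci, idx$lci, tolerance = 1e-12)
})

test_that("interval decay coefficients are log-linear and additive", {
  expect_equal(decay_coefficient(100, 100, 0, 14), 0)
  expect_equal(decay_coefficient(100, 50, 0, 14), log(2) / 14)
  expect_equal(round(decay_coefficient(100, 50, 0, 14), 4), 0.0495)
  expect_equal(decay_coefficient(50, 100, 0, 14),
               -decay_coefficient(100, 50, 0, 14))
  expect_error(decay_coefficient(0, 50, 0, 14), "> 0")
  expect_error(decay_coefficient(100, 50, 14, 14), "exceed")
  # chain identity: duration-weighted mean of interval coefficients
  k1 <- decay_coefficient(100, 80, 0, 14)
  k2 <- decay_coefficient(80, 30, 14, 57)
  ktot <- decay_coefficient(100, 30, 0, 57)
  expect_equal((14 * k1 + 43 * k2) / 57, ktot)
})

test_that("mass reconstruction from CO2 efflux", {
  expect_equal(remaining_mass_from_co2(2000, 0), 2000)
  expect_equal(remaining_mass_from_co2(2000, 2000), 0)
  expect_equal(remaining_mass_from_co2(2000, 750), 1250)
  expect_error(remaining_mass_from_co2(2000, 2001), "exceeds")
  expect_equal(pool_from_concentration(0.2, 1500), 300)
  expect_equal(pool_from_concentration(0, 1500), 0)
  expect_equal(pool_from_concentration(0.2, 0), 0)
})

test_that("k2max estimation recovers the intercept of the k2-LCI line", {
  lci <- c(0.25, 0.3, 0.35, 0.4, 0.45, 0.5)
  exact <- list(lci = lci, k2 = -0.067 * lci + 0.047)
  fit <- estimate_k2max(exact)
  expect_equal(fit$intercept, 0.047, tolerance = 1e-10)
  expect_equal(fit$slope, -0.067, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  const <- list(lci = lci, k2 = rep(0.02, 6))
  fitc <- estimate_k2max(const)
  expect_equal(fitc$slope, 0)
  expect_equal(fitc$intercept, 0.02)
  expect_error(estimate_k2max(list(lci = rep(0.3, 5), k2 = 1:5)),
               "variance")
  expect_error(estimate_k2max(list(lci = c(0.1, 0.2), k2 = c(1, 2))),
               "3 points")
  # noisy recovery, seeded
  set.seed(99)
  lci12 <- seq(0.2, 0.6, length.out = 12)
  k2n <- -0.067 * lci12 + 0.047 + rnorm(12, 0, 0.002)
  fitn <- estimate_k2max(list(lci = lci12, k2 = k2n))
  expect_lt(abs(fitn$intercept - 0.047), 0.004)
})

test_that("printed transfer maps and their clamps", {
  expect_equal(transfer_lci_t(0), 0.70)
  expect_equal(transfer_lci_t(0.778), 0.42, tolerance = 1e-3)
  expect_warning(v <- transfer_kb22(0), "clamped")
  expect_equal(v, 1)
  expect_equal(transfer_kb22(1), 53.22 - 13.65)
  expect_warning(c1t <- transfer_c1t(0), "clamped")
  expect_equal(c1t, 0)
  expect_equal(transfer_c1t(60), 0.02 * 60 - 0.64)
})

test_that("fitted transfer maps reproduce the printed coefficients", {
  # invert the printed lci_t map to get exactly collinear chemistry inputs
  lci_t <- c(0.42, 0.36, 0.46, 0.45)
  kl_ax <- (0.70 - lci_t) / 0.36
  tm <- fit_transfer_model(kl_ax, lci_t)
  expect_equal(tm$slope, -0.36, tolerance = 1e-10)
  expect_equal(tm$intercept, 0.70, tolerance = 1e-10)
  expect_equal(tm$r2, 1)
  expect_equal(predict(tm, 0.778), transfer_lci_t(0.778), tolerance = 1e-9)
  kb22 <- c(29, 33, 23, 19)
  tm2 <- fit_transfer_model((kb22 + 13.65) / 53.22, kb22)
  expect_equal(tm2$slope, 53.22, tolerance = 1e-9)
  expect_equal(tm2$intercept, -13.65, tolerance = 1e-9)
  expect_error(fit_transfer_model(c(1, 1), c(2, 3)), "variance")
  expect_output(print(tm), "Transfer map")
})

test_that("extrapolation builds a valid parameter set from chemistry", {
  # inputs on the scale of the fitted transfer maps (see package docs on
  # the unit conventions of the printed regressions)
  ch <- litter_chemistry(kl = 0.2, glu = 33, ara = 4.5, xyl = 18,
                         gal = 3, uronic = 1.5, c_sol = 15)
  p <- gdm_extrapolate(ch, genotype = "new")
  expect_s3_class(p, "gdm_params")
  expect_equal(p$c1 + p$c2 + p$c3, 2000)
  idx <- derive_indices(ch)
  expect_equal(p$lci_t, transfer_lci_t(idx$kl_ax))
  expect_equal(p$k_b22, transfer_kb22(idx$kl_ax))
  tr <- gdm_simulate(p, t_end = 20)
  expect_true(all(is.finite(tr$cum_co2)))
})
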