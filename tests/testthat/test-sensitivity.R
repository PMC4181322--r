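test_that("perturbation draws are uniform, bounded and reproducible", {
  base <- test_params()
  d0 <- perturbation_design(range = 0, n = 5, seed = 1)
  sets <- draw_design(d0, base)
  expect_true(all(vapply(sets, function(p) p$e2 == base$e2, logical(1))))
  d1 <- perturbation_design(n = 20, seed = 7)
  expect_identical(attr(draw_design(d1, base), "draws"),
                   attr(draw_design(d1, base), "draws"))
  d2 <- perturbation_design(n = 1e4, seed = 3)
  draws <- attr(draw_design(d2, base), "draws")
  expect_lt(abs(mean(draws$e2) - 0.3) / 0.3, 0.005)
  expect_gte(min(draws$e2), 0.27)
  expect_lte(max(draws$e2), 0.33)
  expect_error(perturbation_design(range = 1.2), "range")
  expect_error(perturbation_design(n = 1), "n must")
})

test_that("composite relative difference is a signed sum", {
  expect_equal(composite_relative_difference(c(5, 6), c(5, 6)), 0)
  expect_equal(composite_relative_difference(c(10, 10), c(9, 11)), 0)
  expect_equal(composite_relative_difference(c(10, 20), c(8, 15)), 0.45)
  expect_warning(v <- composite_relative_difference(c(0, 10), c(1, 5)),
                 "zero")
  expect_equal(v, 0.5)
})

# builds a sensitivity-shaped table from a design without running simulations
fake_table <- function(design, base, response_fun, genotype = "G") {
  draws <- attr(draw_design(design, base), "draws")
  resp <- response_fun(draws)
  out <- cbind(data.frame(genotype = genotype,
                          replicate = seq_len(design$n)),
               draws,
               data.frame(resp_c1 = resp, resp_c2 = resp,
                          resp_cum_co2 = resp, resp_resp_rate = resp,
                          resp_overall = 4 * resp))
  structure(out, class = c("gdm_sensitivity", "data.frame"), design = design)
}

test_that("variance partition attributes a pure linear response to its driver", {
  base <- test_params()
  des <- perturbation_design(n = 200, seed = 11)
  set.seed(1)
  tab <- fake_table(des, base,
                    function(d) 7 * d$e2 + rnorm(nrow(d), 0, 1e-8))
  part <- partition_variance(tab)
  row <- part[part$response == "resp_c1", ]
  # finite-sample covariate correlations leave ~1% unattributed
  expect_gt(row$e2, 98)
  expect_lt(max(row$e1, row$k1max, row$bc_max, row$k_b11), 2)
  expect_lt(row$sig_e2, 1e-6)
  # a response unrelated to every parameter gets ~0% everywhere
  set.seed(2)
  tab0 <- fake_table(des, base, function(d) rnorm(nrow(d)))
  part0 <- partition_variance(tab0)
  r0 <- part0[part0$response == "resp_c2", ]
  expect_lt(max(unlist(r0[, c("e1", "e2", "k1max", "bc_max", "k_b11")])), 5)
})

test_that("partition shares match analytic variance shares and invariances", {
  base <- test_params()
  des <- perturbation_design(n = 1000, seed = 5)
  a <- 3; b <- 40
  set.seed(3)
  tab <- fake_table(des, base,
                    function(d) a * d$e2 + b * d$bc_max +
                      rnorm(nrow(d), 0, 1e-6))
  part <- partition_variance(tab)
  row <- part[part$response == "resp_c1", ]
  # uniform on +/-10% of base: Var = (0.2 * base)^2 / 12
  v_e2 <- a^2 * (0.2 * base$e2)^2 / 12
  v_bc <- b^2 * (0.2 * base$bc_max)^2 / 12
  expect_lt(abs(row$e2 - 100 * v_e2 / (v_e2 + v_bc)), 5)       # pp
  expect_lt(abs(row$bc_max - 100 * v_bc / (v_e2 + v_bc)), 5)   # pp
  # percentages sum to 100 within a response
  pars <- c("e1", "e2", "k1max", "bc_max", "k_b11")
  expect_equal(sum(unlist(row[pars])) + row$residual, 100)
  # scale invariance of the response
  tab2 <- tab
  for (cl in grep("^resp_", names(tab2), value = TRUE))
    tab2[[cl]] <- 1000 * tab2[[cl]]
  part2 <- partition_variance(tab2)
  expect_equal(part2[part2$response == "resp_c1", pars],
               part[part$response == "resp_c1", pars], tolerance = 1e-9)
  # identical design + seed: identical partition
  set.seed(3)
  tab3 <- fake_table(des, base,
                     function(d) a * d$e2 + b * d$bc_max +
                       rnorm(nrow(d), 0, 1e-6))
  expect_identical(partition_variance(tab3), part)
})

test_that("drop-one type II sums of squares agree with car::Anova", {
  skip_if_not_installed("car")
  base <- test_params()
  des <- perturbation_design(n = 60, seed = 13)
  set.seed(4)
  tab <- fake_table(des, base,
                    function(d) 2 * d$e2 - 5 * d$bc_max + 0.4 * d$k1max +
                      rnorm(nrow(d), 0, 0.01))
  part <- partition_variance(tab)
  pars <- c("e1", "e2", "k1max", "bc_max", "k_b11")
  fit <- stats::lm(stats::reformulate(pars, "resp_c1"), data = tab)
  ca <- car::Anova(fit, type = 2)
  tss <- sum((tab$resp_c1 - mean(tab$resp_c1))^2)
  expect_equal(unlist(part[part$response == "resp_c1", pars]),
               setNames(100 * ca[pars, "Sum Sq"] / tss, pars),
               tolerance = 1e-8)
})

test_that("the end-to-end perturbation experiment is reproducible", {
  p <- test_params()
  obs <- generate_observations(p, noise_cv = 0, seed = 21)
  des <- perturbation_design(n = 12, seed = 2)
  tab <- gdm_sensitivity(p, obs, des)
  expect_equal(nrow(tab), 12)
  expect_true(all(is.finite(unlist(tab[, grep("^resp_",
                                              names(tab))]))))
  expect_equal(tab$resp_overall,
               tab$resp_c1 + tab$resp_c2 + tab$resp_cum_co2 +
                 tab$resp_resp_rate)
  expect_identical(as.data.frame(gdm_sensitivity(p, obs, des)),
                   as.data.frame(tab))
  part <- partition_variance(tab)
  expect_equal(nrow(part), 5)
  expect_error(partition_variance(tab[1:5, ]), ">= 10")
  # Table-2-shaped CSV output
  path <- tempfile(fileext = ".csv")
  write_partition_csv(part, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 5)
  expect_true(all(c("response", "genotype", "e2", "residual") %in%
                    names(got)))
})
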