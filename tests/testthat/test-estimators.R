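test_that("Wald ratio arithmetic and precondition", {
  e <- mr_wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$se, 0.1, tolerance = 1e-12)
  expect_equal(e$or, exp(e$beta))
  expect_equal(mr_wald_ratio(0.1, 0.01, 0, 0.01)$beta, 0)
  expect_error(mr_wald_ratio(0, 0.01, 0.05, 0.01),
               class = "mrpath_error_undefined_ratio")
})

test_that("IVW equals the WLS-through-origin closed form to 10+ digits", {
  h <- h3()
  est <- mr_ivw(h)
  expect_same_to_digits(est$beta, oracle_ivw(h))
  # homogeneous ratios give that ratio exactly, fixed == random
  hh <- make_harmonized(c(0.1, 0.2, 0.4), 0.01, c(0.05, 0.10, 0.20), 0.01)
  expect_equal(mr_ivw(hh, "fixed")$beta, 0.5, tolerance = 1e-12)
  expect_equal(mr_ivw(hh, "fixed")$se, mr_ivw(hh, "random")$se)
  # fixed se <= random se always
  set.seed(3)
  for (i in 1:20) {
    hr <- make_harmonized(rnorm(5, 0.1, 0.03), 0.01,
                          rnorm(5, 0.02, 0.02), runif(5, 0.005, 0.02))
    expect_lte(mr_ivw(hr, "fixed")$se, mr_ivw(hr, "random")$se)
  }
  expect_error(mr_ivw(h[1, ]),
               class = "mrpath_error_insufficient_instruments")
})

test_that("two-SNP equal-weight IVW is the weight-averaged Wald ratio", {
  h <- make_harmonized(c(0.1, 0.2), 0.01, c(0.06, 0.08), c(0.01, 0.01))
  # with equal se_y, weights on the ratios are proportional to beta_x^2
  r <- h$beta_y / h$beta_x
  w <- h$beta_x^2
  expect_equal(mr_ivw(h)$beta, sum(w * r) / sum(w), tolerance = 1e-12)
})

test_that("Egger matches WLS-with-intercept closed form and is exact on noiseless lines", {
  h <- h3()
  est <- mr_egger(h)
  ora <- oracle_egger(h)
  expect_same_to_digits(est$egger_intercept, ora[1])
  expect_same_to_digits(est$beta, ora[2])
  # exact fit: data on a line Gamma = a + theta * gamma
  hx <- make_harmonized(c(0.05, 0.1, 0.2, 0.3), 0.01,
                        0.02 + 0.4 * c(0.05, 0.1, 0.2, 0.3), 0.01)
  ex <- mr_egger(hx)
  expect_equal(ex$egger_intercept, 0.02, tolerance = 1e-10)
  expect_equal(ex$beta, 0.4, tolerance = 1e-10)
  expect_error(mr_egger(h3()[1:2, ]),
               class = "mrpath_error_insufficient_instruments")
})

test_that("weighted median matches the brute-force interpolated weighted quantile", {
  # equal weights, symmetric ratios -> middle ratio
  h <- make_harmonized(c(0.1, 0.1, 0.1), 0.01,
                       c(0.01, 0.05, 0.09), c(0.01, 0.01, 0.01))
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.5, tolerance = 1e-12)
  # 5-SNP fixture vs oracle
  h5 <- make_harmonized(c(0.10, 0.15, 0.20, 0.12, 0.30), 0.01,
                        c(0.03, 0.09, 0.07, 0.08, 0.12),
                        c(0.010, 0.012, 0.008, 0.015, 0.011))
  got <- mr_weighted_median(h5, n_boot = 0)$beta
  want <- oracle_weighted_median(h5$beta_y / h5$beta_x,
                                 h5$beta_x^2 / h5$se_y^2)
  expect_same_to_digits(got, want)
  # all-equal weights equals the interpolated ordinary median
  he <- make_harmonized(rep(0.1, 4), 0.01,
                        c(0.002, 0.004, 0.011, 0.013), rep(0.01, 4))
  expect_equal(mr_weighted_median(he, n_boot = 0)$beta,
               oracle_weighted_median(he$beta_y / he$beta_x, rep(1, 4)),
               tolerance = 1e-12)
  # dominant-weight SNP pins the estimate to its own ratio
  hd <- make_harmonized(c(0.5, 0.05, 0.05), c(0.01, 0.01, 0.01),
                        c(0.15, 0.04, 0.05), c(0.005, 0.05, 0.05))
  expect_equal(mr_weighted_median(hd, n_boot = 0)$beta, 0.3,
               tolerance = 1e-3)
})

test_that("mode estimators match the independent grid oracle and handle degeneracy", {
  set.seed(11)
  m <- 9
  bx <- runif(m, 0.05, 0.3)
  h9 <- make_harmonized(bx, 0.01,
                        bx * c(rep(0.5, 6), rep(2.0, 3)) + rnorm(m, 0, 0.002),
                        runif(m, 0.008, 0.02))
  r <- h9$beta_y / h9$beta_x
  wv <- h9$se_y^2 / h9$beta_x^2
  expect_same_to_digits(mr_mode(h9, weighted = TRUE, n_boot = 0)$beta,
                        oracle_mode(r, 1 / wv))
  expect_same_to_digits(mr_mode(h9, weighted = FALSE, n_boot = 0)$beta,
                        oracle_mode(r, rep(1, m)))
  # majority cluster wins under equal weights
  set.seed(2)
  bx2 <- runif(9, 0.1, 0.3)
  ratios <- c(0.5 + rnorm(7, 0, 0.01), 2.0 + rnorm(2, 0, 0.01))
  hm <- make_harmonized(bx2, 0.01, bx2 * ratios, 0.01)
  expect_equal(mr_mode(hm, weighted = FALSE, n_boot = 0)$beta, 0.5,
               tolerance = 0.1)
  # identical ratios: degenerate bandwidth returns the common value
  hc <- make_harmonized(c(0.1, 0.2, 0.3), 0.01, c(0.03, 0.06, 0.09), 0.01)
  expect_equal(mr_mode(hc, n_boot = 0)$beta, 0.3, tolerance = 1e-12)
})

test_that("run_all_methods returns five estimates, degrades gracefully, and is deterministic", {
  sim <- simulate_pair(sim_config(m_snps = 10, seed = 5))
  h <- harmonize(sim$exposure, sim$outcome)
  r1 <- run_all_methods(h, seed = 99, n_boot = 50)
  expect_setequal(r1$method, c("ivw", "egger", "weighted_median",
                               "weighted_mode", "simple_mode"))
  expect_true(all(r1$or == exp(r1$beta)))
  expect_true(all(r1$ci_low <= r1$ci_high))
  r2 <- run_all_methods(h, seed = 99, n_boot = 50)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  # degradation
  expect_equal(run_all_methods(h[1, ])$method, "wald_ratio")
  expect_equal(run_all_methods(h[1:2, ])$method, "ivw")
})

test_that("direction consistency requires one strict shared sign", {
  mk <- function(betas) tibble::tibble(beta = betas)
  expect_true(direction_consistent(mk(c(0.1, 0.2, 0.05, 0.3, 0.15))))
  expect_false(direction_consistent(mk(c(0.1, -0.01, 0.2, 0.3, 0.15))))
  expect_true(direction_consistent(mk(-0.2)))
  expect_false(direction_consistent(mk(c(0, 0.1))))
})

test_that("log-OR and OR round-trip at printed precision", {
  h <- make_harmonized(c(0.1, 0.2, 0.4), 0.01,
                       log(1.195) * c(0.1, 0.2, 0.4), 0.01)
  est <- mr_ivw(h)
  expect_equal(est$or, 1.195, tolerance = 1e-10)
})
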