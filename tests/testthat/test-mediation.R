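test_that("the four screening gates flip independently and conjoin", {
  base_est <- structure(tibble::tibble(
    method = c("ivw", "egger", "weighted_median", "weighted_mode",
               "simple_mode"),
    beta = c(0.10, 0.12, 0.09, 0.11, 0.10),
    pvalue = c(0.01, 0.2, 0.05, 0.1, 0.1)),
    exposure_id = "X", outcome_id = "Y")
  base_sens <- list(presso_global_p = 0.4, egger_intercept_p = 0.3)
  expect_true(screen(base_est, base_sens)$passed)

  weak_ivw <- base_est; weak_ivw$pvalue[1] <- 0.06
  d <- screen(weak_ivw, base_sens)
  expect_false(d$passed)
  expect_true(d$direction_ok && d$presso_ok && d$pleiotropy_ok)

  flipped <- base_est; flipped$beta[3] <- -0.01
  d <- screen(flipped, base_sens)
  expect_false(d$passed); expect_false(d$direction_ok)
  expect_true(d$presso_ok && d$pleiotropy_ok)

  d <- screen(base_est, list(presso_global_p = 0.01,
                             egger_intercept_p = 0.3))
  expect_false(d$passed); expect_false(d$presso_ok)

  d <- screen(base_est, list(presso_global_p = 0.4,
                             egger_intercept_p = 0.04))
  expect_false(d$passed); expect_false(d$pleiotropy_ok)

  # unavailable diagnostics fail conservatively
  d <- screen(base_est, list(presso_global_p = NA_real_,
                             egger_intercept_p = 0.3))
  expect_false(d$presso_ok)
})

test_that("screening is monotone: improving one gate never un-passes a decision", {
  est <- structure(tibble::tibble(
    method = c("ivw", "egger"), beta = c(0.1, 0.12),
    pvalue = c(0.03, 0.2)), exposure_id = "X", outcome_id = "Y")
  sens <- list(presso_global_p = 0.10, egger_intercept_p = 0.08)
  d0 <- screen(est, sens)
  est2 <- est; est2$pvalue[1] <- est$pvalue[1] / 2
  sens2 <- list(presso_global_p = 0.5, egger_intercept_p = 0.6)
  d1 <- screen(est2, sens2)
  expect_gte(d1$passed, d0$passed)
})

test_that("adjusted mediator instruments drop shared SNPs and their LD partners", {
  med <- make_sumstats(c("a", "b", "c", "d"), beta = 0.1, se = 0.01,
                       pvalue = 1e-8)
  expo <- make_sumstats(c("x", "y"), beta = 0.1, se = 0.01, pvalue = 1e-8)
  expect_equal(adjusted_mediator_instruments(med, expo)$snp_id,
               c("a", "b", "c", "d"))  # disjoint -> unchanged
  shared <- make_sumstats(c("b", "z"), beta = 0.1, se = 0.01, pvalue = 1e-8)
  expect_equal(adjusted_mediator_instruments(med, shared)$snp_id,
               c("a", "c", "d"))
  # LD partner of a shared SNP removed too
  ids <- c("a", "b", "c", "d", "z")
  r2 <- diag(5)
  r2[2, 3] <- r2[3, 2] <- 0.5  # c in LD with shared b
  ld <- ld_matrix(ids, r2)
  expect_equal(adjusted_mediator_instruments(med, shared, ld)$snp_id,
               c("a", "d"))
  all_shared <- make_sumstats(c("a", "b", "c", "d"), beta = 0.1,
                              se = 0.01, pvalue = 1e-8)
  expect_error(adjusted_mediator_instruments(med, all_shared),
               class = "mrpath_error_no_instruments")
})

test_that("Sobel product-of-coefficients matches the closed form and is symmetric", {
  s <- sobel(0.5, 0.1, 0.4, 0.1)
  expect_equal(s$indirect, 0.2, tolerance = 1e-12)
  expect_equal(s$indirect_se, sqrt(0.25 * 0.01 + 0.16 * 0.01),
               tolerance = 1e-12)
  expect_equal(s$z, 0.2 / sqrt(0.0041), tolerance = 1e-12)
  expect_equal(s$z, 3.1235, tolerance = 1e-4)
  # zero leg
  s0 <- sobel(0, 0.1, 0.4, 0.1)
  expect_equal(s0$indirect, 0)
  expect_equal(s0$z, 0)
  expect_equal(s0$pvalue, 1)
  # swapping legs changes nothing
  expect_equal(sobel(0.4, 0.1, 0.5, 0.1), s)
  # z / CI internal consistency at the same normal quantile
  for (z in c(1.9, 1.96, 2.0, -2.5)) {
    si <- sobel(z * 0.1, 0.1, 1, 1e-9)
    expect_equal(abs(si$z) >= qnorm(0.975),
                 si$ci_low > 0 || si$ci_high < 0)
  }
})

test_that("mediated proportion is a signed percentage with an inconsistency flag", {
  expect_equal(mediated_proportion(0.2, 0.5)$proportion_pct, 40)
  p <- mediated_proportion(-0.1, 0.5)
  expect_equal(p$proportion_pct, -20)
  expect_true(p$inconsistent)
  expect_false(mediated_proportion(0.2, 0.5)$inconsistent)
  expect_error(mediated_proportion(0.2, 0),
               class = "mrpath_error_undefined_proportion")
})

test_that("run_mediation recovers planted effects and is deterministic", {
  cfg <- sim_config(m_snps = 40, seed = 314, theta_xm = 0.3, theta_my = 0.2,
                    direct_xy = 0.4)
  trip <- simulate_mediation_triple(cfg)
  expect_equal(trip$truth$proportion_pct, 100 * 0.06 / 0.46)
  res <- suppressWarnings(run_mediation(
    trip$exposure, trip$mediator, trip$outcome,
    params = mr_params(n_boot = 0, presso_nsim = 100),
    seed = 7, screen_legs = FALSE))
  expect_s3_class(res, "mr_mediation")
  expect_equal(res$beta_a, 0.3, tolerance = 0.1)
  expect_equal(res$beta_b, 0.2, tolerance = 0.1)
  expect_equal(res$beta_t, 0.46, tolerance = 0.15)
  expect_equal(res$indirect, res$beta_a * res$beta_b, tolerance = 1e-15)
  expect_equal(res$proportion_pct, 13.04, tolerance = 3)
  expect_false(res$reverse_assessed)  # outcome has no genome-wide hits
  res2 <- suppressWarnings(run_mediation(
    trip$exposure, trip$mediator, trip$outcome,
    params = mr_params(n_boot = 0, presso_nsim = 100),
    seed = 7, screen_legs = FALSE))
  expect_identical(tibble::as_tibble(res), tibble::as_tibble(res2))
  # Monte-Carlo CI option reports an interval containing the point estimate
  res3 <- suppressWarnings(run_mediation(
    trip$exposure, trip$mediator, trip$outcome,
    params = mr_params(n_boot = 0, presso_nsim = 100),
    seed = 7, screen_legs = FALSE, mc_ci = TRUE, n_mc = 2000))
  expect_lt(res3$mc_ci_low, res3$indirect)
  expect_gt(res3$mc_ci_high, res3$indirect)
})

test_that("reverse MR flags a planted reverse effect and respects the null", {
  # planted reverse effect: treat the simulated pair's exposure as the
  # disease and its outcome as the metabolite; the 'disease' has strong
  # instruments and a true effect theta on the 'metabolite'
  power_hits <- 0
  null_hits <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    sim <- simulate_pair(sim_config(m_snps = 20, seed = 50000 + i,
                                    theta_xy = 0.3))
    rev <- reverse_mr_check(sim$exposure, sim$outcome,
                            params = mr_params(reverse_p = 1e-5))
    power_hits <- power_hits + rev$flagged
    sim0 <- simulate_pair(sim_config(m_snps = 20, seed = 60000 + i,
                                     theta_xy = 0))
    rev0 <- reverse_mr_check(sim0$exposure, sim0$outcome,
                             params = mr_params(reverse_p = 1e-5))
    null_hits <- null_hits + rev0$flagged
  }
  expect_gt(power_hits / reps, 0.9)
  expect_lt(null_hits / reps, 0.15)
})
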