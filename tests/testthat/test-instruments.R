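test_that("p-value filtering is strict and order-preserving", {
  tab <- make_sumstats(c("a", "b", "c"), beta = 0.1, se = 0.01,
                       pvalue = c(1e-9, 1e-6, 1e-4))
  expect_equal(filter_pvalue(tab, 1e-5)$snp_id, c("a", "b"))
  expect_equal(filter_pvalue(tab, 5e-8)$snp_id, "a")
  expect_equal(filter_pvalue(tab, 1e-6)$snp_id, "a")  # equality excluded
})

test_that("greedy clumping matches its forced hand-trace", {
  tab <- make_sumstats(c("s1", "s2", "s3"),
                       beta = 0.1, se = 0.01,
                       pvalue = c(1e-10, 1e-9, 1e-8),
                       pos = c(100000L, 150000L, 300000L))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[1, 3] <- r2[3, 1] <- 0.0005
  r2[2, 3] <- r2[3, 2] <- 0.0005
  ld <- ld_matrix(c("s1", "s2", "s3"), r2)
  out <- clump(tab, ld)
  expect_setequal(out$snp_id, c("s1", "s3"))
  # two linked SNPs outside the window are both kept
  far <- make_sumstats(c("s1", "s2"), beta = 0.1, se = 0.01,
                       pvalue = c(1e-10, 1e-9),
                       pos = c(1L, 20000001L + 1L))
  ld2 <- ld_matrix(c("s1", "s2"), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(nrow(clump(far, ld2, window_kb = 10000)), 2)
})

test_that("clumping equals an independent brute-force sweep on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- 6
    ids <- sprintf("v%d", 1:m)
    tab <- make_sumstats(ids, beta = 0.1, se = 0.01,
                         pvalue = runif(m, 1e-10, 1e-4),
                         pos = sort(sample.int(3e7, m)))
    r2 <- matrix(runif(m * m), m)
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    ld <- ld_matrix(ids, r2)
    got <- clump(tab, ld, r2_max = 0.3, window_kb = 5000)
    want <- oracle_clump(tab, function(a, b) ld[a, b],
                         r2_max = 0.3, window_kb = 5000)
    expect_setequal(got$snp_id, want)
  }
})

test_that("clumping degenerate settings keep everything", {
  set.seed(1)
  m <- 8
  ids <- sprintf("v%d", 1:m)
  tab <- make_sumstats(ids, beta = 0.1, se = 0.01,
                       pvalue = runif(m, 1e-10, 1e-4))
  r2 <- matrix(0.9, m, m); diag(r2) <- 1
  ld <- ld_matrix(ids, r2)
  expect_equal(nrow(clump(tab, ld, r2_max = 1.0)), m)   # only r2 >= 1 conflicts
  expect_equal(nrow(clump(tab, ld, window_kb = 0)), m)  # zero window
  expect_equal(nrow(clump(tab, ld_matrix(ids, diag(m)))), m)  # identity LD
  expect_equal(nrow(clump(tab, NULL)), m)  # absent pairs are unlinked
  # pairwise compatibility invariant on a clumped set
  out <- clump(tab, ld, r2_max = 0.5, window_kb = 10000)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j) next
      near <- abs(out$pos[i] - out$pos[j]) <= 1e7
      expect_false(near && ld[out$snp_id[i], out$snp_id[j]] >= 0.5)
    }
  }
})

test_that("outcome-associated SNPs are excluded; missing SNPs retained", {
  exposure <- make_sumstats(c("a", "b", "c"), beta = 0.1, se = 0.01,
                            pvalue = 1e-8)
  outcome <- make_sumstats(c("a", "b"), beta = 0.1, se = 0.01,
                           pvalue = c(1e-9, 1e-7))
  out <- exclude_outcome_associated(exposure, outcome)
  expect_equal(out$snp_id, c("b", "c"))
})

test_that("instrument strength follows the R2 formula with the Wald fallback", {
  tab <- make_sumstats("a", beta = 0.05, se = 0.01, pvalue = 1e-8,
                       eaf = 0.2, n = 10000)
  st <- instrument_strength(tab)
  r2 <- 2 * 0.2 * 0.8 * 0.05^2
  expect_equal(st$r2_explained, r2, tolerance = 1e-12)
  expect_equal(st$f_stat, r2 * 9998 / (1 - r2), tolerance = 1e-12)
  expect_equal(st$f_method, "r2")
  # fallback when eaf missing
  tab2 <- make_sumstats("a", beta = 0.1, se = 0.01, pvalue = 1e-8,
                        eaf = NA, n = 10000)
  st2 <- instrument_strength(tab2)
  expect_equal(st2$f_stat, 100, tolerance = 1e-12)
  expect_equal(st2$f_method, "wald")
  # null effect
  tab3 <- make_sumstats("a", beta = 0, se = 0.01, pvalue = 0.9,
                        eaf = 0.5, n = 10000)
  st3 <- instrument_strength(tab3)
  expect_equal(st3$r2_explained, 0)
  expect_equal(st3$f_stat, 0)
  expect_error(instrument_strength(tab, n = 2), class = "mrpath_error_domain")
})

test_that("select_instruments removes one known SNP per stage with matching attrition", {
  # 8 SNPs engineered so each stage removes exactly one:
  # s1 fails the p threshold; s2 is clumped away (high LD with s3, worse p);
  # s4 is outcome-associated; s5 is weak (low F); the rest survive.
  ids <- sprintf("s%d", 1:8)
  tab <- make_sumstats(
    ids,
    beta = c(0.05, 0.05, 0.05, 0.05, 0.001, 0.05, 0.05, 0.05),
    se = 0.005, pvalue = c(1e-4, 1e-7, 1e-8, 1e-8, 1e-6, 1e-8, 1e-8, 1e-8),
    eaf = 0.3, n = 1e5,
    pos = c(1:4 * 100000L, 5:8 * 100000L))
  r2 <- diag(8)
  r2[2, 3] <- r2[3, 2] <- 0.9
  ld <- ld_matrix(ids, r2)
  outcome <- make_sumstats(ids, beta = 0.01, se = 0.005,
                           pvalue = c(rep(0.5, 3), 1e-9, rep(0.5, 4)))
  ivs <- select_instruments(tab, outcome, ld, p_threshold = 1e-5)
  expect_setequal(ivs$snp_id, c("s3", "s6", "s7", "s8"))
  att <- attr(ivs, "attrition")
  expect_equal(att$n_in, c(8, 7, 6, 5))
  expect_equal(att$n_out, c(7, 6, 5, 4))
  expect_equal(att$stage, c("pvalue", "clump", "outcome_association",
                            "strength"))
  # attrition counts sum to the output size
  expect_equal(att$n_in[1] - sum(att$n_removed), nrow(ivs))
})

test_that("select_instruments errors name the emptying stage; vacuous filters remove nothing", {
  tab <- make_sumstats(c("a", "b"), beta = 0.1, se = 0.01, pvalue = 1e-3)
  outcome <- make_sumstats(c("a", "b"), beta = 0.01, se = 0.01, pvalue = 0.5)
  err <- expect_error(select_instruments(tab, outcome, NULL),
                      class = "mrpath_error_no_instruments")
  expect_match(conditionMessage(err), "pvalue")
  strong <- make_sumstats(c("a", "b"), beta = 0.1, se = 0.01, pvalue = 1e-8,
                          eaf = 0.3, n = 1e5)
  ivs <- select_instruments(strong, outcome, NULL, f_min = 0, maf_min = 0)
  expect_equal(nrow(ivs), 2)
})

test_that("proxy search obeys the threshold and stated tie-breaks", {
  ids <- c("target", "p1", "p2", "p3")
  r2 <- diag(4)
  r2[1, 2] <- r2[2, 1] <- 0.90
  r2[1, 3] <- r2[3, 1] <- 0.85
  r2[1, 4] <- r2[4, 1] <- 0.79
  ld <- ld_matrix(ids, r2)
  cands <- make_sumstats(c("p1", "p2", "p3"), beta = 0.1, se = 0.01,
                         pvalue = c(1e-6, 1e-8, 1e-9))
  expect_equal(find_proxy("target", ld, cands)$snp_id, "p1")
  # strict threshold: best 0.79 -> none
  ld79 <- ld_matrix(ids, {
    m <- diag(4); m[1, 4] <- m[4, 1] <- 0.79; m
  })
  expect_null(find_proxy("target", ld79, cands))
  # exact r2 tie broken by lower p
  r2t <- diag(4)
  r2t[1, 2] <- r2t[2, 1] <- 0.9
  r2t[1, 3] <- r2t[3, 1] <- 0.9
  tie <- find_proxy("target", ld_matrix(ids, r2t),
                    make_sumstats(c("p1", "p2"), beta = 0.1, se = 0.01,
                                  pvalue = c(1e-6, 1e-8)))
  expect_equal(tie$snp_id, "p2")
})
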