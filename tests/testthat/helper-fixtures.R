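# Fixture builders and independent oracle implementations used across the
# suite. Oracles deliberately take a different computational route from the
# package (stats::lm, explicit loops) so agreement is a real cross-check.

make_sumstats <- function(snp_id, beta, se, pvalue,
                          effect_allele = "A", other_allele = "G",
                          chrom = "1", pos = seq_along(snp_id) * 100000L,
                          eaf = 0.3, n = 1e5, trait_id = "trait",
                          trait_class = "other") {
  as_gwas_sumstats(tibble::tibble(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n
  ), trait_id = trait_id, trait_class = trait_class)
}

make_harmonized <- function(beta_x, se_x, beta_y, se_y,
                            snp_id = sprintf("rs%03d", seq_along(beta_x))) {
  structure(tibble::tibble(
    snp_id = snp_id, chrom = "1",
    pos = seq_along(beta_x) * 100000L,
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
    eaf_x = 0.3, n_x = 1e5, pvalue_x = 1e-8
  ), exposure_id = "X", outcome_id = "Y",
  class = c("mr_harmonized", class(tibble::tibble())))
}

# canonical 3-SNP fixture used by several closed-form checks
h3 <- function() {
  make_harmonized(beta_x = c(0.10, 0.20, 0.15),
                  se_x = c(0.01, 0.01, 0.02),
                  beta_y = c(0.06, 0.08, 0.09),
                  se_y = c(0.01, 0.01, 0.02))
}

# WLS oracles via stats::lm (QR decomposition, independent of the package's
# closed-form sums)
oracle_ivw <- function(h) {
  fit <- stats::lm(beta_y ~ 0 + beta_x, data = h, weights = 1 / h$se_y^2)
  unname(coef(fit)[1])
}

oracle_egger <- function(h) {
  fit <- stats::lm(beta_y ~ beta_x, data = h, weights = 1 / h$se_y^2)
  unname(coef(fit))  # (intercept, slope)
}

# interpolated weighted quantile at q = 0.5, written as an explicit scan
oracle_weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- numeric(length(r))
  acc <- 0
  for (j in seq_along(r)) {
    p[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(p)])
  k <- max(which(p <= 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

# dense-grid kernel-density argmax, explicit double loop over the same
# 512-point grid the estimator uses
oracle_mode <- function(ratio, weight, phi = 1, grid_n = 512) {
  m <- length(ratio)
  s <- stats::sd(ratio)
  iq <- stats::IQR(ratio) / 1.34
  spread <- if (iq > 0) min(s, iq) else s
  bw <- phi * 0.9 * spread * m^(-1 / 5)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = grid_n)
  w <- weight / sum(weight)
  dens <- numeric(grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(m)) {
      dens[i] <- dens[i] + w[j] * exp(-(grid[i] - ratio[j])^2 / (2 * bw^2))
    }
  }
  top <- which(dens == max(dens))
  mean(grid[range(top)])
}

# brute-force greedy clump: literal restatement of the sort-and-sweep rule
oracle_clump <- function(tab, r2_lookup, r2_max, window_kb) {
  ord <- order(tab$pvalue, tab$snp_id)
  alive <- rep(TRUE, nrow(tab))
  accepted <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    accepted <- c(accepted, i)
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (tab$chrom[j] == tab$chrom[i] &&
          abs(tab$pos[j] - tab$pos[i]) <= window_kb * 1000 &&
          r2_lookup(tab$snp_id[i], tab$snp_id[j]) >= r2_max) {
        alive[j] <- FALSE
      }
    }
  }
  sort(tab$snp_id[accepted])
}

expect_same_to_digits <- function(actual, expected, digits = 10) {
  expect_equal(actual, expected, tolerance = 10^(-digits))
}
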