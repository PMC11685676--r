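#' Configuration for the synthetic GWAS generator
#'
#' Defaults describe a well-powered two-sample design: 50 instruments,
#' GWAS sample sizes of 100,000, instrument effects with spread 0.03 on the
#' standardized scale, and MAFs uniform on \[0.05, 0.5\] — strong enough
#' that instruments typically clear the 1e-5 significance threshold.
#'
#' @param m_snps instruments per block (default 50).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (default 1e5).
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param gamma_sd spread of true instrument effects; effects are drawn
#'   half-normal `|N(0, gamma_sd^2)|`, i.e. oriented positive.
#' @param theta_xy true exposure-on-outcome effect for [simulate_pair()].
#' @param theta_xm,theta_my,direct_xy true effects for
#'   [simulate_mediation_triple()]: exposure-on-mediator,
#'   mediator-on-outcome, and the direct exposure-on-outcome path; the
#'   total effect is `theta_xm * theta_my + direct_xy`.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects)
#'   or `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_mean,pleiotropy_sd direct-effect distribution for
#'   invalid instruments.
#' @param invalid_fraction share of instruments given pleiotropic effects.
#' @param ld_block_size,ld_within_r2 block-LD structure for [simulate_ld()]:
#'   SNPs within a block share `ld_within_r2`, blocks are independent.
#' @param seed master seed; expands into named substreams (maf, gamma,
#'   pleiotropy, noise per sample) so one component can change while others
#'   stay fixed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 50, n_exposure = 1e5, n_mediator = 1e5,
                       n_outcome = 1e5, maf_range = c(0.05, 0.5),
                       gamma_sd = 0.03, theta_xy = 0.2,
                       theta_xm = 0.3, theta_my = 0.2, direct_xy = 0.4,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       invalid_fraction = 0,
                       ld_block_size = 1, ld_within_r2 = 0,
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(m_snps >= 1, n_exposure > 2, n_mediator > 2, n_outcome > 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            gamma_sd > 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            ld_block_size >= 1, ld_within_r2 >= 0, ld_within_r2 <= 1)
  if (pleiotropy_mode == "balanced") pleiotropy_mean <- 0
  structure(list(m_snps = m_snps, n_exposure = n_exposure,
                 n_mediator = n_mediator, n_outcome = n_outcome,
                 maf_range = maf_range, gamma_sd = gamma_sd,
                 theta_xy = theta_xy, theta_xm = theta_xm,
                 theta_my = theta_my, direct_xy = direct_xy,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 ld_block_size = ld_block_size,
                 ld_within_r2 = ld_within_r2,
                 seed = seed),
            class = "sim_config")
}

# non-palindromic effect/other allele pairs
allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

sim_snp_frame <- function(cfg, m, prefix) {
  maf <- with_seed(substream_seed(cfg$seed, paste0(prefix, "_maf")),
                   runif(m, cfg$maf_range[1], cfg$maf_range[2]))
  pair_idx <- with_seed(substream_seed(cfg$seed, paste0(prefix, "_alleles")),
                        sample.int(nrow(allele_pairs), m, replace = TRUE))
  tibble::tibble(
    snp_id = sprintf("rs%s%04d", prefix, seq_len(m)),
    chrom = "1",
    pos = as.integer(seq_len(m) * 100000L +
                       if (prefix == "m") 500000000L else 0L),
    effect_allele = allele_pairs[pair_idx, 1],
    other_allele = allele_pairs[pair_idx, 2],
    eaf = maf,
    maf = maf
  )
}

observe_gwas <- function(base, true_beta, n, cfg, stream) {
  sigma <- 1 / sqrt(2 * n * base$maf * (1 - base$maf))
  beta <- true_beta + with_seed(substream_seed(cfg$seed, stream),
                                rnorm(nrow(base), 0, sigma))
  tibble::tibble(
    snp_id = base$snp_id, chrom = base$chrom, pos = base$pos,
    effect_allele = base$effect_allele, other_allele = base$other_allele,
    eaf = base$eaf, beta = beta, se = sigma,
    pvalue = pmax(2 * pnorm(-abs(beta / sigma)), .Machine$double.xmin),
    n = n
  )
}

draw_pleiotropy <- function(cfg, m, prefix) {
  alpha <- numeric(m)
  if (cfg$pleiotropy_mode != "none" && cfg$invalid_fraction > 0) {
    k <- round(cfg$invalid_fraction * m)
    idx <- with_seed(substream_seed(cfg$seed, paste0(prefix, "_invalid")),
                     sample.int(m, k))
    alpha[idx] <- with_seed(
      substream_seed(cfg$seed, paste0(prefix, "_pleiotropy")),
      rnorm(k, cfg$pleiotropy_mean, cfg$pleiotropy_sd))
  }
  alpha
}

#' Simulate a two-sample exposure/outcome GWAS pair with known truth
#'
#' Per SNP: MAF uniform on `maf_range`; true exposure effect half-normal
#' `|N(0, gamma_sd^2)|`; a pleiotropic direct effect for the invalid
#' fraction; true outcome effect `theta_xy * gamma + alpha`. Sampling
#' standard errors follow the standardized-trait approximation
#' `1 / sqrt(2 n maf (1 - maf))`; observed effects add independent normal
#' noise in the two (non-overlapping) samples, and p-values are Wald tests.
#'
#' @param cfg a [sim_config()].
#' @return A list: `exposure` and `outcome` (`gwas_sumstats` tibbles) and
#'   `truth` (list with `theta_xy` and the per-SNP tibble of latent
#'   quantities).
#' @export
simulate_pair <- function(cfg = sim_config()) {
  m <- cfg$m_snps
  base <- sim_snp_frame(cfg, m, "x")
  gamma <- abs(with_seed(substream_seed(cfg$seed, "x_gamma"),
                         rnorm(m, 0, cfg$gamma_sd)))
  alpha <- draw_pleiotropy(cfg, m, "x")
  gamma_out <- cfg$theta_xy * gamma + alpha
  exposure <- as_gwas_sumstats(
    observe_gwas(base, gamma, cfg$n_exposure, cfg, "noise_x"),
    trait_id = "sim_exposure", trait_class = "other")
  outcome <- as_gwas_sumstats(
    observe_gwas(base, gamma_out, cfg$n_outcome, cfg, "noise_y"),
    trait_id = "sim_outcome", trait_class = "outcome")
  truth <- list(theta_xy = cfg$theta_xy,
                per_snp = tibble::tibble(snp_id = base$snp_id,
                                         maf = base$maf, gamma = gamma,
                                         alpha = alpha,
                                         gamma_out = gamma_out))
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate an exposure -> mediator -> outcome GWAS triple with known truth
#'
#' Two disjoint instrument blocks of `m_snps` SNPs each: X-instruments act
#' on the exposure (effect `gamma`), on the mediator through
#' `theta_xm * gamma`, and on the outcome through
#' `(theta_xm * theta_my + direct_xy) * gamma`; M-instruments act on the
#' mediator only (effect `delta`) and on the outcome through
#' `theta_my * delta`. All three summary tables share consistent SNP ids so
#' that harmonization and the exposure-adjustment of mediator instruments
#' are exercised. The true total effect is `theta_xm * theta_my + direct_xy`
#' and the true mediated proportion
#' `100 * theta_xm * theta_my / (theta_xm * theta_my + direct_xy)`.
#'
#' @param cfg a [sim_config()].
#' @return A list: `exposure`, `mediator`, `outcome` tibbles and `truth`
#'   (planted effects, total effect, mediated proportion, instrument id
#'   blocks).
#' @export
simulate_mediation_triple <- function(cfg = sim_config()) {
  m <- cfg$m_snps
  bx <- sim_snp_frame(cfg, m, "x")
  bm <- sim_snp_frame(cfg, m, "m")
  gamma <- abs(with_seed(substream_seed(cfg$seed, "x_gamma"),
                         rnorm(m, 0, cfg$gamma_sd)))
  delta <- abs(with_seed(substream_seed(cfg$seed, "m_gamma"),
                         rnorm(m, 0, cfg$gamma_sd)))
  total <- cfg$theta_xm * cfg$theta_my + cfg$direct_xy
  base <- dplyr::bind_rows(bx, bm)
  true_x <- c(gamma, rep(0, m))
  true_m <- c(cfg$theta_xm * gamma, delta)
  true_y <- c(total * gamma, cfg$theta_my * delta)
  exposure <- as_gwas_sumstats(
    observe_gwas(base, true_x, cfg$n_exposure, cfg, "noise_x"),
    trait_id = "sim_exposure", trait_class = "metabolite")
  mediator <- as_gwas_sumstats(
    observe_gwas(base, true_m, cfg$n_mediator, cfg, "noise_m"),
    trait_id = "sim_mediator", trait_class = "immune")
  outcome <- as_gwas_sumstats(
    observe_gwas(base, true_y, cfg$n_outcome, cfg, "noise_y"),
    trait_id = "sim_outcome", trait_class = "outcome")
  truth <- list(theta_xm = cfg$theta_xm, theta_my = cfg$theta_my,
                direct_xy = cfg$direct_xy,
                beta_t = total,
                indirect = cfg$theta_xm * cfg$theta_my,
                proportion_pct = 100 * cfg$theta_xm * cfg$theta_my / total,
                x_instruments = bx$snp_id, m_instruments = bm$snp_id)
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate a block-diagonal LD matrix
#'
#' Consecutive SNPs are grouped into blocks of `ld_block_size`; within a
#' block every off-diagonal r-squared equals `ld_within_r2`, across blocks
#' zero (the last block may be smaller).
#'
#' @param cfg a [sim_config()].
#' @param snp_ids SNP ids, in order.
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(cfg, snp_ids) {
  m <- length(snp_ids)
  r2 <- matrix(0, m, m)
  starts <- seq(1, m, by = cfg$ld_block_size)
  for (s in starts) {
    idx <- s:min(s + cfg$ld_block_size - 1, m)
    r2[idx, idx] <- cfg$ld_within_r2
  }
  diag(r2) <- 1
  ld_matrix(snp_ids, r2)
}
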