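#' Strict screening of one exposure-outcome MR result
#'
#' Evaluates the four gates a strongly supported exposure must pass:
#' (1) IVW p-value below `alpha`; (2) consistent effect direction across all
#' reported methods; (3) MR-PRESSO global p above `alpha` (no outlier
#' interference); (4) Egger-intercept p above `alpha` (no directional
#' pleiotropy). A gate whose statistic is unavailable (e.g. MR-PRESSO with
#' < 4 SNPs) counts as failed, keeping the screen conservative.
#'
#' @param estimates estimate tibble from [run_all_methods()] (must contain
#'   an `ivw` row).
#' @param sens an `mr_sensitivity` report from [full_sensitivity()].
#' @param alpha significance level for all four gates (default 0.05).
#' @return A one-row tibble of class `mr_screen_decision`: `exposure_id`,
#'   `outcome_id`, `ivw_p`, `direction_ok`, `presso_ok`, `pleiotropy_ok`,
#'   `passed`.
#' @export
screen <- function(estimates, sens, alpha = 0.05) {
  stopifnot("ivw" %in% estimates$method)
  ivw_p <- estimates$pvalue[estimates$method == "ivw"][1]
  direction_ok <- direction_consistent(estimates)
  presso_ok <- isTRUE(sens$presso_global_p > alpha)
  pleiotropy_ok <- isTRUE(sens$egger_intercept_p > alpha)
  tibble::tibble(
    exposure_id = attr(estimates, "exposure_id") %||% sens$exposure_id %||% "exposure",
    outcome_id = attr(estimates, "outcome_id") %||% sens$outcome_id %||% "outcome",
    ivw_p = ivw_p,
    direction_ok = direction_ok,
    presso_ok = presso_ok,
    pleiotropy_ok = pleiotropy_ok,
    passed = (ivw_p < alpha) && direction_ok && presso_ok && pleiotropy_ok
  )
}

#' Adjust mediator instruments for the exposure
#'
#' For the mediator-to-outcome leg of a two-step mediation analysis, the
#' mediator's instruments are purged of the exposure's influence by removing
#' every SNP used in the exposure-to-mediator analysis, and (by default) any
#' SNP in LD at `r2 >= r2_max` with one of them.
#'
#' @param mediator_ivs mediator instrument tibble.
#' @param exposure_mediator_ivs instruments used in the exposure-to-mediator
#'   analysis.
#' @param ld [ld_matrix()] or `NULL`.
#' @param r2_max LD threshold for partner removal (default 0.001).
#' @param remove_ld_partners also remove LD partners (default `TRUE`).
#' @return The reduced mediator instrument tibble.
#' @export
adjusted_mediator_instruments <- function(mediator_ivs, exposure_mediator_ivs,
                                          ld = NULL, r2_max = 0.001,
                                          remove_ld_partners = TRUE) {
  drop_ids <- unique(exposure_mediator_ivs$snp_id)
  keep <- !mediator_ivs$snp_id %in% drop_ids
  if (remove_ld_partners && !is.null(ld) && length(drop_ids) > 0) {
    for (sid in drop_ids) {
      r2 <- ld_r2_with(ld, sid, mediator_ivs$snp_id)
      keep <- keep & r2 < r2_max
    }
  }
  out <- keep_attrs(mediator_ivs, mediator_ivs[keep, , drop = FALSE])
  if (nrow(out) == 0) {
    abort("no mediator instruments remain after adjusting for the exposure",
          class = "mrpath_error_no_instruments")
  }
  out
}

#' Product-of-coefficients (Sobel) indirect effect
#'
#' `indirect = beta_a * beta_b` with first-order delta-method standard error
#' `sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)`, normal z test and
#' confidence interval.
#'
#' @param beta_a,se_a exposure-to-mediator effect and standard error.
#' @param beta_b,se_b mediator-to-outcome effect and standard error.
#' @return A one-row tibble: `indirect`, `indirect_se`, `z`, `pvalue`,
#'   `ci_low`, `ci_high`.
#' @export
sobel <- function(beta_a, se_a, beta_b, se_b) {
  stopifnot(is.finite(beta_a), is.finite(beta_b), se_a > 0, se_b > 0)
  indirect <- beta_a * beta_b
  se <- sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)
  z <- if (se == 0) 0 else indirect / se
  zc <- z_crit()
  tibble::tibble(indirect = indirect, indirect_se = se, z = z,
                 pvalue = 2 * pnorm(-abs(z)),
                 ci_low = indirect - zc * se,
                 ci_high = indirect + zc * se)
}

#' Mediated proportion
#'
#' `indirect / beta_t`, reported as a signed percentage. May be negative or
#' exceed 100 (inconsistent mediation, when the indirect and total effects
#' have opposite signs); no clamping is applied.
#'
#' @param indirect indirect effect (product of coefficients).
#' @param beta_t total effect.
#' @param floor smallest `|beta_t|` for which the proportion is defined
#'   (default 1e-8).
#' @return A one-row tibble: `proportion_pct`, `inconsistent`.
#' @export
mediated_proportion <- function(indirect, beta_t, floor = 1e-8) {
  if (!is.finite(beta_t) || abs(beta_t) < floor) {
    abort("mediated proportion undefined: |total effect| below floor",
          class = "mrpath_error_undefined_proportion")
  }
  tibble::tibble(proportion_pct = 100 * indirect / beta_t,
                 inconsistent = indirect * beta_t < 0)
}

#' Reverse-MR check for a pathway
#'
#' Runs the standard pipeline with the roles swapped (outcome as exposure)
#' to test for reverse causation; a significant reverse IVW effect
#' (p < `alpha`) flags the pathway for exclusion. When no reverse
#' instruments can be selected the check cannot be performed: the flag is
#' `FALSE` with a warning.
#'
#' @param outcome_table the original outcome GWAS (used as exposure here).
#' @param exposure_table the original exposure GWAS (used as outcome here).
#' @param ld [ld_matrix()] or `NULL`.
#' @param params [mr_params()] list; `reverse_p` (default 5e-8) is the
#'   instrument threshold for the outcome-as-exposure GWAS.
#' @return A list: `flagged` (logical), `estimate` (IVW row or `NULL`),
#'   `assessed` (logical).
#' @export
reverse_mr_check <- function(outcome_table, exposure_table, ld = NULL,
                             params = mr_params()) {
  ivs <- tryCatch(
    select_instruments(outcome_table, exposure_table, ld,
                       p_threshold = params$reverse_p,
                       r2_max = params$clump_r2,
                       window_kb = params$clump_kb,
                       outcome_p = params$outcome_p,
                       f_min = params$f_min, maf_min = params$maf_min),
    mrpath_error_no_instruments = function(e) NULL)
  if (is.null(ivs)) {
    warn("reverse MR could not be assessed: no instruments for the outcome")
    return(list(flagged = FALSE, estimate = NULL, assessed = FALSE))
  }
  h <- tryCatch(harmonize(ivs, exposure_table),
                mrpath_error_empty_harmonization = function(e) NULL)
  if (is.null(h) || nrow(h) < 2) {
    warn("reverse MR could not be assessed: harmonization left < 2 SNPs")
    return(list(flagged = FALSE, estimate = NULL, assessed = FALSE))
  }
  est <- mr_ivw(h, model = params$ivw_model)
  list(flagged = est$pvalue < params$alpha, estimate = est, assessed = TRUE)
}

leg_ivw <- function(exposure, outcome, ld, params, leg) {
  ivs <- tryCatch(
    select_instruments(exposure, outcome, ld,
                       p_threshold = params$exposure_p,
                       r2_max = params$clump_r2,
                       window_kb = params$clump_kb,
                       outcome_p = params$outcome_p,
                       f_min = params$f_min, maf_min = params$maf_min),
    mrpath_error_no_instruments = function(e) {
      abort(sprintf("mediation leg '%s' failed instrument selection: %s",
                    leg, conditionMessage(e)),
            class = "mrpath_error_mediation_leg")
    })
  list(ivs = ivs, harmonized = harmonize(ivs, outcome))
}

#' Two-step mediation MR for one exposure -> mediator -> outcome pathway
#'
#' Estimates the total effect `beta_t` (exposure on outcome), the
#' exposure-to-mediator effect `beta_a`, and the mediator-to-outcome effect
#' `beta_b` (on mediator instruments purged of the exposure-to-mediator
#' SNPs), all by IVW; forms the indirect effect `beta_a * beta_b` with
#' delta-method inference ([sobel()]), the mediated proportion, and runs the
#' reverse-MR exclusion check. With `screen_legs = TRUE` each leg must also
#' pass the four-gate strict screen.
#'
#' @param exposure,mediator,outcome `gwas_sumstats` tibbles.
#' @param ld [ld_matrix()] or `NULL`.
#' @param params [mr_params()] list.
#' @param seed master seed (substreams per leg and per test).
#' @param screen_legs apply the strict screen to every leg (default `TRUE`);
#'   set `FALSE` for pure effect estimation.
#' @param mc_ci also compute a Monte-Carlo CI for the indirect effect by
#'   sampling `beta_a`, `beta_b` from normals (default `FALSE`).
#' @param n_mc Monte-Carlo draws when `mc_ci` (default 10000).
#' @return A one-row tibble of class `mr_mediation` with the leg estimates
#'   (`beta_a`, `se_a`, `beta_b`, `se_b`, `beta_t`, `se_t`), the indirect
#'   effect with `z`, `pvalue`, `ci_low`, `ci_high`, the
#'   `proportion_pct` and `inconsistent` flag, `reverse_flagged`,
#'   `reverse_assessed`, and (when screened) `legs_passed`.
#' @export
run_mediation <- function(exposure, mediator, outcome, ld = NULL,
                          params = mr_params(), seed = 1,
                          screen_legs = TRUE, mc_ci = FALSE, n_mc = 10000) {
  # step 0: total effect X -> Y
  t_leg <- leg_ivw(exposure, outcome, ld, params, "exposure->outcome")
  est_t <- mr_ivw(t_leg$harmonized, model = params$ivw_model)
  # step 1: X -> M
  a_leg <- leg_ivw(exposure, mediator, ld, params, "exposure->mediator")
  est_a <- mr_ivw(a_leg$harmonized, model = params$ivw_model)
  # step 2: M -> Y on adjusted instruments
  m_ivs <- tryCatch(
    select_instruments(mediator, outcome, ld,
                       p_threshold = params$exposure_p,
                       r2_max = params$clump_r2,
                       window_kb = params$clump_kb,
                       outcome_p = params$outcome_p,
                       f_min = params$f_min, maf_min = params$maf_min),
    mrpath_error_no_instruments = function(e) {
      abort(sprintf("mediation leg 'mediator->outcome' failed instrument selection: %s",
                    conditionMessage(e)),
            class = "mrpath_error_mediation_leg")
    })
  m_ivs <- adjusted_mediator_instruments(m_ivs, a_leg$ivs, ld,
                                         r2_max = params$clump_r2)
  h_b <- harmonize(m_ivs, outcome)
  est_b <- mr_ivw(h_b, model = params$ivw_model)

  legs_passed <- NA
  if (screen_legs) {
    pass_one <- function(h, i) {
      ests <- run_all_methods(h, seed = substream_seed(seed, paste0("leg", i)),
                              n_boot = params$n_boot,
                              ivw_model = params$ivw_model)
      sens <- full_sensitivity(h, ests,
                               seed = substream_seed(seed, paste0("sens", i)),
                               n_sim = params$presso_nsim)
      screen(ests, sens, alpha = params$alpha)$passed
    }
    legs_passed <- pass_one(t_leg$harmonized, 1) &&
      pass_one(a_leg$harmonized, 2) && pass_one(h_b, 3)
  }

  sob <- sobel(est_a$beta, est_a$se, est_b$beta, est_b$se)
  prop <- mediated_proportion(sob$indirect, est_t$beta,
                              floor = params$proportion_floor)
  rev <- reverse_mr_check(outcome, exposure, ld, params)

  out <- tibble::tibble(
    exposure_id = trait_id_of(exposure, "exposure"),
    mediator_id = trait_id_of(mediator, "mediator"),
    outcome_id = trait_id_of(outcome, "outcome"),
    beta_a = est_a$beta, se_a = est_a$se,
    beta_b = est_b$beta, se_b = est_b$se,
    beta_t = est_t$beta, se_t = est_t$se,
    indirect = sob$indirect, indirect_se = sob$indirect_se,
    z = sob$z, pvalue = sob$pvalue,
    ci_low = sob$ci_low, ci_high = sob$ci_high,
    proportion_pct = prop$proportion_pct,
    inconsistent = prop$inconsistent,
    reverse_flagged = rev$flagged,
    reverse_assessed = rev$assessed,
    legs_passed = legs_passed
  )
  if (mc_ci) {
    mc <- with_seed(substream_seed(seed, "mc_ci"), {
      a <- rnorm(n_mc, est_a$beta, est_a$se)
      b <- rnorm(n_mc, est_b$beta, est_b$se)
      quantile(a * b, c(0.025, 0.975), names = FALSE)
    })
    out$mc_ci_low <- mc[1]
    out$mc_ci_high <- mc[2]
  }
  structure(out, seed = seed,
            class = c("mr_mediation", class(tibble::tibble())))
}
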