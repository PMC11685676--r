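#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (beta_y_j - theta * beta_x_j)^2)` with `w_j = 1 / se_y_j^2`,
#' evaluated at the (fixed-effects) IVW estimate unless another `theta` is
#' supplied; under homogeneity Q is chi-squared with `n - 1` degrees of
#' freedom.
#'
#' @param h an `mr_harmonized` tibble with >= 2 SNPs.
#' @param theta causal estimate at which to evaluate Q; defaults to the
#'   fixed-effects IVW estimate (which minimizes Q).
#' @return A one-row tibble with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(h, theta = NULL) {
  h <- check_harmonized(h, 2L, "Cochran's Q")
  if (is.null(theta)) theta <- ivw_core(h$beta_x, h$beta_y, h$se_y)$beta
  w <- 1 / h$se_y^2
  q <- sum(w * (h$beta_y - theta * h$beta_x)^2)
  df <- nrow(h) - 1L
  tibble::tibble(q_stat = q, q_df = df,
                 q_pvalue = pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect dropping each SNP in turn, to reveal single
#' instruments that drive the pooled estimate. The full-set estimate is
#' appended as a row with `snp_id = "All"`.
#'
#' @param h an `mr_harmonized` tibble with >= 3 SNPs.
#' @param model IVW standard-error model; see [mr_ivw()].
#' @return A tibble of class `mr_loo` with one row per left-out SNP plus the
#'   full-set row: `snp_id`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
leave_one_out <- function(h, model = "random") {
  h <- check_harmonized(h, 3L, "leave-one-out")
  rows <- purrr::map(seq_len(nrow(h)), function(j) {
    e <- mr_ivw(h[-j, ], model = model)
    tibble::tibble(snp_id = h$snp_id[j], beta = e$beta, se = e$se,
                   ci_low = e$ci_low, ci_high = e$ci_high,
                   pvalue = e$pvalue)
  })
  full <- mr_ivw(h, model = model)
  out <- dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tibble::tibble(snp_id = "All", beta = full$beta, se = full$se,
                   ci_low = full$ci_low, ci_high = full$ci_high,
                   pvalue = full$pvalue))
  structure(out, class = c("mr_loo", class(tibble::tibble())))
}

#' Assemble the full sensitivity report for one exposure-outcome pair
#'
#' Combines Cochran's Q, the Egger intercept test (taken from the Egger fit
#' when supplied, else refit), MR-PRESSO (global, outlier and distortion
#' tests) and the leave-one-out analysis.
#'
#' @param h an `mr_harmonized` tibble.
#' @param estimates optional estimate tibble from [run_all_methods()]; its
#'   Egger row is reused.
#' @param seed seed for the MR-PRESSO simulations.
#' @param n_sim MR-PRESSO simulation count (default 1000).
#' @param outlier_alpha MR-PRESSO outlier significance level (default 0.05).
#' @return A list of class `mr_sensitivity` with elements `q_stat`, `q_df`,
#'   `q_pvalue`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `presso_global_p`, `presso_outliers`,
#'   `presso_distortion_p`, `loo`, `n_snp`. MR-PRESSO fields are `NA` when
#'   fewer than 4 SNPs are available.
#' @export
full_sensitivity <- function(h, estimates = NULL, seed = 1, n_sim = 1000,
                             outlier_alpha = 0.05) {
  h <- check_harmonized(h, 2L, "sensitivity analysis")
  q <- cochran_q(h)
  if (!is.null(estimates) && "egger" %in% estimates$method) {
    eg <- estimates[estimates$method == "egger", ]
  } else if (nrow(h) >= 3) {
    eg <- mr_egger(h)
  } else {
    eg <- NULL
  }
  if (nrow(h) >= 4) {
    pr <- mr_presso(h, n_sim = n_sim, outlier_alpha = outlier_alpha,
                    seed = substream_seed(seed, "presso"))
    presso_global_p <- pr$global_p
    presso_outliers <- pr$outliers
    presso_distortion_p <- pr$distortion_p
  } else {
    pr <- NULL
    presso_global_p <- NA_real_
    presso_outliers <- character(0)
    presso_distortion_p <- NA_real_
  }
  loo <- if (nrow(h) >= 3) leave_one_out(h) else NULL
  structure(list(
    exposure_id = attr(h, "exposure_id"),
    outcome_id = attr(h, "outcome_id"),
    n_snp = nrow(h),
    q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$egger_intercept,
    egger_intercept_se = if (is.null(eg)) NA_real_ else eg$egger_intercept_se,
    egger_intercept_p = if (is.null(eg)) NA_real_ else eg$egger_intercept_p,
    presso_global_p = presso_global_p,
    presso_outliers = presso_outliers,
    presso_distortion_p = presso_distortion_p,
    presso = pr,
    loo = loo
  ), class = "mr_sensitivity")
}
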