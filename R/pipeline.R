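#' Analysis parameters for the MR screening and mediation pipeline
#'
#' Bundles every threshold and method option with its conventional default:
#' exposure instruments at p < 1e-5 (molecular traits), outcome (reverse)
#' instruments at p < 5e-8, LD clumping at r-squared 0.001 within a
#' 10,000 kb window, instrument strength F > 10 and MAF > 0.01, and a 0.05
#' significance level throughout.
#'
#' @param exposure_p instrument p-value threshold for exposures
#'   (default 1e-5).
#' @param outcome_p outcome-association exclusion threshold (default 5e-8).
#' @param reverse_p instrument threshold for reverse MR, where the outcome
#'   GWAS supplies the instruments (default 5e-8).
#' @param clump_r2,clump_kb LD-clumping parameters (defaults 0.001, 10000).
#' @param f_min,maf_min instrument-strength minima (defaults 10, 0.01).
#' @param alpha significance level for screening gates and mediation
#'   (default 0.05).
#' @param ivw_model `"random"` or `"fixed"`; see [mr_ivw()].
#' @param n_boot bootstrap replicates for median/mode standard errors
#'   (default 1000).
#' @param presso_nsim MR-PRESSO simulation count (default 1000).
#' @param proportion_floor smallest `|beta_t|` with a defined mediated
#'   proportion (default 1e-8).
#' @param fdr append a Benjamini-Hochberg adjusted p column to stage outputs
#'   (informational; never changes pass/fail) (default `FALSE`).
#' @return A validated list of class `mr_params`.
#' @export
mr_params <- function(exposure_p = 1e-5, outcome_p = 5e-8, reverse_p = 5e-8,
                      clump_r2 = 0.001, clump_kb = 10000,
                      f_min = 10, maf_min = 0.01, alpha = 0.05,
                      ivw_model = c("random", "fixed"),
                      n_boot = 1000, presso_nsim = 1000,
                      proportion_floor = 1e-8, fdr = FALSE) {
  ivw_model <- match.arg(ivw_model)
  stopifnot(exposure_p > 0, exposure_p < 1, outcome_p > 0, outcome_p < 1,
            reverse_p > 0, reverse_p < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb >= 0,
            f_min >= 0, maf_min >= 0, maf_min < 0.5,
            alpha > 0, alpha < 1, n_boot >= 0, presso_nsim >= 1,
            proportion_floor > 0)
  structure(list(exposure_p = exposure_p, outcome_p = outcome_p,
                 reverse_p = reverse_p, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min, maf_min = maf_min,
                 alpha = alpha, ivw_model = ivw_model, n_boot = n_boot,
                 presso_nsim = presso_nsim,
                 proportion_floor = proportion_floor, fdr = isTRUE(fdr)),
            class = c("mr_params", "list"))
}

#' Screen a catalog of exposures against one outcome
#'
#' For every exposure table: select instruments, harmonize, run the five MR
#' methods, the full sensitivity suite, and the four-gate strict screen.
#' Failures of individual exposures (no instruments, empty harmonization)
#' are recorded and skipped, never fatal, so large catalogs survive
#' individual dropouts.
#'
#' @param exposures named list of `gwas_sumstats` tibbles.
#' @param outcome outcome `gwas_sumstats` tibble.
#' @param ld [ld_matrix()] or `NULL`.
#' @param params [mr_params()] list.
#' @param seed master seed; each exposure gets its own substream.
#' @return A list of class `mr_screen_stage`: `decisions` (one row per
#'   screened exposure), `estimates` (all method rows), `sensitivity` (one
#'   row per exposure), `skipped` (exposure id + reason), and counts.
#' @export
run_screen_stage <- function(exposures, outcome, ld = NULL,
                             params = mr_params(), seed = 1) {
  if (length(exposures) == 0) {
    abort("exposure catalog is empty", class = "mrpath_error_config")
  }
  if (!inherits(outcome, "data.frame") || nrow(outcome) == 0) {
    abort("outcome table is missing or empty", class = "mrpath_error_config")
  }
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, trait_id_of, character(1))
  }
  decisions <- list(); estimates <- list(); sens_rows <- list()
  skipped <- list()
  for (nm in names(exposures)) {
    res <- tryCatch({
      ivs <- select_instruments(exposures[[nm]], outcome, ld,
                                p_threshold = params$exposure_p,
                                r2_max = params$clump_r2,
                                window_kb = params$clump_kb,
                                outcome_p = params$outcome_p,
                                f_min = params$f_min,
                                maf_min = params$maf_min)
      h <- harmonize(ivs, outcome)
      ests <- run_all_methods(h, seed = substream_seed(seed, nm),
                              n_boot = params$n_boot,
                              ivw_model = params$ivw_model)
      sens <- full_sensitivity(h, ests,
                               seed = substream_seed(seed, paste0(nm, "_s")),
                               n_sim = params$presso_nsim)
      dec <- screen(ests, sens, alpha = params$alpha)
      dec$exposure_id <- nm
      list(dec = dec, ests = ests, sens = tidy_sensitivity_row(sens, nm))
    }, error = function(e) {
      if (inherits(e, c("mrpath_error_no_instruments",
                        "mrpath_error_empty_harmonization",
                        "mrpath_error_insufficient_instruments"))) {
        inform(sprintf("skipping exposure '%s': %s", nm,
                       conditionMessage(e)))
        NULL
      } else {
        stop(e)
      }
    })
    if (is.null(res)) {
      skipped[[nm]] <- tibble::tibble(exposure_id = nm, reason = "error")
    } else {
      decisions[[nm]] <- res$dec
      estimates[[nm]] <- tibble::as_tibble(res$ests)
      sens_rows[[nm]] <- res$sens
    }
  }
  decisions <- dplyr::bind_rows(decisions)
  if (params$fdr && nrow(decisions) > 0) {
    decisions$ivw_p_fdr <- p.adjust(decisions$ivw_p, method = "BH")
  }
  structure(list(decisions = decisions,
                 estimates = dplyr::bind_rows(estimates),
                 sensitivity = dplyr::bind_rows(sens_rows),
                 skipped = dplyr::bind_rows(skipped),
                 n_screened = nrow(decisions),
                 n_passed = sum(decisions$passed %||% logical(0))),
            class = "mr_screen_stage")
}

tidy_sensitivity_row <- function(sens, exposure_id) {
  tibble::tibble(
    exposure_id = exposure_id,
    outcome_id = sens$outcome_id %||% "outcome",
    n_snp = sens$n_snp,
    q_stat = sens$q_stat, q_df = sens$q_df, q_pvalue = sens$q_pvalue,
    egger_intercept = sens$egger_intercept,
    egger_intercept_se = sens$egger_intercept_se,
    egger_intercept_p = sens$egger_intercept_p,
    presso_global_p = sens$presso_global_p,
    presso_n_outliers = length(sens$presso_outliers),
    presso_outliers = paste(sens$presso_outliers, collapse = ","),
    presso_distortion_p = sens$presso_distortion_p
  )
}

#' Run the mediation stage over passed exposures and mediators
#'
#' For every exposure x mediator pair whose exposure-to-mediator IVW leg is
#' significant, runs [run_mediation()]; pathways flagged by the reverse-MR
#' check are removed; the final table is sorted by the Sobel p-value.
#' Per-pair failures are logged and skipped.
#'
#' @param exposures,mediators named lists of `gwas_sumstats` tibbles that
#'   passed screening.
#' @param outcome outcome `gwas_sumstats` tibble.
#' @param ld [ld_matrix()] or `NULL`.
#' @param params [mr_params()] list.
#' @param seed master seed.
#' @param screen_legs passed through to [run_mediation()] (default `TRUE`).
#' @return A tibble of mediation results (possibly empty), one row per
#'   surviving pathway, sorted by `pvalue`; with a `pvalue_fdr` column when
#'   `params$fdr`.
#' @export
run_mediation_stage <- function(exposures, mediators, outcome, ld = NULL,
                                params = mr_params(), seed = 1,
                                screen_legs = TRUE) {
  stopifnot(length(exposures) > 0, length(mediators) > 0)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, trait_id_of, character(1))
  }
  if (is.null(names(mediators))) {
    names(mediators) <- vapply(mediators, trait_id_of, character(1))
  }
  rows <- list()
  for (en in names(exposures)) {
    for (mn in names(mediators)) {
      res <- tryCatch(
        run_mediation(exposures[[en]], mediators[[mn]], outcome, ld,
                      params = params,
                      seed = substream_seed(seed, paste(en, mn)),
                      screen_legs = screen_legs),
        error = function(e) {
          if (inherits(e, c("mrpath_error_mediation_leg",
                            "mrpath_error_no_instruments",
                            "mrpath_error_empty_harmonization",
                            "mrpath_error_insufficient_instruments",
                            "mrpath_error_undefined_proportion"))) {
            inform(sprintf("skipping pathway %s -> %s: %s", en, mn,
                           conditionMessage(e)))
            NULL
          } else {
            stop(e)
          }
        })
      if (!is.null(res)) {
        res$exposure_id <- en
        res$mediator_id <- mn
        rows[[paste(en, mn)]] <- tibble::as_tibble(res)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warn("no mediation pathways could be evaluated")
    return(out)
  }
  out <- out[!out$reverse_flagged, , drop = FALSE]
  out <- out[order(out$pvalue), , drop = FALSE]
  if (params$fdr && nrow(out) > 0) {
    out$pvalue_fdr <- p.adjust(out$pvalue, method = "BH")
  }
  out
}
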