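#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR result
#'
#' @param x an `mr_result` from [run_all_methods()].
#' @param ... unused.
#' @return A plain tibble, one row per method, with the estimate columns
#'   (`exposure`, `outcome`, `method`, `n_snp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `or`, `or_ci_low`, `or_ci_high`).
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  cols <- c("exposure", "outcome", "method", "n_snp", "beta", "se",
            "ci_low", "ci_high", "pvalue", "or", "or_ci_low", "or_ci_high")
  tibble::as_tibble(x)[, intersect(cols, names(x))]
}

#' One-row summary of an MR result
#'
#' @param x an `mr_result` from [run_all_methods()].
#' @param ... unused.
#' @return A one-row tibble: ids, SNP count, the primary (IVW) estimate and
#'   p-value, OR, and whether all methods agree in direction.
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  primary <- if ("ivw" %in% x$method) {
    x[x$method == "ivw", ]
  } else {
    x[1, ]
  }
  tibble::tibble(
    exposure = primary$exposure, outcome = primary$outcome,
    n_snp = primary$n_snp,
    method_primary = primary$method,
    beta = primary$beta, se = primary$se, pvalue = primary$pvalue,
    or = primary$or,
    n_methods = nrow(x),
    direction_consistent = direction_consistent(x)
  )
}

#' Tidy a sensitivity report into one diagnostic row per test
#'
#' @param x an `mr_sensitivity` from [full_sensitivity()].
#' @param ... unused.
#' @return A tibble with columns `test`, `statistic`, `pvalue`, `detail`.
#' @method tidy mr_sensitivity
#' @export
tidy.mr_sensitivity <- function(x, ...) {
  tibble::tibble(
    test = c("cochran_q", "egger_intercept", "presso_global",
             "presso_distortion"),
    statistic = c(x$q_stat, x$egger_intercept, NA_real_,
                  x$presso$distortion_coef %||% NA_real_),
    pvalue = c(x$q_pvalue, x$egger_intercept_p, x$presso_global_p,
               x$presso_distortion_p),
    detail = c(sprintf("df=%d", x$q_df),
               sprintf("se=%.4g", x$egger_intercept_se),
               sprintf("outliers=%s",
                       if (length(x$presso_outliers) == 0) "none"
                       else paste(x$presso_outliers, collapse = ",")),
               "raw vs outlier-corrected shift")
  )
}

#' One-row summary of a sensitivity report
#'
#' @param x an `mr_sensitivity` from [full_sensitivity()].
#' @param ... unused.
#' @return A one-row tibble of the headline diagnostics.
#' @method glance mr_sensitivity
#' @export
glance.mr_sensitivity <- function(x, ...) {
  tidy_sensitivity_row(x, x$exposure_id %||% "exposure")
}

#' Tidy an MR-PRESSO fit
#'
#' @param x an `mr_presso` from [mr_presso()].
#' @param ... unused.
#' @return The per-SNP outlier-test tibble.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outlier_tests

#' One-row summary of an MR-PRESSO fit
#'
#' @param x an `mr_presso` from [mr_presso()].
#' @param ... unused.
#' @return A one-row tibble: global p, outlier count, raw and corrected
#'   estimates, distortion results.
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_p = x$global_p,
    n_outliers = length(x$outliers),
    beta_raw = x$raw$beta,
    beta_corrected = if (is.null(x$corrected)) NA_real_ else x$corrected$beta,
    distortion_coef = x$distortion_coef,
    distortion_p = x$distortion_p,
    n_sim = x$n_sim
  )
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf("MR sensitivity report: %s -> %s (%d SNPs)\n",
              x$exposure_id %||% "exposure", x$outcome_id %||% "outcome",
              x$n_snp))
  print(tidy.mr_sensitivity(x))
  invisible(x)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global p = %.4g, %d outlier(s)%s\n",
              x$global_p, length(x$outliers),
              if (length(x$outliers)) paste0(" [",
                paste(x$outliers, collapse = ", "), "]") else ""))
  invisible(x)
}
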