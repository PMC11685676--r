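#' @importFrom ggplot2 ggplot aes geom_point geom_pointrange geom_errorbarh
#'   geom_vline geom_abline labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Forest plot of the five MR estimates
#'
#' Point estimates with 95% confidence intervals per method, on the log-odds
#' scale, with a reference line at zero.
#'
#' @param object an `mr_result` from [run_all_methods()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  df <- tidy.mr_result(object)
  ggplot(df, aes(x = .data$beta, y = .data$method)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_pointrange(aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    labs(x = "causal effect (log OR)", y = NULL,
         title = sprintf("%s → %s",
                         attr(object, "exposure_id") %||% "exposure",
                         attr(object, "outcome_id") %||% "outcome")) +
    theme_minimal()
}

#' Leave-one-out forest plot
#'
#' IVW estimate after removing each SNP in turn; a SNP whose removal moves
#' the estimate across the reference line is driving the result.
#'
#' @param object an `mr_loo` from [leave_one_out()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$snp_id <- factor(df$snp_id, levels = rev(df$snp_id))
  ggplot(df, aes(x = .data$beta, y = .data$snp_id)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_pointrange(aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    labs(x = "IVW estimate without this SNP", y = NULL) +
    theme_minimal()
}

#' Scatter plot of SNP effects with fitted MR slopes
#'
#' Per-SNP outcome effects against exposure effects with error bars, and
#' one fitted line per method (IVW and the robust estimators through the
#' origin; MR-Egger with its intercept).
#'
#' @param h an `mr_harmonized` tibble.
#' @param estimates an estimate tibble from [run_all_methods()].
#' @return A ggplot object.
#' @export
plot_snp_effects <- function(h, estimates) {
  est <- tibble::as_tibble(estimates)
  est$intercept <- ifelse(est$method == "egger",
                          est[["egger_intercept"]] %||% 0, 0)
  ggplot(tibble::as_tibble(h), aes(x = .data$beta_x, y = .data$beta_y)) +
    geom_errorbarh(aes(xmin = .data$beta_x - .data$se_x,
                       xmax = .data$beta_x + .data$se_x),
                   colour = "grey70", height = 0) +
    ggplot2::geom_errorbar(aes(ymin = .data$beta_y - .data$se_y,
                               ymax = .data$beta_y + .data$se_y),
                           colour = "grey70", width = 0) +
    geom_point() +
    geom_abline(data = est,
                aes(intercept = .data$intercept, slope = .data$beta,
                    colour = .data$method)) +
    labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
         colour = "method") +
    theme_minimal()
}
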