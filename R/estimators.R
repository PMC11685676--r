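estimate_row <- function(method, n_snp, beta, se, pvalue, ci_low, ci_high,
                         ...) {
  extras <- list(...)
  out <- tibble::tibble(
    method = method, n_snp = as.integer(n_snp),
    beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pvalue = pvalue,
    or = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high)
  )
  for (nm in names(extras)) out[[nm]] <- extras[[nm]]
  out
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate `beta_y / beta_x` with first-order standard
#' error `|se_y / beta_x|`; the building block of every multi-SNP estimator.
#'
#' @param beta_x,se_x SNP-exposure effect and standard error.
#' @param beta_y,se_y SNP-outcome effect and standard error.
#' @return A one-row estimate tibble (`method = "wald_ratio"`).
#' @export
mr_wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) {
    abort("Wald ratio undefined for beta_x = 0",
          class = "mrpath_error_undefined_ratio")
  }
  b <- beta_y / beta_x
  s <- abs(se_y / beta_x)
  z <- z_crit()
  estimate_row("wald_ratio", 1L, b, s,
               two_sided_normal_p(b, s), b - z * s, b + z * s)
}

# shared IVW sums; returns list with beta, se_fixed, q
ivw_core <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  list(beta = beta,
       se_fixed = sqrt(1 / sxx),
       q = sum(w * (by - beta * bx)^2))
}

#' Inverse-variance-weighted estimator
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects through the origin with weights `1 / se_y^2`. The default
#' multiplicative random-effects model scales the fixed-effects standard
#' error by `max(1, sqrt(Q / (n - 1)))`, where Q is Cochran's heterogeneity
#' statistic at the estimate.
#'
#' @param h an `mr_harmonized` tibble with >= 2 SNPs.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return A one-row estimate tibble (`method = "ivw"`) with a `q_stat`
#'   column.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  h <- check_harmonized(h, 2L, "IVW")
  n <- nrow(h)
  core <- ivw_core(h$beta_x, h$beta_y, h$se_y)
  scale <- if (model == "random") max(1, sqrt(core$q / (n - 1))) else 1
  se <- core$se_fixed * scale
  z <- z_crit()
  estimate_row("ivw", n, core$beta, se,
               two_sided_normal_p(core$beta, se),
               core$beta - z * se, core$beta + z * se,
               q_stat = core$q, ivw_model = model)
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept, weights `1 / se_y^2`. The slope is the
#' causal estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy and its test is the screening gate for pleiotropy. Both
#' standard errors carry the multiplicative random-effects scaling
#' `max(1, sqrt(Q_egger / (n - 2)))`; p-values and confidence limits use the
#' t distribution with `n - 2` degrees of freedom (regression convention).
#'
#' @param h an `mr_harmonized` tibble with >= 3 SNPs.
#' @param model `"random"` (default) or `"fixed"` standard-error model.
#' @return A one-row estimate tibble (`method = "egger"`) with columns
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  h <- check_harmonized(h, 3L, "MR-Egger")
  n <- nrow(h)
  w <- 1 / h$se_y^2
  x <- h$beta_x; y <- h$beta_y
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  inter <- ybar - slope * xbar
  q <- sum(w * (y - inter - slope * x)^2)
  scale <- if (model == "random") max(1, sqrt(q / (n - 2))) else 1
  se_slope <- sqrt(1 / sxx) * scale
  se_inter <- sqrt(1 / sw + xbar^2 / sxx) * scale
  df <- n - 2
  tq <- qt(0.975, df)
  p_slope <- 2 * pt(-abs(slope / se_slope), df)
  p_inter <- 2 * pt(-abs(inter / se_inter), df)
  estimate_row("egger", n, slope, se_slope, p_slope,
               slope - tq * se_slope, slope + tq * se_slope,
               egger_intercept = inter,
               egger_intercept_se = se_inter,
               egger_intercept_p = p_inter,
               q_stat = q)
}

ratio_stats <- function(h) {
  list(ratio = h$beta_y / h$beta_x,
       # first-order variance of the per-SNP ratio
       var = h$se_y^2 / h$beta_x^2)
}

weighted_median_point <- function(ratio, wvar) {
  w <- (1 / wvar)
  w <- w / sum(w)
  o <- order(ratio)
  r <- ratio[o]; w <- w[o]
  p <- cumsum(w) - w / 2
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

boot_se <- function(h, point_fun, n_boot, seed) {
  if (is.null(n_boot) || n_boot < 1) return(NA_real_)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(h), h$beta_x, h$se_x)
      by <- rnorm(nrow(h), h$beta_y, h$se_y)
      point_fun(bx, by)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted-median estimator
#'
#' The interpolated weighted median of the per-SNP Wald ratios, with
#' inverse-variance weights (ratio variance taken as `se_y^2 / beta_x^2`);
#' consistent when instruments carrying at least half the weight are valid.
#' The standard error comes from a parametric bootstrap that redraws both
#' effect vectors from normals with their reported standard errors.
#'
#' @param h an `mr_harmonized` tibble with >= 3 SNPs.
#' @param n_boot bootstrap replicates for the standard error (default 1000;
#'   0 skips the bootstrap, leaving `se` and `pvalue` `NA`).
#' @param seed seed for the bootstrap stream.
#' @return A one-row estimate tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  h <- check_harmonized(h, 3L, "weighted median")
  rs <- ratio_stats(h)
  b <- weighted_median_point(rs$ratio, rs$var)
  se <- boot_se(h, function(bx, by) {
    weighted_median_point(by / bx, h$se_y^2 / bx^2)
  }, n_boot, seed)
  z <- z_crit()
  estimate_row("weighted_median", nrow(h), b, se,
               two_sided_normal_p(b, se),
               b - z * se, b + z * se, n_boot = as.integer(n_boot))
}

mode_bandwidth <- function(ratio, phi) {
  m <- length(ratio)
  s <- sd(ratio)
  iq <- IQR(ratio) / 1.34
  spread <- if (iq > 0) min(s, iq) else s
  phi * 0.9 * spread * m^(-1 / 5)
}

mode_point <- function(ratio, w, phi, grid_n = 512) {
  bw <- mode_bandwidth(ratio, phi)
  if (!is.finite(bw) || bw <= 0) return(ratio[1])  # all ratios identical
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = grid_n)
  dens <- vapply(grid, function(g) {
    sum(w * exp(-(g - ratio)^2 / (2 * bw^2)))
  }, numeric(1))
  top <- which(dens == max(dens))
  mean(grid[range(top)])  # tie -> midpoint of tied grid points
}

#' Mode-based estimator (weighted or simple)
#'
#' The argmax of a Gaussian-kernel density over the per-SNP Wald ratios,
#' evaluated on a 512-point grid spanning the ratio range plus three
#' bandwidths; consistent when the largest cluster of instruments is valid.
#' Bandwidth is `phi * 0.9 * min(sd, IQR/1.34) * m^(-1/5)`. Weights are
#' inverse-variance when `weighted`, equal otherwise (the simple mode,
#' sometimes called the sample mode). Standard error by the same parametric
#' bootstrap as [mr_weighted_median()].
#'
#' @param h an `mr_harmonized` tibble with >= 3 SNPs.
#' @param weighted use inverse-variance weights (default `TRUE`).
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot,seed bootstrap controls; see [mr_weighted_median()].
#' @return A one-row estimate tibble (`method = "weighted_mode"` or
#'   `"simple_mode"`) with a `bandwidth` column.
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = 1) {
  h <- check_harmonized(h, 3L, "mode-based estimator")
  rs <- ratio_stats(h)
  wts <- function(var) {
    if (weighted) {
      w <- 1 / var
    } else {
      w <- rep(1, length(var))
    }
    w / sum(w)
  }
  b <- mode_point(rs$ratio, wts(rs$var), phi)
  se <- boot_se(h, function(bx, by) {
    r <- by / bx
    mode_point(r, wts(h$se_y^2 / bx^2), phi)
  }, n_boot, seed)
  z <- z_crit()
  estimate_row(if (weighted) "weighted_mode" else "simple_mode",
               nrow(h), b, se, two_sided_normal_p(b, se),
               b - z * se, b + z * se,
               bandwidth = mode_bandwidth(rs$ratio, phi),
               n_boot = as.integer(n_boot))
}

#' Run the five MR estimators on one harmonized exposure-outcome pair
#'
#' Computes IVW (the primary method), MR-Egger, weighted median, weighted
#' mode and simple mode. With only 2 SNPs the set degrades to IVW alone;
#' with 1 SNP to the Wald ratio; the degradation is recorded. Each
#' stochastic estimator receives its own seed substream derived from `seed`,
#' so results are deterministic given `(h, seed)`.
#'
#' @param h an `mr_harmonized` tibble.
#' @param seed master seed for the bootstrap substreams.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param ivw_model `"random"` or `"fixed"`; see [mr_ivw()].
#' @param phi mode bandwidth multiplier.
#' @return A tibble of class `mr_result`, one row per method, with
#'   attributes `exposure_id`, `outcome_id`, `harmonized`, `seed`,
#'   `degraded`.
#' @export
run_all_methods <- function(h, seed = 1, n_boot = 1000,
                            ivw_model = "random", phi = 1) {
  hh <- check_harmonized(h, 1L, "MR analysis")
  n <- nrow(hh)
  if (n == 1) {
    est <- mr_wald_ratio(hh$beta_x, hh$se_x, hh$beta_y, hh$se_y)
    degraded <- "wald_ratio_only"
  } else if (n == 2) {
    est <- mr_ivw(hh, model = ivw_model)
    degraded <- "ivw_only"
  } else {
    est <- dplyr::bind_rows(
      mr_ivw(hh, model = ivw_model),
      mr_egger(hh),
      mr_weighted_median(hh, n_boot = n_boot,
                         seed = substream_seed(seed, "weighted_median")),
      mr_mode(hh, weighted = TRUE, phi = phi, n_boot = n_boot,
              seed = substream_seed(seed, "weighted_mode")),
      mr_mode(hh, weighted = FALSE, phi = phi, n_boot = n_boot,
              seed = substream_seed(seed, "simple_mode"))
    )
    degraded <- NA_character_
  }
  est$exposure <- attr(h, "exposure_id") %||% "exposure"
  est$outcome <- attr(h, "outcome_id") %||% "outcome"
  structure(est,
            exposure_id = attr(h, "exposure_id"),
            outcome_id = attr(h, "outcome_id"),
            harmonized = hh, seed = seed, degraded = degraded,
            class = c("mr_result", class(tibble::tibble())))
}

#' Are causal-effect directions consistent across methods?
#'
#' `TRUE` iff all estimates strictly share one sign (a zero estimate counts
#' as inconsistent). One of the strict screening gates.
#'
#' @param estimates an estimate tibble (e.g. from [run_all_methods()]).
#' @return Logical flag.
#' @export
direction_consistent <- function(estimates) {
  b <- estimates$beta
  stopifnot(length(b) >= 1)
  all(b > 0) || all(b < 0)
}
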