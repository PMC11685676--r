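#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Intersects two summary-statistic tables on `snp_id` and aligns the outcome
#' effects to the exposure's effect allele, producing the per-SNP
#' (beta_x, se_x, beta_y, se_y) quadruples every MR estimator consumes.
#'
#' Allele reconciliation per SNP, in order:
#' \enumerate{
#'   \item outcome alleles equal exposure alleles: kept as is;
#'   \item outcome alleles equal exposure alleles swapped: outcome beta
#'     negated (and its effect-allele frequency complemented);
#'   \item after relabeling the outcome alleles to the complementary strand
#'     (A<->T, C<->G), one of the two cases above applies (relabels are
#'     tallied);
#'   \item otherwise the SNP is dropped as allele-incompatible.
#' }
#' Palindromic SNPs (A/T or C/G pairs), whose strand cannot be resolved from
#' alleles alone, are removed under the default policy. The `"infer"` policy
#' instead retains a palindromic SNP when both effect-allele frequencies are
#' present and both minor-allele frequencies are below `maf_inference_max`,
#' aligning by frequency; palindromic SNPs without usable frequencies are
#' still dropped.
#'
#' @param exposure,outcome `gwas_sumstats` tibbles (see [as_gwas_sumstats()]).
#' @param palindromic `"drop"` (default) removes all palindromic SNPs;
#'   `"infer"` applies frequency inference as described above.
#' @param maf_inference_max MAF ceiling for frequency inference (default
#'   0.42); near 0.5 the two strand readings are indistinguishable.
#' @return A tibble of class `mr_harmonized` with columns `snp_id`, `chrom`,
#'   `pos`, `beta_x`, `se_x`, `beta_y`, `se_y`, `eaf_x`, `n_x`, `pvalue_x`,
#'   in exposure order, and attributes `exposure_id`, `outcome_id`,
#'   `n_palindromic_dropped`, `n_incompatible`, `n_strand_relabelled`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic = c("drop", "infer"),
                      maf_inference_max = 0.42) {
  palindromic <- match.arg(palindromic)
  stopifnot(nrow(exposure) > 0, nrow(outcome) > 0)
  o <- tibble::as_tibble(outcome)[, c("snp_id", "effect_allele",
                                      "other_allele", "eaf", "beta", "se")]
  names(o) <- c("snp_id", "ea_y", "oa_y", "eaf_y", "beta_y", "se_y")
  m <- dplyr::inner_join(tibble::as_tibble(exposure), o, by = "snp_id")

  ea_x <- m$effect_allele; oa_x <- m$other_allele
  ea_y <- m$ea_y; oa_y <- m$oa_y
  pal <- is_palindromic(ea_x, oa_x)

  direct  <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
  flip_direct  <- !direct & !swapped & cea == ea_x & coa == oa_x
  flip_swapped <- !direct & !swapped & cea == oa_x & coa == ea_x
  n_relabel <- sum((flip_direct | flip_swapped) & !pal)

  action <- rep("incompatible", nrow(m))
  action[direct | flip_direct] <- "keep"
  action[swapped | flip_swapped] <- "flip"

  if (any(pal)) {
    if (palindromic == "drop") {
      action[pal] <- "palindromic"
    } else {
      # frequency inference: usable only when both frequencies are well away
      # from 0.5; align the outcome reading whose frequency matches
      maf_x <- pmin(m$eaf, 1 - m$eaf)
      maf_y <- pmin(m$eaf_y, 1 - m$eaf_y)
      usable <- pal & !is.na(maf_x) & !is.na(maf_y) &
        maf_x < maf_inference_max & maf_y < maf_inference_max
      concord <- (m$eaf < 0.5) == (m$eaf_y < 0.5)
      action[pal] <- "palindromic"
      action[usable & concord] <- "keep"
      action[usable & !concord] <- "flip"
    }
  }

  beta_y <- ifelse(action == "flip", -m$beta_y, m$beta_y)
  keep <- action %in% c("keep", "flip")
  h <- tibble::tibble(
    snp_id = m$snp_id[keep],
    chrom = m$chrom[keep],
    pos = m$pos[keep],
    beta_x = m$beta[keep],
    se_x = m$se[keep],
    beta_y = beta_y[keep],
    se_y = m$se_y[keep],
    eaf_x = m$eaf[keep],
    n_x = m$n[keep],
    pvalue_x = m$pvalue[keep]
  )
  if (nrow(h) == 0) {
    abort(sprintf(
      "harmonization of '%s' vs '%s' left zero SNPs (%d palindromic, %d allele-incompatible, %d matched by id)",
      trait_id_of(exposure, "exposure"), trait_id_of(outcome, "outcome"),
      sum(action == "palindromic"), sum(action == "incompatible"), nrow(m)),
      class = "mrpath_error_empty_harmonization")
  }
  structure(h,
            exposure_id = trait_id_of(exposure, "exposure"),
            outcome_id = trait_id_of(outcome, "outcome"),
            n_palindromic_dropped = sum(action == "palindromic"),
            n_incompatible = sum(action == "incompatible"),
            n_strand_relabelled = n_relabel,
            class = c("mr_harmonized", class(tibble::tibble())))
}

check_harmonized <- function(h, min_snp = 1L, method = "estimator") {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  missing_cols <- setdiff(need, names(h))
  if (length(missing_cols) > 0) {
    abort(sprintf("harmonized set lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "mrpath_error_config")
  }
  ok <- stats::complete.cases(h[, need]) &
    h$se_x > 0 & h$se_y > 0 &
    is.finite(h$beta_x) & is.finite(h$beta_y)
  h <- h[ok, , drop = FALSE]
  if (nrow(h) < min_snp) stop_insufficient(method, min_snp, nrow(h))
  h
}
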