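#' Filter a summary-statistics table on association p-value
#'
#' Strict `pvalue < threshold` filter, preserving row order. The
#' conventional thresholds are 5e-8 for a well-powered outcome GWAS and
#' 1e-5 for molecular traits with fewer genome-wide-significant hits.
#'
#' @param table a `gwas_sumstats` tibble.
#' @param threshold p-value threshold in (0, 1).
#' @return The filtered tibble (attributes preserved).
#' @export
filter_pvalue <- function(table, threshold) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  keep_attrs(table, table[table$pvalue < threshold, , drop = FALSE])
}

keep_attrs <- function(src, dst) {
  for (a in c("trait_id", "trait_class")) attr(dst, a) <- attr(src, a)
  class(dst) <- class(src)
  dst
}

#' Greedy LD clumping of a summary-statistics table
#'
#' Retains the most significant SNP per LD neighborhood: SNPs are visited in
#' ascending p-value order (ties broken by `snp_id`); each accepted index
#' SNP discards every remaining SNP on the same chromosome within
#' `window_kb` kilobases having r-squared >= `r2_max` with it. SNP pairs
#' absent from `ld` are treated as unlinked.
#'
#' @param table a `gwas_sumstats` tibble with `chrom` and `pos`.
#' @param ld an [ld_matrix()] or `NULL` (all pairs unlinked).
#' @param r2_max r-squared at or above which two SNPs conflict
#'   (default 0.001).
#' @param window_kb clumping window in kb (default 10000); two SNPs conflict
#'   only when `|pos_a - pos_b| <= window_kb * 1000` on the same chromosome.
#' @return The clumped tibble in genomic (chrom, pos) order.
#' @export
clump <- function(table, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  if (nrow(table) <= 1) return(table)
  tab <- tibble::as_tibble(table)
  ord <- order(tab$pvalue, tab$snp_id)
  remaining <- ord
  accepted <- integer(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    accepted <- c(accepted, idx)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- !is.na(tab$chrom[remaining]) & !is.na(tab$chrom[idx]) &
      tab$chrom[remaining] == tab$chrom[idx]
    near <- same_chr & !is.na(tab$pos[remaining]) & !is.na(tab$pos[idx]) &
      abs(tab$pos[remaining] - tab$pos[idx]) <= window_kb * 1000
    if (any(near)) {
      r2 <- ld_r2_with(ld, tab$snp_id[idx], tab$snp_id[remaining[near]])
      drop <- rep(FALSE, length(remaining))
      drop[near] <- r2 >= r2_max
      remaining <- remaining[!drop]
    }
  }
  out <- tab[accepted, , drop = FALSE]
  chrom_num <- suppressWarnings(as.numeric(out$chrom))
  out <- out[order(chrom_num, out$chrom, out$pos, out$snp_id), , drop = FALSE]
  keep_attrs(table, out)
}

#' Exclude SNPs significantly associated with the outcome
#'
#' Drops exposure SNPs whose outcome association p-value is below
#' `threshold` (such SNPs may act on the outcome directly, violating the
#' exclusion-restriction assumption). SNPs absent from the outcome table are
#' retained; they fall out at harmonization if truly unmatchable.
#'
#' @param table exposure `gwas_sumstats` tibble.
#' @param outcome outcome `gwas_sumstats` tibble.
#' @param threshold outcome p-value below which a SNP is excluded
#'   (default 5e-8).
#' @return The filtered exposure tibble.
#' @export
exclude_outcome_associated <- function(table, outcome, threshold = 5e-8) {
  bad <- outcome$snp_id[outcome$pvalue < threshold]
  keep_attrs(table, table[!table$snp_id %in% bad, , drop = FALSE])
}

#' Per-SNP instrument strength (variance explained and F-statistic)
#'
#' With an effect-allele frequency and sample size available, the variance
#' explained by a SNP under the standardized-trait approximation is
#' `R2 = 2 * maf * (1 - maf) * beta^2` and its strength
#' `F = R2 * (n - 2) / (1 - R2)`. When `eaf` or `n` is missing the square of
#' the Wald z, `(beta / se)^2`, is used instead; the formula applied is
#' recorded per SNP.
#'
#' @param table a `gwas_sumstats` tibble.
#' @param n sample sizes (recycled); defaults to the table's `n` column.
#' @return The table with columns `maf`, `r2_explained`, `f_stat`,
#'   `f_method` (`"r2"` or `"wald"`) appended.
#' @export
instrument_strength <- function(table, n = table$n) {
  n <- rep(n, length.out = nrow(table))
  if (any(!is.na(n) & n <= 2)) {
    abort("sample size must exceed 2 to compute an F-statistic",
          class = "mrpath_error_domain")
  }
  maf <- pmin(table$eaf, 1 - table$eaf)
  r2 <- 2 * maf * (1 - maf) * table$beta^2
  use_r2 <- !is.na(maf) & !is.na(n)
  f <- ifelse(use_r2, r2 * (n - 2) / (1 - r2), (table$beta / table$se)^2)
  out <- tibble::as_tibble(table)
  out$maf <- maf
  out$r2_explained <- ifelse(use_r2, r2, NA_real_)
  out$f_stat <- f
  out$f_method <- ifelse(use_r2, "r2", "wald")
  keep_attrs(table, out)
}

#' Select genetic instruments for one exposure
#'
#' Applies the instrument-selection cascade: (1) association p-value below
#' `p_threshold`; (2) LD clumping at `r2_max` within `window_kb`;
#' (3) exclusion of SNPs associated with the outcome at `outcome_p`;
#' (4) strength filter `F > f_min` and MAF `> maf_min` (the MAF gate is
#' skipped for SNPs without a frequency). Per-stage attrition counts are
#' attached as the `"attrition"` attribute; an empty result at any stage is
#' an error naming that stage.
#'
#' @param table exposure `gwas_sumstats` tibble.
#' @param outcome outcome `gwas_sumstats` tibble.
#' @param ld [ld_matrix()] or `NULL`.
#' @param p_threshold exposure significance threshold (default 1e-5).
#' @param r2_max,window_kb clumping parameters; see [clump()].
#' @param outcome_p outcome-association exclusion threshold (default 5e-8).
#' @param f_min minimum F-statistic (default 10).
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param exclude_before_clump run the outcome-association exclusion before
#'   clumping instead of after (default `FALSE`).
#' @return Instrument tibble with strength columns (see
#'   [instrument_strength()]) and an `"attrition"` attribute tibble with
#'   columns `stage`, `n_in`, `n_removed`, `n_out`.
#' @export
select_instruments <- function(table, outcome, ld = NULL,
                               p_threshold = 1e-5,
                               r2_max = 0.001, window_kb = 10000,
                               outcome_p = 5e-8,
                               f_min = 10, maf_min = 0.01,
                               exclude_before_clump = FALSE) {
  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_removed = n_in - n_out, n_out = n_out)
    if (n_out == 0) {
      abort(sprintf("no instruments for '%s' remain after stage '%s'",
                    trait_id_of(table), stage),
            class = "mrpath_error_no_instruments")
    }
  }
  cur <- filter_pvalue(table, p_threshold)
  note("pvalue", nrow(table), nrow(cur))
  if (exclude_before_clump) {
    prev <- nrow(cur)
    cur <- exclude_outcome_associated(cur, outcome, outcome_p)
    note("outcome_association", prev, nrow(cur))
  }
  prev <- nrow(cur)
  cur <- clump(cur, ld, r2_max = r2_max, window_kb = window_kb)
  note("clump", prev, nrow(cur))
  if (!exclude_before_clump) {
    prev <- nrow(cur)
    cur <- exclude_outcome_associated(cur, outcome, outcome_p)
    note("outcome_association", prev, nrow(cur))
  }
  prev <- nrow(cur)
  cur <- instrument_strength(cur)
  keep <- cur$f_stat > f_min & (is.na(cur$maf) | cur$maf > maf_min)
  cur <- keep_attrs(cur, cur[keep, , drop = FALSE])
  note("strength", prev, nrow(cur))
  attr(cur, "attrition") <- dplyr::bind_rows(stages)
  cur
}

#' Find an LD proxy for a missing or low-quality SNP
#'
#' Returns the candidate SNP in highest LD with `snp_id`, provided its
#' r-squared strictly exceeds `r2_min`; ties are broken by lower p-value,
#' then lexicographic `snp_id`.
#'
#' @param snp_id the SNP to substitute.
#' @param ld an [ld_matrix()]; if it does not cover `snp_id`, no proxy is
#'   found.
#' @param candidates `gwas_sumstats` tibble of substitute candidates.
#' @param r2_min minimum r-squared (default 0.8, exclusive).
#' @return A one-row tibble (the chosen candidate with an `r2_proxy`
#'   column), or `NULL` when no candidate qualifies.
#' @export
find_proxy <- function(snp_id, ld, candidates, r2_min = 0.8) {
  cand <- candidates[candidates$snp_id != snp_id, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  r2 <- ld_r2_with(ld, snp_id, cand$snp_id)
  cand$r2_proxy <- unname(r2)
  cand <- cand[cand$r2_proxy > r2_min, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(-cand$r2_proxy, cand$pvalue, cand$snp_id), , drop = FALSE]
  tibble::as_tibble(cand[1, , drop = FALSE])
}
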