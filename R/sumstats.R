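#' Default GWAS-SSF-style column mapping
#'
#' Maps the fields a summary-statistics table must provide to the header
#' names used in the input file. Override individual entries to read files
#' with other dialects, e.g. `gwas_ssf_columns(snp_id = "rsid", pvalue = "p")`.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pvalue,n
#'   column names in the file for each field.
#' @return Named character vector mapping field -> file column.
#' @export
gwas_ssf_columns <- function(snp_id = "variant_id",
                             chrom = "chromosome",
                             pos = "base_pair_location",
                             effect_allele = "effect_allele",
                             other_allele = "other_allele",
                             eaf = "effect_allele_frequency",
                             beta = "beta",
                             se = "standard_error",
                             pvalue = "p_value",
                             n = "n") {
  c(snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
}

required_fields <- c("snp_id", "effect_allele", "other_allele",
                     "beta", "se", "pvalue")
optional_fields <- c("chrom", "pos", "eaf", "n")

#' Coerce a data frame to a validated summary-statistics table
#'
#' Validates per-record invariants (alleles in A/C/G/T and distinct,
#' `se > 0`, `pvalue` in (0, 1], `eaf` in \[0, 1\] when present, finite
#' `beta`), upper-cases alleles, and drops failing rows, recording the tally
#' in the `"n_dropped"` attribute. Duplicate `snp_id`s keep the first
#' occurrence.
#'
#' @param df data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `chrom`, `pos`,
#'   `eaf`, `n`.
#' @param trait_id identifier of the trait this GWAS measured.
#' @param trait_class one of `"metabolite"`, `"immune"`, `"outcome"`,
#'   `"other"`.
#' @return A tibble of class `gwas_sumstats` with attributes `trait_id`,
#'   `trait_class` and `n_dropped`.
#' @export
as_gwas_sumstats <- function(df, trait_id, trait_class = "other") {
  trait_class <- match.arg(trait_class,
                           c("metabolite", "immune", "outcome", "other"))
  missing_cols <- setdiff(required_fields, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("required column(s) missing: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "mrpath_error_config")
  }
  if (nrow(df) == 0) {
    abort("summary-statistics table has no rows",
          class = "mrpath_error_empty_input")
  }
  out <- tibble::as_tibble(df)
  for (f in optional_fields) {
    if (!f %in% names(out)) out[[f]] <- NA
  }
  out <- dplyr::mutate(
    out,
    snp_id = as.character(.data$snp_id),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pvalue = as.numeric(.data$pvalue),
    n = as.numeric(.data$n)
  )
  out <- out[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")]
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(out$snp_id) &
    out$effect_allele %in% bases &
    out$other_allele %in% bases &
    out$effect_allele != out$other_allele &
    is.finite(out$beta) &
    is.finite(out$se) & out$se > 0 &
    is.finite(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1 &
    (is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1))
  n_dropped <- sum(!ok)
  out <- out[ok, ]
  dup <- duplicated(out$snp_id)
  n_dropped <- n_dropped + sum(dup)
  out <- out[!dup, ]
  structure(out,
            trait_id = trait_id,
            trait_class = trait_class,
            n_dropped = n_dropped,
            class = c("gwas_sumstats", class(tibble::tibble())))
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or comma-delimited file with a header row, renames columns
#' according to `column_map`, and validates records via
#' [as_gwas_sumstats()].
#'
#' @param path file path.
#' @param column_map named character vector mapping fields to file columns;
#'   see [gwas_ssf_columns()].
#' @param trait_id trait identifier attached to the table.
#' @param trait_class trait class; see [as_gwas_sumstats()].
#' @return A `gwas_sumstats` tibble; the count of rows dropped for failing
#'   record invariants is in `attr(, "n_dropped")`.
#' @export
read_summary_stats <- function(path, column_map = gwas_ssf_columns(),
                               trait_id = basename(path),
                               trait_class = "other") {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    abort(sprintf("empty summary-statistics file: %s", path),
          class = "mrpath_error_empty_input")
  }
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_guess()))
  missing_req <- required_fields[!column_map[required_fields] %in% names(raw)]
  if (length(missing_req) > 0) {
    abort(sprintf("column(s) named in column_map not found in %s: %s",
                  path,
                  paste(column_map[missing_req], collapse = ", ")),
          class = "mrpath_error_config")
  }
  if (nrow(raw) == 0) {
    abort(sprintf("empty summary-statistics file: %s", path),
          class = "mrpath_error_empty_input")
  }
  present <- column_map[column_map %in% names(raw)]
  df <- raw[, unname(present)]
  names(df) <- names(present)
  as_gwas_sumstats(df, trait_id = trait_id, trait_class = trait_class)
}

trait_id_of <- function(x, default = "trait") {
  attr(x, "trait_id") %||% default
}

#' Write result tables and a run manifest
#'
#' Writes one TSV per result type (`estimates`, `sensitivity`, `loo`,
#' `mediation`, `decisions`, ...) with a stable column order, plus
#' `manifest.json` recording the files written, the parameters and the seed,
#' so a run can be reproduced from the manifest alone.
#'
#' @param results named list of data frames; names become file stems.
#' @param out_dir output directory, created if absent.
#' @param params optional parameter list (e.g. [mr_params()]) stored in the
#'   manifest.
#' @param seed optional seed stored in the manifest.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(results, out_dir, params = NULL, seed = NULL) {
  stopifnot(is.list(results), !is.null(names(results)))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory not writable: %s", out_dir),
          class = "mrpath_error_io")
  }
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(results[[nm]]), f, progress = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "mrpath",
    version = as.character(utils::packageVersion("mrpath")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    params = params,
    files = basename(files)
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, mf))
}
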