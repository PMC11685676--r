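#' Construct an LD matrix object
#'
#' A symmetric matrix of squared allelic correlations (r-squared) keyed by
#' SNP id. SNP pairs absent from the matrix are treated as unlinked
#' (r-squared 0) wherever the matrix is consulted.
#'
#' @param snp_ids character vector of SNP ids (row/column order).
#' @param r2 square numeric matrix of r-squared values.
#' @return A matrix of class `ld_matrix` with `snp_ids` as dimnames.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(r2 < 0 | r2 > 1)) {
    abort("LD r-squared entries must lie in [0, 1]",
          class = "mrpath_error_config")
  }
  if (any(abs(r2 - t(r2)) > 1e-8)) {
    abort("LD matrix must be symmetric", class = "mrpath_error_config")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    abort("LD matrix diagonal must be 1", class = "mrpath_error_config")
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read LD information from a file
#'
#' Accepts either a square-matrix TSV (first column and header are SNP ids)
#' or a long-format TSV with columns `snp_a`, `snp_b`, `r2` (plink
#' `.ld`-style); the long format is symmetrized and given a unit diagonal.
#'
#' @param path file path.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(tab))) {
    ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
    r2 <- diag(1, length(ids))
    dimnames(r2) <- list(ids, ids)
    for (i in seq_len(nrow(tab))) {
      a <- tab$snp_a[i]; b <- tab$snp_b[i]
      r2[a, b] <- tab$r2[i]
      r2[b, a] <- tab$r2[i]
    }
    return(ld_matrix(ids, r2))
  }
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  ld_matrix(ids, m)
}

# r2 between one SNP and a vector of SNPs; pairs not covered by `ld` are
# unlinked (0). `ld = NULL` means no LD information at all.
ld_r2_with <- function(ld, snp, others) {
  out <- setNames(numeric(length(others)), others)
  if (is.null(ld)) return(out)
  ids <- rownames(ld)
  if (!snp %in% ids) return(out)
  hit <- others %in% ids
  out[hit] <- ld[snp, others[hit]]
  out
}
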