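#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats pnorm pt pchisq qnorm qt rnorm runif sd approx quantile
#'   IQR p.adjust setNames
NULL

# Named child seeds so each stochastic component has its own reproducible
# stream; changing one component's draws leaves the others fixed.
# Result stays below 2^31 (R integers are 32-bit).
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(label)
  h <- sum(chars * seq_along(chars)) %% 1000003L
  as.integer(((abs(as.integer(seed)) %% 1000003L) * 2011L + h) %% 2147483647L)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# DNA complement used for strand relabeling during harmonization
complement_allele <- function(x) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[x])
}

is_palindromic <- function(a1, a2) {
  a1 == complement_allele(a2)
}

z_crit <- function(level = 0.95) qnorm(1 - (1 - level) / 2)

two_sided_normal_p <- function(beta, se) {
  p <- 2 * pnorm(-abs(beta / se))
  p[se == 0 & beta == 0] <- 1
  p
}

stop_insufficient <- function(method, needed, got) {
  abort(
    sprintf("%s requires at least %d SNPs (got %d)", method, needed, got),
    class = "mrpath_error_insufficient_instruments"
  )
}
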