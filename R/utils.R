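#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' global RNG state afterwards, so seeded generators do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# column-wise sd with the n-1 denominator, without the matrix copy apply() makes
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute column standard deviations")
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
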