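# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs user
# simulations. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so the state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Row variances of a numeric matrix (denominator n - 1).
.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute row variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

.assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", what))
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s contains non-finite values", what))
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop(sprintf("%s must have unique row (probe) names", what))
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop(sprintf("%s must have unique column (sample) names", what))
  invisible(x)
}

# log(sum(exp(v))) computed stably; v a numeric vector.
.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}
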