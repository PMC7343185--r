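# Internal helpers shared across modules.

#' Root mean square of a numeric vector
#'
#' @param x numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded operations do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Causal discrete convolution: zero history before frame 1, output truncated
# to length(x).  Shared by the synthesizer and the fitter so both sides of the
# validation loop use one forward model (direct summation, exact arithmetic).
conv_causal <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  if (m > n) stop("HRF kernel (", m, " samples) is longer than the series (", n, ")")
  y <- numeric(n)
  for (j in seq_len(m)) y[j:n] <- y[j:n] + kernel[j] * x[seq_len(n - j + 1L)]
  y
}

# Row-wise causal convolution of a nodes x frames matrix (same arithmetic
# order per element as conv_causal).
conv_causal_rows <- function(X, kernel) {
  n <- ncol(X)
  m <- length(kernel)
  if (m > n) stop("HRF kernel is longer than the series")
  Y <- matrix(0, nrow(X), n)
  for (j in seq_len(m)) Y[, j:n] <- Y[, j:n] + kernel[j] * X[, seq_len(n - j + 1L), drop = FALSE]
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("`", name, "` must be a single positive number")
}
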