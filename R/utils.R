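# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tmmp <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)

check_scalar <- function(x, name, lo = -Inf, hi = Inf, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_tmmp("'%s' must be a single finite number", name)
  bad_lo <- if (open_lo) x <= lo else x < lo
  bad_hi <- if (open_hi) x >= hi else x > hi
  if (bad_lo || bad_hi)
    stop_tmmp("'%s' = %g is outside its admissible range %s%g, %g%s", name, x,
              if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  invisible(x)
}

#' Derive a reproducible substream seed
#'
#' Mixes a master seed with arbitrary string/integer labels into a 31-bit
#' integer seed, so that per-population (or per-draw) random streams are
#' invariant to the order in which populations are processed.
#'
#' @param seed Master integer seed.
#' @param ... Labels (strings or integers) identifying the substream.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "A", 3L) == substream_seed(1, "A", 3L)
#' @export
substream_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(labels)
  # polynomial rolling hash mod 2^31 - 1, exact in double arithmetic
  m <- 2^31 - 1
  h <- 17
  for (b in bytes) h <- (h * 1159241 + b) %% m
  as.integer(h)
}

# log-density of x under N(mean, Sigma) given upper Cholesky factor R (Sigma = R'R)
chol_logdens <- function(x, mean, R) {
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# draw from N(0, Sigma) given upper Cholesky factor R
chol_draw <- function(R) drop(crossprod(R, stats::rnorm(ncol(R))))
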