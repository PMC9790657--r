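#' Differencing matrix
#'
#' Builds the `(K - r) x K` matrix `D` such that `D %*% delta` equals the
#' r-th order difference of `delta`, composed from `r` first-difference
#' matrices (each with entries `D[i, i] = -1`, `D[i, i + 1] = 1`).
#'
#' @param K Length of the coefficient vector.
#' @param r Differencing order, `0 <= r < K`. `r = 0` returns the identity.
#' @return A `(K - r) x K` matrix.
#' @examples
#' difference_matrix(3, 1)
#' difference_matrix(4, 2)  # rows c(1, -2, 1, 0), c(0, 1, -2, 1)
#' @export
difference_matrix <- function(K, r) {
  if (!is_count(K) || K < 1) stop_tmmp("'K' must be a positive integer")
  if (!is_count(r) || r < 0 || r >= K)
    stop_tmmp("differencing order r = %s must satisfy 0 <= r < K = %s", r, K)
  D <- diag(K)
  for (i in seq_len(r)) {
    k <- K - i + 1
    D1 <- cbind(-diag(k - 1), 0) + cbind(0, diag(k - 1))
    D <- D1 %*% D
  }
  D
}

#' Anchoring constraints for differenced coefficients
#'
#' For a smoother of differencing order `r`, identifiability requires `r`
#' anchoring equations: for each order `d = 0, ..., r - 1`, the d-th
#' differences of the coefficients must sum to zero over an index set `K_d`.
#' Index sets are positional into the length-`(K - d)` vector of d-th
#' differences (so for `d = 0` they index the coefficients themselves).
#'
#' @param ... Integer index vectors, one per order `d = 0, 1, ..., r - 1`,
#'   in that order. Use `NULL` entries to keep the positional convention when
#'   skipping documentation of a level is not possible.
#' @return An object of class `tmmp_anchor` (a list of index sets).
#' @examples
#' # second-order random walk anchored at coefficient k* with
#' # first differences summing to zero over positions 1..(K-1):
#' anchor_sets(5L, 1:12)
#' @export
anchor_sets <- function(...) {
  sets <- list(...)
  if (!length(sets)) stop_tmmp("at least one anchoring index set is required")
  for (s in sets)
    if (!is.numeric(s) || !length(s) || any(s != round(s)) || any(s < 1))
      stop_tmmp("anchoring sets must be positive integer index vectors")
  structure(lapply(sets, as.integer), class = "tmmp_anchor")
}

#' Recover coefficient levels from their differences
#'
#' Solves `D %*% delta = gamma` for `delta`, resolving the r-dimensional null
#' space of `D` by one of two constraint modes:
#'
#' * `minimum_norm`: `delta = t(D) %*% solve(D %*% t(D)) %*% gamma`, the
#'   unique solution orthogonal to the null space of `D`.
#' * `anchored`: the unique solution satisfying the anchoring equations of an
#'   [anchor_sets()] object (`sum of d-th differences over K_d equals 0` for
#'   `d < r`).
#'
#' @param gamma Vector of r-th order differences, length `K - r`.
#' @param r Differencing order (`>= 1`; for `r = 0` the levels are the
#'   differences themselves).
#' @param constraint Either the string `"minimum_norm"` or an [anchor_sets()]
#'   object with `r` index sets.
#' @return The length-`K` coefficient vector `delta`.
#' @examples
#' recover_levels(c(1, 1), r = 1)                    # c(-1, 0, 1)
#' recover_levels(c(1, 1), r = 1, anchor_sets(1L))   # c(0, 1, 2)
#' @export
recover_levels <- function(gamma, r, constraint = "minimum_norm") {
  gamma <- as.numeric(gamma)
  if (r == 0) return(gamma)
  K <- length(gamma) + r
  D <- difference_matrix(K, r)
  if (identical(constraint, "minimum_norm")) {
    DDt <- tcrossprod(D)
    delta <- drop(crossprod(D, solve(DDt, gamma)))
    # one step of iterative refinement keeps the residual near machine
    # precision even for large, ill-conditioned K
    resid <- gamma - drop(D %*% delta)
    return(delta + drop(crossprod(D, solve(DDt, resid))))
  }
  if (!inherits(constraint, "tmmp_anchor"))
    stop_tmmp("'constraint' must be \"minimum_norm\" or an anchor_sets() object")
  if (length(constraint) != r)
    stop_tmmp("anchored recovery at r = %d needs exactly %d index sets, got %d",
              r, r, length(constraint))
  A <- matrix(0, r, K)
  for (d in seq_len(r) - 1L) {
    Dd <- difference_matrix(K, d)
    idx <- constraint[[d + 1L]]
    if (any(idx > K - d))
      stop_tmmp("anchoring set for order d = %d has indices beyond %d", d, K - d)
    A[d + 1L, ] <- colSums(Dd[idx, , drop = FALSE])
  }
  M <- rbind(D, A)
  qrM <- qr(M)
  if (qrM$rank < K)
    stop_tmmp("anchoring constraints do not pin down the null space (rank %d < %d)",
              qrM$rank, K)
  drop(qr.coef(qrM, c(gamma, rep(0, r))))
}
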