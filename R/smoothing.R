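#' Smoothing component specification
#'
#' Combines a basis, a covariance kernel, a differencing order and a
#' constraint mode into the model for the stochastic smoothing component
#' `epsilon = B %*% delta` with `diff^r(delta) ~ N(0, Sigma(kernel))`.
#'
#' When `r > 0` the level of `delta` is not identified by its differences and
#' an anchoring rule is required: either `"minimum_norm"` (the solution
#' orthogonal to the null space of the differencing matrix) or an explicit
#' [anchor_sets()] object whose `r` index sets each force a sum of d-th
#' differences to zero.
#'
#' @param basis A [basis_spec()].
#' @param kernel A [kernel_spec()].
#' @param r Differencing order, 0, 1 or 2.
#' @param constraint `"none"` (only valid when `r = 0`), `"minimum_norm"`, or
#'   an [anchor_sets()] object.
#' @return An object of class `tmmp_smoothing`.
#' @export
smoothing_spec <- function(basis, kernel, r = 0L, constraint = if (r == 0) "none" else "minimum_norm") {
  if (!inherits(basis, "tmmp_basis_spec")) stop_tmmp("'basis' must be a basis_spec()")
  if (!inherits(kernel, "tmmp_kernel")) stop_tmmp("'kernel' must be a kernel_spec()")
  if (!is_count(r) || r < 0 || r > 2) stop_tmmp("'r' must be 0, 1 or 2")
  if (r == 0 && !identical(constraint, "none"))
    stop_tmmp("r = 0 smoothers take constraint = \"none\"")
  if (r > 0 && identical(constraint, "none"))
    stop_tmmp("r = %d requires a constraint mode (\"minimum_norm\" or anchor_sets())", r)
  if (inherits(constraint, "tmmp_anchor") && length(constraint) != r)
    stop_tmmp("anchored constraint needs %d index sets, got %d", r, length(constraint))
  structure(list(basis = basis, kernel = kernel, r = as.integer(r), constraint = constraint),
            class = "tmmp_smoothing")
}

# Precompute the matrices a smoother needs over a set of times:
#   B (times x K), recovery map A (K x m) with delta = A gamma, m = K - r.
smoothing_matrices <- function(spec, times, span = range(times)) {
  B <- build_basis(spec$basis, times, span)
  K <- ncol(B)
  r <- spec$r
  m <- K - r
  if (m < 1) stop_tmmp("differencing order r = %d too high for K = %d coefficients", r, K)
  if (r == 0) {
    A <- diag(K)
  } else if (identical(spec$constraint, "minimum_norm")) {
    D <- difference_matrix(K, r)
    A <- t(D) %*% solve(tcrossprod(D))
  } else {
    D <- difference_matrix(K, r)
    Arows <- matrix(0, r, K)
    for (d in seq_len(r) - 1L) {
      Dd <- difference_matrix(K, d)
      idx <- spec$constraint[[d + 1L]]
      if (any(idx > K - d))
        stop_tmmp("anchoring set for order d = %d has indices beyond %d", d, K - d)
      Arows[d + 1L, ] <- colSums(Dd[idx, , drop = FALSE])
    }
    M <- rbind(D, Arows)
    A <- solve(M)[, seq_len(m), drop = FALSE]
  }
  list(B = B, BA = B %*% A, A = A, K = K, m = m, r = r, span = span)
}

#' Sample smoothing-component draws from the prior
#'
#' Draws the differenced coefficients from `N(0, Sigma(kernel))`, recovers the
#' coefficient levels under the declared constraint mode, and maps them
#' through the basis. Anchoring constraints hold exactly by construction.
#'
#' @param spec A [smoothing_spec()].
#' @param grid A [time_grid()]; draws cover the estimation period `1..T`.
#' @param n_draws Number of draws (0 returns a 0-row matrix).
#' @param seed Integer seed; draws are reproducible under a fixed seed.
#' @return An `n_draws x T` matrix of smoothing-component draws.
#' @export
sample_smoothing <- function(spec, grid, n_draws, seed = 1L) {
  mats <- smoothing_matrices(spec, seq_len(grid$T))
  if (n_draws == 0) return(matrix(numeric(0), 0, grid$T))
  S <- build_covariance(spec$kernel, mats$m)
  R <- chol(S)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * mats$m), n_draws, mats$m)
  gamma <- Z %*% R
  gamma %*% t(mats$BA)
}

#' Generic Gaussian conditioning
#'
#' Conditional distribution of the remaining coordinates of a zero-mean
#' multivariate normal given the coordinates in `idx`.
#'
#' @param Sigma Joint covariance matrix.
#' @param idx Indices of the conditioned-on coordinates.
#' @param value Observed values at `idx`.
#' @return List with `mean` and `cov` of the remaining coordinates.
#' @export
gaussian_conditional <- function(Sigma, idx, value) {
  n <- nrow(Sigma)
  rest <- setdiff(seq_len(n), idx)
  S11 <- Sigma[idx, idx, drop = FALSE]
  S21 <- Sigma[rest, idx, drop = FALSE]
  S22 <- Sigma[rest, rest, drop = FALSE]
  W <- tryCatch(solve(S11, t(S21)), error = function(e)
    stop_tmmp("singular conditioning block: %s", conditionMessage(e)))
  list(mean = drop(S21 %*% solve(S11, value)),
       cov = S22 - S21 %*% W)
}

#' Conditional law of projection-period differenced coefficients
#'
#' Under the estimation model, the differenced coefficients over the extended
#' period are jointly `N(0, Sigma*)` with `Sigma*` built from the kernel. The
#' projection-period coefficients' distribution is the Gaussian conditional of
#' the `K_added` new differences given the estimation-period differences
#' `diff^r(delta_hat)`.
#'
#' @param spec A [smoothing_spec()].
#' @param delta_hat Estimated coefficient vector (length `K`).
#' @param K_added Number of coefficients (equivalently differenced
#'   coefficients) appended for the projection period.
#' @return List with `mean` (length `K_added`), `cov`
#'   (`K_added x K_added`) and `gamma_hat` (the conditioning values).
#' @export
condition_projection <- function(spec, delta_hat, K_added) {
  if (!is_count(K_added) || K_added < 1) stop_tmmp("'K_added' must be >= 1")
  K <- length(delta_hat)
  r <- spec$r
  gamma_hat <- if (r == 0) as.numeric(delta_hat)
               else drop(difference_matrix(K, r) %*% delta_hat)
  m <- length(gamma_hat)
  Sstar <- build_covariance(spec$kernel, m + K_added)
  out <- gaussian_conditional(Sstar, seq_len(m), gamma_hat)
  out$gamma_hat <- gamma_hat
  out
}

#' Extend coefficient levels with new differenced draws
#'
#' Given estimated levels `delta_hat` and projection-period r-th order
#' differences `gamma_new`, rebuilds the appended coefficient levels through
#' the difference recursion (for `r = 2`:
#' `delta[K+1] = 2 delta[K] - delta[K-1] + gamma_new[1]`, and so on).
#'
#' @param delta_hat Estimated coefficient levels.
#' @param r Differencing order.
#' @param gamma_new New differenced values (length = number appended).
#' @return The extended coefficient vector.
#' @export
extend_levels <- function(delta_hat, r, gamma_new) {
  delta <- as.numeric(delta_hat)
  if (r == 0) return(c(delta, gamma_new))
  w <- sapply(seq_len(r), function(i) (-1)^(i + 1) * choose(r, i))
  for (g in gamma_new) {
    K <- length(delta)
    delta <- c(delta, sum(w * delta[K - seq_len(r) + 1L]) + g)
  }
  delta
}
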