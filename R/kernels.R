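#' Covariance kernels for the stochastic smoothing component
#'
#' The (differenced) smoothing coefficients are jointly normal with a
#' stationary covariance `Sigma[t1, t2] = s(|t1 - t2|, kappa)`. Five kernel
#' families are available:
#'
#' * `ar1`: `s(h) = kappa^2 * rho^h`, with marginal sd `kappa > 0` and
#'   autocorrelation `0 <= rho < 1`.
#' * `squared_exponential`: `s(h) = kappa^2 * exp(-h^2 / (2 * ell^2))`.
#' * `matern`: `s(h) = kappa^2 * 2^(1-nu)/Gamma(nu) * (sqrt(2 nu) h / ell)^nu *
#'   K_nu(sqrt(2 nu) h / ell)`, evaluated through the modified Bessel function
#'   of the second kind, with exact closed forms at `nu` in 1/2, 3/2, 5/2.
#' * `arma11`: the stationary ARMA(1,1) autocovariance, parametrized by its
#'   stationary standard deviation `sigma > 0` (not the innovation sd),
#'   autoregressive parameter `0 <= rho < 1` and moving-average parameter
#'   `-1 <= theta <= 0`.
#' * `iid`: `s(0) = sigma^2`, zero at positive lags.
#'
#' All families except `iid` have `s(h) -> 0` as `h -> Inf`.
#'
#' @param family Kernel family name.
#' @param kappa,ell,nu,rho,theta,sigma Family-specific hyperparameters (see
#'   Details).
#' @return An object of class `tmmp_kernel`.
#' @examples
#' autocovariance(kernel_spec("ar1", kappa = 2, rho = 0.5), 0:3)
#' @export
kernel_spec <- function(family = c("ar1", "squared_exponential", "matern", "arma11", "iid"),
                        kappa = NULL, ell = NULL, nu = NULL, rho = NULL,
                        theta = NULL, sigma = NULL) {
  family <- match.arg(family)
  need <- function(x, nm) {
    if (is.null(x)) stop_tmmp("kernel '%s' requires hyperparameter '%s'", family, nm)
    x
  }
  pars <- switch(family,
    ar1 = list(kappa = check_scalar(need(kappa, "kappa"), "kappa", 0, open_lo = TRUE),
               rho = check_scalar(need(rho, "rho"), "rho", 0, 1, open_hi = TRUE)),
    squared_exponential = list(
      kappa = check_scalar(need(kappa, "kappa"), "kappa", 0, open_lo = TRUE),
      ell = check_scalar(need(ell, "ell"), "ell", 0, open_lo = TRUE)),
    matern = list(
      kappa = check_scalar(need(kappa, "kappa"), "kappa", 0, open_lo = TRUE),
      ell = check_scalar(need(ell, "ell"), "ell", 0, open_lo = TRUE),
      nu = check_scalar(need(nu, "nu"), "nu", 0, open_lo = TRUE)),
    arma11 = list(
      sigma = check_scalar(need(sigma, "sigma"), "sigma", 0, open_lo = TRUE),
      rho = check_scalar(need(rho, "rho"), "rho", 0, 1, open_hi = TRUE),
      theta = check_scalar(need(theta, "theta"), "theta", -1, 0)),
    iid = list(sigma = check_scalar(need(sigma, "sigma"), "sigma", 0, open_lo = TRUE))
  )
  structure(c(list(family = family), pars), class = "tmmp_kernel")
}

#' @export
print.tmmp_kernel <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("<tmmp_kernel> %s(%s)\n", x$family,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Kernel autocovariance at integer lags
#'
#' @param kernel A [kernel_spec()].
#' @param lag Vector of nonnegative lags.
#' @return `s(lag, kappa)`, vectorized over `lag`.
#' @export
autocovariance <- function(kernel, lag) {
  if (!inherits(kernel, "tmmp_kernel")) stop_tmmp("'kernel' must be a kernel_spec()")
  if (any(lag < 0)) stop_tmmp("'lag' must be nonnegative")
  h <- as.numeric(lag)
  switch(kernel$family,
    ar1 = kernel$kappa^2 * kernel$rho^h,
    squared_exponential = kernel$kappa^2 * exp(-h^2 / (2 * kernel$ell^2)),
    matern = matern_cov(h, kernel$kappa, kernel$ell, kernel$nu),
    arma11 = arma11_cov(h, kernel$sigma, kernel$rho, kernel$theta),
    iid = ifelse(h == 0, kernel$sigma^2, 0)
  )
}

# Matern autocovariance; closed forms at nu in {1/2, 3/2, 5/2}, Bessel otherwise
matern_cov <- function(h, kappa, ell, nu) {
  out <- numeric(length(h))
  z <- sqrt(2 * nu) * h / ell
  if (isTRUE(all.equal(nu, 0.5))) {
    out <- kappa^2 * exp(-h / ell)
  } else if (isTRUE(all.equal(nu, 1.5))) {
    a <- sqrt(3) * h / ell
    out <- kappa^2 * (1 + a) * exp(-a)
  } else if (isTRUE(all.equal(nu, 2.5))) {
    a <- sqrt(5) * h / ell
    out <- kappa^2 * (1 + a + a^2 / 3) * exp(-a)
  } else {
    pos <- z > 0
    out[!pos] <- kappa^2
    zp <- z[pos]
    out[pos] <- kappa^2 * 2^(1 - nu) / gamma(nu) * zp^nu * besselK(zp, nu)
  }
  out[h == 0] <- kappa^2
  out
}

# Stationary ARMA(1,1) autocovariance scaled to stationary variance sigma^2.
# For x_t = rho x_{t-1} + e_t + theta e_{t-1}:
#   gamma0 = sigma_e^2 (1 + 2 rho theta + theta^2) / (1 - rho^2)
#   gamma1 = sigma_e^2 (1 + rho theta)(rho + theta) / (1 - rho^2)
#   gammah = rho^(h-1) gamma1,  h >= 1
arma11_cov <- function(h, sigma, rho, theta) {
  denom <- 1 + 2 * rho * theta + theta^2
  if (denom <= 0) stop_tmmp("degenerate ARMA(1,1): 1 + 2*rho*theta + theta^2 <= 0")
  acf1 <- (1 + rho * theta) * (rho + theta) / denom
  ifelse(h == 0, sigma^2, sigma^2 * acf1 * rho^(pmax(h, 1) - 1))
}

#' Build a kernel covariance matrix
#'
#' Returns the `n x n` Toeplitz covariance matrix implied by the kernel on a
#' unit-spaced grid, with a one-time diagonal jitter of `1e-10 * s(0)` applied
#' before any factorization to guard against numerically semidefinite cases.
#'
#' @inheritParams autocovariance
#' @param n Matrix dimension.
#' @return An `n x n` symmetric positive (semi)definite matrix.
#' @export
build_covariance <- function(kernel, n) {
  if (!is_count(n) || n < 1) stop_tmmp("'n' must be a positive integer")
  s <- autocovariance(kernel, 0:(n - 1))
  S <- stats::toeplitz(s)
  S <- S + diag(1e-10 * s[1], n)
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-9 * s[1])
    stop_tmmp("kernel covariance is not positive semidefinite (min eigenvalue %g)", ev)
  S
}
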