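# MCMC primitives: elliptical slice sampling for conditionally Gaussian
# blocks and stepping-out slice sampling for scalars. Both are rejection-free
# and tuning-free, which keeps the Gibbs scheme robust across the very
# different model structures the class can express.

# One elliptical slice sampling update (Murray, Adams & MacKay 2010).
# x: current value; mu: prior mean; nu: a draw from N(0, Sigma_prior);
# loglik: function(x) -> log-likelihood (anything non-Gaussian in the target).
ess_update <- function(x, mu, nu, loglik) {
  ll0 <- loglik(x)
  if (!is.finite(ll0)) {
    # fall back to a fresh prior draw if the current point is degenerate
    x <- mu + nu
    ll0 <- loglik(x)
    if (!is.finite(ll0)) return(list(x = x, ll = ll0))
  }
  ly <- ll0 + log(stats::runif(1))
  ang <- stats::runif(1, 0, 2 * pi)
  lo <- ang - 2 * pi
  hi <- ang
  repeat {
    xp <- mu + (x - mu) * cos(ang) + nu * sin(ang)
    llp <- loglik(xp)
    if (is.finite(llp) && llp >= ly) return(list(x = xp, ll = llp))
    if (hi - lo < 1e-12) return(list(x = x, ll = ll0))
    if (ang < 0) lo <- ang else hi <- ang
    ang <- stats::runif(1, lo, hi)
  }
}

# One univariate slice-sampling update (Neal 2003, stepping out + shrinkage).
# logf must return -Inf outside the support (lo, hi).
slice_update <- function(x, logf, w = 1, lo = -Inf, hi = Inf, max_steps = 50L) {
  f0 <- logf(x)
  if (!is.finite(f0)) stop_tmmp("slice sampler started at a zero-density point")
  y <- f0 + log(stats::runif(1))
  L <- x - w * stats::runif(1)
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1L - j
  while (j > 0 && L > lo && logf(L) > y) { L <- L - w; j <- j - 1L }
  while (k > 0 && R < hi && logf(R) > y) { R <- R + w; k <- k - 1L }
  L <- max(L, lo)
  R <- min(R, hi)
  repeat {
    x1 <- stats::runif(1, L, R)
    f1 <- logf(x1)
    if (is.finite(f1) && f1 >= y) return(list(x = x1, ll = f1))
    if (x1 < x) L <- x1 else R <- x1
    if (R - L < 1e-12) return(list(x = x, ll = f0))
  }
}

#' Convergence diagnostics
#'
#' Split-\eqn{\hat{R}} and effective sample size per stored parameter, following
#' the standard rank-free formulation: chains are split in half, the
#' potential scale reduction factor is computed from the between- and
#' within-half variances, and the effective sample size from the
#' chain-averaged autocorrelations truncated by Geyer's initial positive
#' sequence rule.
#'
#' @param posterior A `tmmp_posterior` from [fit_tmmp()], or a
#'   draws-by-chains-by-parameters array.
#' @param parameters Optional character vector restricting which parameters
#'   are diagnosed.
#' @return A data frame of class `tmmp_diagnostics` with columns `parameter`,
#'   `rhat`, `ess`. With a single chain `rhat` is `NA` (with a message).
#' @export
diagnose <- function(posterior, parameters = NULL) {
  arr <- if (is.array(posterior)) posterior else posterior_array(posterior)
  if (!is.null(parameters)) arr <- arr[, , parameters, drop = FALSE]
  n_chain <- dim(arr)[2]
  pars <- dimnames(arr)[[3]]
  if (n_chain < 2) message("single chain: split-Rhat omitted")
  out <- data.frame(parameter = pars,
                    rhat = NA_real_, ess = NA_real_)
  for (p in seq_along(pars)) {
    draws <- arr[, , p, drop = FALSE]
    dim(draws) <- dim(arr)[1:2]
    out$rhat[p] <- if (n_chain >= 2) split_rhat(draws) else NA_real_
    out$ess[p] <- ess_mean(draws)
  }
  class(out) <- c("tmmp_diagnostics", "data.frame")
  out
}

split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W < 1e-300) return(1)  # constant parameter
  sqrt(((half - 1) / half * W + B / half) / W)
}

ess_mean <- function(draws) {
  n <- nrow(draws)
  m <- ncol(draws)
  vars <- apply(draws, 2, stats::var)
  if (all(vars < 1e-300)) return(n * m)
  rho_sum <- 0
  max_lag <- min(n - 2, 200L)
  acfs <- sapply(seq_len(m), function(j)
    stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[-1])
  acfs <- rowMeans(cbind(acfs))
  # Geyer initial positive sequence on paired sums
  t <- 1L
  while (t + 1 <= length(acfs)) {
    pair <- acfs[t] + acfs[t + 1]
    if (pair < 0) break
    rho_sum <- rho_sum + pair
    t <- t + 2L
  }
  max(1, (n * m) / (1 + 2 * rho_sum))
}

#' @export
print.tmmp_diagnostics <- function(x, ...) {
  cat(sprintf("<tmmp_diagnostics> %d parameters; max rhat %.3f, min ESS %.0f\n",
              nrow(x), suppressWarnings(max(x$rhat, na.rm = TRUE)), min(x$ess)))
  invisible(x)
}
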