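#' Covariate components
#'
#' Functions `g2(X, beta)` mapping covariates to the transformed scale of the
#' process model. Four forms are provided, matching the covariate structures
#' used in published indicator models:
#'
#' * [covariate_linear()]: population intercept plus global slopes,
#'   `beta0_c + sum_k X_k beta_k` (used e.g. for maternal mortality with
#'   log(GDP), log(GFR) and SAB as covariates).
#' * [covariate_gbd()]: the non-linear under-five mortality regression in
#'   LDI, education and HIV death rate,
#'   `log10(exp(b1 log LDI + b2 EDU + b3) + b4 HIV)`.
#' * [covariate_piecewise_nmr()]: piecewise-linear in log U5MR with a
#'   cut-off, `beta0_c + beta1 (log U5MR - log beta2) 1[U5MR > beta2]`.
#' * [covariate_pca()]: principal-component regression
#'   `sum_k X_k beta_k` with population-and-time-varying coefficients.
#'
#' @param X Numeric vector of covariate values for one population-time (or a
#'   matrix, rows = times).
#' @param beta0 Population intercept.
#' @param beta Slope vector (one per covariate column).
#' @return Component value(s) on the transformed scale.
#' @name covariate_components
NULL

#' @rdname covariate_components
#' @export
covariate_linear <- function(X, beta0, beta) {
  X <- rbind(X)
  if (ncol(X) != length(beta))
    stop_tmmp("covariate_linear: %d covariate columns but %d slopes", ncol(X), length(beta))
  unname(drop(beta0 + X %*% beta))
}

#' @rdname covariate_components
#' @param LDI,EDU,HIV Covariate values (LDI > 0, HIV >= 0).
#' @param betas Length-4 coefficient vector `(b1, b2, b3, b4)`.
#' @export
covariate_gbd <- function(LDI, EDU, HIV, betas) {
  if (length(betas) != 4) stop_tmmp("covariate_gbd needs 4 coefficients")
  if (any(LDI <= 0)) stop_tmmp("LDI must be positive")
  if (any(HIV < 0)) stop_tmmp("HIV death rate must be nonnegative")
  inner <- exp(betas[1] * log(LDI) + betas[2] * EDU + betas[3]) + betas[4] * HIV
  if (any(!is.finite(inner)) || any(inner <= 0))
    stop_tmmp("covariate_gbd: argument of log10 is nonpositive or non-finite")
  log10(inner)
}

#' @rdname covariate_components
#' @param U5MR Under-five mortality covariate (positive, same scale as the
#'   cut-off `beta2`).
#' @param beta1 Slope beyond the cut-off.
#' @param beta2 Cut-off value (positive).
#' @export
covariate_piecewise_nmr <- function(U5MR, beta0, beta1, beta2) {
  if (any(U5MR <= 0)) stop_tmmp("U5MR must be positive")
  check_scalar(beta2, "beta2", 0, open_lo = TRUE)
  beta0 + beta1 * (log(U5MR) - log(beta2)) * (U5MR > beta2)
}

#' @rdname covariate_components
#' @export
covariate_pca <- function(X, beta) {
  X <- rbind(X)
  B <- rbind(beta)
  if (ncol(X) != ncol(B))
    stop_tmmp("covariate_pca: %d components but %d coefficients", ncol(X), ncol(B))
  if (nrow(B) == 1L) unname(drop(X %*% t(B))) else unname(rowSums(X * B))
}

#' Systematic components
#'
#' Parametric trend functions `g3` on the transformed scale.
#'
#' `systematic_linear()` is the population-specific linear trend
#' `alpha0 + alpha1 * (t - t_star)`, with `t_star` typically the middle of a
#' population's observation period.
#'
#' `systematic_logistic_step()` is one forward step of the logistic
#' contraceptive-use transition: given the previous level `eta_prev` in
#' (0, 1), the next transformed-scale value is
#' `logit(P_tilde * plogis(qlogis(eta_prev / P_tilde) + omega))` while
#' `eta_prev < P_tilde`, and `qlogis(eta_prev)` (no growth) otherwise, so the
#' trajectory rises in an S-shape towards the asymptote `P_tilde` without
#' overshooting. `systematic_logistic_backstep()` inverts the forward map
#' exactly, used to propagate the trend backwards from the reference year.
#'
#' `systematic_trapezoid()` rises linearly from 0 to `xi` over
#' `(gamma0, gamma0 + lambda1)`, stays at `xi` for `lambda2` time units, falls
#' back to 0 over `lambda3` units, and is 0 outside.
#'
#' @param t Time (grid units).
#' @param alpha0,alpha1 Intercept and slope.
#' @param t_star Reference time.
#' @return Component value(s) on the transformed scale.
#' @name systematic_components
NULL

#' @rdname systematic_components
#' @export
systematic_linear <- function(t, alpha0, alpha1, t_star) {
  alpha0 + alpha1 * (t - t_star)
}

#' @rdname systematic_components
#' @param eta_prev Previous-period level on the natural (0, 1) scale.
#' @param P_tilde Asymptote in (0, 1].
#' @param omega Rate parameter (> 0 for an increasing transition).
#' @export
systematic_logistic_step <- function(eta_prev, P_tilde, omega) {
  check_scalar(P_tilde, "P_tilde", 0, 1, open_lo = TRUE)
  if (any(eta_prev <= 0 | eta_prev >= 1)) stop_tmmp("eta_prev must be in (0, 1)")
  ifelse(eta_prev < P_tilde,
         stats::qlogis(P_tilde * stats::plogis(stats::qlogis(eta_prev / P_tilde) + omega)),
         stats::qlogis(eta_prev))
}

#' @rdname systematic_components
#' @param eta_next Current-period level on the natural (0, 1) scale.
#' @export
systematic_logistic_backstep <- function(eta_next, P_tilde, omega) {
  check_scalar(P_tilde, "P_tilde", 0, 1, open_lo = TRUE)
  if (any(eta_next <= 0 | eta_next >= 1)) stop_tmmp("eta_next must be in (0, 1)")
  ifelse(eta_next < P_tilde,
         P_tilde * stats::plogis(stats::qlogis(eta_next / P_tilde) - omega),
         eta_next)
}

#' @rdname systematic_components
#' @param xi Plateau height.
#' @param gamma0 Start of the rise.
#' @param lambda1,lambda2,lambda3 Durations (all positive) of the rise,
#'   plateau and fall.
#' @export
systematic_trapezoid <- function(t, xi, gamma0, lambda1, lambda2, lambda3) {
  for (nm in c("lambda1", "lambda2", "lambda3"))
    check_scalar(get(nm), nm, 0, open_lo = TRUE)
  g1 <- gamma0 + lambda1
  g2 <- g1 + lambda2
  g3 <- g2 + lambda3
  out <- numeric(length(t))
  rise <- t > gamma0 & t <= g1
  flat <- t > g1 & t < g2
  fall <- t >= g2 & t < g3
  out[rise] <- xi * (t[rise] - gamma0) / lambda1
  out[flat] <- xi
  out[fall] <- xi - xi * (t[fall] - g2) / lambda3
  out
}

#' Propagate the logistic transition over the whole grid
#'
#' Computes the latent path `eta[1..T]` for the logistic-transition process
#' model `qlogis(eta_t) = g3(eta_{t-1}) + eps_t`, anchored at the reference
#' time `t_star` where the transformed level equals `Omega`. The trend is
#' propagated forward from `t_star` by the one-step logistic map and backward
#' by its exact inverse. By default the recursion carries the realized level
#' (systematic step plus that period's smoothing deviation); with
#' `include_eps_in_recursion = FALSE` the recursion is driven by the
#' systematic path only and deviations are added afterwards.
#'
#' @param Omega Transformed-scale (logit) level at `t_star`.
#' @param P_tilde,omega Logistic transition parameters.
#' @param t_star Reference time index.
#' @param eps Length-`T` vector of smoothing deviations (logit scale).
#' @param include_eps_in_recursion Logical; see Description.
#' @return Length-`T` vector of `eta` on the natural (0, 1) scale.
#' @export
logistic_path <- function(Omega, P_tilde, omega, t_star, eps,
                          include_eps_in_recursion = TRUE) {
  check_scalar(P_tilde, "P_tilde", 0, 1, open_lo = TRUE)
  Tn <- length(eps)
  e <- if (include_eps_in_recursion) eps else numeric(Tn)
  z <- numeric(Tn)                       # logit-scale path
  z[t_star] <- Omega + e[t_star]
  P <- P_tilde
  om <- omega
  # recursions inlined: one systematic step on the logit scale per period
  if (t_star < Tn) for (t in (t_star + 1):Tn) {
    zp <- z[t - 1]
    x <- 1 / (1 + exp(-zp))              # realized eta_{t-1}
    if (x < P) {
      r <- x / P
      zn <- P / (1 + exp(-(log(r) - log1p(-r) + om)))
      zp <- log(zn) - log1p(-zn)
    }
    z[t] <- zp + e[t]
  }
  # step back systematically from the realized level, then add that
  # period's deviation (mirrors the forward recursion)
  if (t_star > 1) for (t in (t_star - 1):1) {
    zn1 <- z[t + 1]
    x <- 1 / (1 + exp(-zn1))
    if (x < P) {
      r <- x / P
      zn <- P / (1 + exp(-(log(r) - log1p(-r) - om)))
      zn1 <- log(zn) - log1p(-zn)
    }
    z[t] <- zn1 + e[t]
  }
  if (!include_eps_in_recursion) z <- z + eps
  stats::plogis(z)
}

#' Assemble the latent field from process-model components
#'
#' Combines covariate, systematic and offset components with smoothing-
#' component draws on the transformed scale and maps back to the natural
#' scale: `eta = g1^{-1}(g2 + g3 + a + eps)`. Assembly is additive, so the
#' order of the non-recursive components is immaterial. For the recursive
#' logistic transition, supply `logistic`: the path is then built by the
#' anchored recursion (deviations included step by step) and the additive
#' `g2`/`g3` inputs are ignored for that population.
#'
#' @param eps Smoothing-component draws: a `draws x C x T` array (or a
#'   `C x T` matrix for a single draw), transformed scale.
#' @param transform A [transform_spec()] or its name.
#' @param g2,g3 Covariate and systematic component values (`C x T` matrices
#'   or single numbers; default 0).
#' @param offsets Offset values `a` (`C x T` matrix or 0).
#' @param logistic Optional list with per-population vectors/values `Omega`,
#'   `P_tilde`, `omega` and `t_star` for the recursive transition.
#' @return Latent-field draws, `draws x C x T` on the natural scale.
#' @examples
#' eps <- array(0, c(2, 1, 4))
#' assemble_eta(eps, "log")[1, 1, ]   # exp(0) = 1
#' @export
assemble_eta <- function(eps, transform, g2 = 0, g3 = 0, offsets = 0,
                         logistic = NULL) {
  if (is.matrix(eps)) eps <- array(eps, c(1, dim(eps)))
  dd <- dim(eps)
  z_fix <- array(0, dd[2:3])
  z_fix <- z_fix + g2 + g3 + offsets
  out <- array(NA_real_, dd, dimnames = dimnames(eps))
  for (i in seq_len(dd[1])) for (c_i in seq_len(dd[2])) {
    zrow <- z_fix[c_i, ] + eps[i, c_i, ]
    out[i, c_i, ] <- if (is.null(logistic)) {
      eta <- transform_invert(zrow, transform)
      if (any(!is.finite(eta)))
        stop_tmmp("non-finite latent value at population %d, draw %d", c_i, i)
      eta
    } else {
      logistic_path(Omega = logistic$Omega[[c_i]],
                    P_tilde = logistic$P_tilde[[c_i]],
                    omega = logistic$omega[[c_i]],
                    t_star = logistic$t_star[[c_i]],
                    eps = zrow)
    }
  }
  out
}
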