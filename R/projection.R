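#' Project the latent field beyond the estimation period
#'
#' Generates latent-field draws for `T+1 .. T_star` from a fitted model. Two
#' methods are available:
#'
#' * `default_conditional`: the estimation process model is extended. Per
#'   posterior draw, the basis is extended at the original knot spacing, the
#'   projection-period r-th order differenced coefficients are sampled from
#'   their closed-form Gaussian conditional given the estimation-period
#'   differences, coefficient levels are rebuilt through the difference
#'   recursion and the process model re-assembled. Covariate and systematic
#'   components extend deterministically (covariates must be supplied to
#'   `T_star`).
#' * `log_pooling`: the second-order differences of the spline coefficients
#'   are drawn as `gamma_k ~ N(Gamma_k, Theta_k)` where the moments follow
#'   the pooling recursions `Gamma_k = W G + (1 - W) Gamma_{k-1}` (seeded at
#'   the last estimated second-order difference) and
#'   `Theta_k = W V + (1 - W) Theta_{k-1}` (seeded at the population's
#'   smoothing variance), so that with increasing horizon the distribution of
#'   rates of change converges to the global `(G, V)`. `W = 1` pools fully
#'   from the start; `W = 0` reproduces the default extrapolation law.
#'
#' @param posterior A `tmmp_posterior` from [fit_tmmp()].
#' @param method Projection method; defaults to the model's projection spec.
#' @param W,G,V Log-pooling weight and global median/variance of past
#'   second-order differences. `G`, `V` default to
#'   [compute_pooling_targets()] on the posterior.
#' @param seed Integer seed for the projection-period draws.
#' @return An object of class `tmmp_projection`: array `eta`
#'   (`draws x chains x populations x (T_star - T)`) on the natural scale,
#'   plus the projection times. If `T_star == T` the projection is empty.
#' @export
project_tmmp <- function(posterior, method = NULL, W = NULL, G = NULL, V = NULL,
                         seed = 1L) {
  plan <- posterior$plan
  grid <- posterior$grid
  method <- method %||% posterior$model$projection$method %||% "default_conditional"
  if (identical(method, "joint"))
    stop_tmmp("projection method 'joint' estimates to T_star inside fit_tmmp()")
  H <- grid$T_star - plan$T_fit
  nk <- posterior$n_draws
  nc <- posterior$chains
  if (identical(method, "log_pooling")) {
    W <- W %||% posterior$model$projection$W
    if (is.null(W) || W < 0 || W > 1) stop_tmmp("log_pooling needs W in [0, 1]")
  }
  out <- array(NA_real_, c(nk, nc, plan$C, max(H, 0)),
               dimnames = list(NULL, NULL, plan$pops, NULL))
  proj <- structure(list(eta = out, times = if (H > 0) plan$T_fit + seq_len(H) else integer(),
                         method = method, grid = grid, pops = plan$pops),
                    class = "tmmp_projection")
  if (H == 0) return(proj)

  if (identical(method, "log_pooling")) {
    if (is.null(G) || is.null(V)) {
      gv <- compute_pooling_targets(posterior)
      G <- G %||% gv["G"]
      V <- V %||% gv["V"]
    }
    if (plan$smooth$r != 2)
      stop_tmmp("log_pooling projection requires an r = 2 spline smoother")
  }

  # extended basis over 1..T_star
  Bext <- extend_basis(plan$smooth$B, times = seq_len(grid$T_star),
                       to_time = grid$T_star)
  K_added <- attr(Bext, "K_added")
  if (K_added < 1) K_added <- 1L
  m <- plan$smooth$m
  r <- plan$smooth$r
  tproj <- plan$T_fit + seq_len(H)
  cond_cache <- new.env(parent = emptyenv())

  set.seed(substream_seed(seed, "project"))
  for (it in seq_len(nk)) for (ch in seq_len(nc)) {
    st <- draw_state(posterior, it, ch)
    for (ci in seq_len(plan$C)) {
      p <- plan$pops[ci]
      th <- st$theta[[paste0("theta[", p, "]")]] %||% NULL
      gam <- draw_gamma(posterior, plan, p, it, ch, st)
      delta <- drop(plan$smooth$A %*% gam)
      sigma_c <- plan$pop_scale(st, p)
      if (identical(method, "log_pooling")) {
        gnew <- pooling_draw(gam, K_added, W, G, V, sigma_c)
      } else {
        cnd <- unit_conditional(plan, st, p, m, K_added, cond_cache)
        gnew <- drop(cnd$W %*% gam) + sigma_c * chol_draw(cnd$Ru)
      }
      delta_star <- extend_levels(delta, r, gnew)
      eps_star <- drop(Bext[tproj, , drop = FALSE] %*% delta_star)
      if (plan$eta_mode == "logistic") {
        eta_T <- pop_eta(plan, st, p)[plan$T_fit]
        proj$eta[it, ch, ci, ] <- logistic_continue(
          eta_T, th, plan, eps_star)
      } else {
        z <- pop_z(plan, st, p)[tproj] + eps_star
        proj$eta[it, ch, ci, ] <- transform_invert(z, plan$transform)
      }
    }
  }
  proj
}

# rebuild a sampler state from stored draws
draw_state <- function(posterior, it, ch) {
  st <- new.env(parent = emptyenv())
  st$theta <- lapply(posterior$draws$theta, function(a) a[it, ch, ])
  sc_ids <- vapply(posterior$plan$scalars, `[[`, "", "id")
  st$sc <- if (length(sc_ids)) posterior$draws$pars[it, ch, sc_ids] else numeric()
  st
}

# model-scale differenced coefficients for one population and draw,
# reconstructed from the non-centered storage
draw_gamma <- function(posterior, plan, p, it, ch, st = NULL) {
  st <- st %||% draw_state(posterior, it, ch)
  th <- st$theta[[paste0("theta[", p, "]")]]
  u <- th[grep("^u_gamma\\[", names(th))]
  plan$gamma_of_u(st, p, u)
}

# conditional of K_added new differenced coefficients given the m estimated
# ones, computed at unit kernel scale (scale-invariant weights; the
# conditional sd then scales linearly with the kernel scale)
unit_conditional <- function(plan, st, p, m, K_added, cache) {
  kern <- plan$kernel_for(st, p)
  scale_nm <- kernel_scale_name(kern$family)
  kern[[scale_nm]] <- 1
  key <- paste(kern$family, paste(format(unlist(kern[-1]), digits = 12), collapse = ","))
  if (!is.null(cache[[key]])) return(cache[[key]])
  s <- autocovariance(kern, 0:(m + K_added - 1))
  S <- stats::toeplitz(s) + diag(1e-10, m + K_added)
  idx <- seq_len(m)
  S11 <- S[idx, idx]
  S21 <- S[-idx, idx, drop = FALSE]
  S22 <- S[-idx, -idx, drop = FALSE]
  Wm <- S21 %*% solve(S11)
  covu <- S22 - Wm %*% t(S21)
  covu <- (covu + t(covu)) / 2 + diag(1e-12, K_added)
  val <- list(W = Wm, Ru = chol(covu))
  cache[[key]] <- val
  val
}

# log-pooling draw of K_added new second-order differences
pooling_draw <- function(gam, K_added, W, G, V, sigma_c) {
  Gam <- gam[length(gam)]      # seeded at the last estimated 2nd difference
  The <- sigma_c^2
  out <- numeric(K_added)
  for (j in seq_len(K_added)) {
    Gam <- W * G + (1 - W) * Gam
    The <- W * V + (1 - W) * The
    out[j] <- stats::rnorm(1, Gam, sqrt(The))
  }
  out
}

logistic_continue <- function(eta_T, th, plan, eps_star) {
  lay <- plan$logistic
  P <- bounded_transform(th[lay$p_idx], 0.5, 1)
  om <- bounded_transform(th[lay$w_idx], 0.01, 0.5)
  H <- length(eps_star)
  eta <- numeric(H)
  prev <- eta_T
  for (h in seq_len(H)) {
    z <- systematic_logistic_step(prev, P, om) + eps_star[h]
    prev <- stats::plogis(z)
    eta[h] <- prev
  }
  eta
}

#' Global pooling targets from a fitted posterior
#'
#' Computes the global median `G` and variance `V` of the estimated past
#' second-order differences of the spline coefficients: posterior medians of
#' every differenced coefficient, pooled across all populations and
#' coefficient indices.
#'
#' @param posterior A `tmmp_posterior` whose model uses a differenced
#'   smoother.
#' @return Named vector `c(G = ..., V = ...)`.
#' @export
compute_pooling_targets <- function(posterior) {
  plan <- posterior$plan
  nk <- posterior$n_draws
  nc <- posterior$chains
  meds <- unlist(lapply(plan$pops, function(p) {
    g <- vapply(seq_len(nk * nc), function(i) {
      it <- (i - 1) %% nk + 1
      ch <- (i - 1) %/% nk + 1
      draw_gamma(posterior, plan, p, it, ch)
    }, numeric(plan$smooth$m))
    apply(rbind(g), 1, stats::median)
  }))
  if (length(meds) < 2) stop_tmmp("fewer than 2 pooled differences")
  c(G = stats::median(meds), V = stats::var(meds))
}

#' @export
print.tmmp_projection <- function(x, ...) {
  cat(sprintf("<tmmp_projection> %s, %d populations, horizon %d\n",
              x$method, length(x$pops), length(x$times)))
  invisible(x)
}
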