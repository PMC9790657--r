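#' Fit a temporal model for multiple populations
#'
#' Samples from the joint posterior of all free parameters and the latent
#' field by a Gibbs scheme: conditionally Gaussian coefficient blocks
#' (systematic-trend parameters, covariate coefficients and the differenced
#' smoothing coefficients, jointly per population) are updated by elliptical
#' slice sampling; scalar hyperparameters (kernel hyperparameters, hierarchy
#' means and scales, estimated observation sds) by stepping-out slice
#' sampling. The smoothing coefficients are parametrized by their free
#' differences and mapped through the constraint-mode recovery, so anchoring
#' constraints hold exactly in every draw. Populations with no observations
#' receive latent-field draws from their prior (prior-predictive behaviour).
#'
#' @param model A [tmmp_model()].
#' @param data An observation table (see [read_observations()]), or any data
#'   frame with the same columns.
#' @param grid A [time_grid()].
#' @param covariates Covariate table over `1..T_star` (long format), if the
#'   model uses covariates.
#' @param offsets Optional offsets matrix (populations x `T_star`, see
#'   [read_offsets()]).
#' @param groupings Optional data frame mapping `population` to grouping
#'   columns (innermost first) for multi-level hierarchies.
#' @param chains,draws,warmup,seed MCMC settings; defaults from
#'   `model$inference`.
#' @param thin Keep every `thin`-th draw after warmup.
#' @param verbose Print progress.
#' @return An object of class `tmmp_posterior`: draw arrays for every free
#'   parameter and the latent field `eta` (`draws x chains x C x T`), the
#'   fitted model, grid, seed and a config fingerprint. If any parameter has
#'   split-Rhat above 1.05 a warning is attached (field `rhat_warning`) and
#'   signalled.
#' @export
fit_tmmp <- function(model, data, grid, covariates = NULL, offsets = NULL,
                     groupings = NULL, chains = NULL, draws = NULL,
                     warmup = NULL, seed = NULL, thin = 1L, verbose = FALSE) {
  inf <- model$inference %||% list()
  chains <- chains %||% inf$chains %||% 2L
  draws <- draws %||% inf$draws %||% 1000L
  warmup <- warmup %||% inf$warmup %||% 1000L
  seed <- seed %||% inf$seed %||% 1L
  plan <- compile_model(model, data, grid, covariates, offsets, groupings)

  n_keep <- draws %/% thin
  par_labels <- c(unlist(lapply(plan$blocks, `[[`, "labels")),
                  vapply(plan$scalars, `[[`, "", "id"))
  n_par <- length(par_labels)
  pars <- array(NA_real_, c(n_keep, chains, n_par),
                dimnames = list(NULL, NULL, par_labels))
  eta <- array(NA_real_, c(n_keep, chains, plan$C, grid$T),
               dimnames = list(NULL, NULL, plan$pops, NULL))
  theta_store <- lapply(plan$blocks, function(b)
    array(NA_real_, c(n_keep, chains, b$dim), dimnames = list(NULL, NULL, b$labels)))
  names(theta_store) <- vapply(plan$blocks, `[[`, "", "id")

  init_ll <- NULL
  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, "chain", ch))
    st <- new_state(plan)
    ll0 <- total_logpost(plan, st)
    if (!is.finite(ll0))
      stop_tmmp("non-finite log-density at initialization (chain %d)", ch)
    if (is.null(init_ll)) init_ll <- ll0
    keep_i <- 0L
    for (it in seq_len(warmup + draws)) {
      one_sweep(plan, st)
      if (it > warmup && (it - warmup) %% thin == 0L) {
        keep_i <- keep_i + 1L
        vec <- c(unlist(st$theta, use.names = FALSE), st$sc)
        pars[keep_i, ch, ] <- vec
        for (b in names(st$theta)) theta_store[[b]][keep_i, ch, ] <- st$theta[[b]]
        for (ci in seq_len(plan$C))
          eta[keep_i, ch, ci, ] <- pop_eta(plan, st, plan$pops[ci])[seq_len(grid$T)]
      }
      if (verbose && it %% 200 == 0) cat(sprintf("chain %d iter %d\n", ch, it))
    }
  }

  post <- structure(list(
    draws = list(pars = pars, eta = eta, theta = theta_store),
    model = model, grid = grid, pops = plan$pops, plan = plan,
    chains = chains, n_draws = n_keep, seed = seed,
    fingerprint = substream_seed(0, serialize_config(model), seed, chains, draws, warmup)),
    class = "tmmp_posterior")

  if (chains >= 2) {
    dg <- diagnose(post)
    bad <- dg$parameter[!is.na(dg$rhat) & dg$rhat > 1.05]
    post$diagnostics <- dg
    if (length(bad)) {
      post$rhat_warning <- sprintf("split-Rhat > 1.05 for: %s",
                                   paste(utils::head(bad, 8), collapse = ", "))
      warning(post$rhat_warning, call. = FALSE)
    }
  }
  post
}

# one full Gibbs sweep over blocks then scalars (in place)
one_sweep <- function(plan, st) {
  joint_state <- if (!is.null(plan$joint)) joint_mh_update(plan, st)
  for (b in plan$blocks) {
    bid <- b$id
    if (identical(joint_state, "exact")) break
    # the conjugate mean update is an exact Gibbs step; run it regardless of
    # whether the joint proposal was accepted
    if (!is.null(b$conjugate_rw2)) { rw2_conjugate_update(plan, st, b); next }
    if (is.null(joint_state)) {
      mh <- if (!is.null(plan$mh_info[[bid]])) mh_gauss_update(plan, st, b) else FALSE
      if (identical(mh, "exact")) next
    }
    # after an approximate MH jump, an elliptical slice pass refines locally
    lfun <- function(x) {
      st$theta[[bid]] <- x
      s <- 0
      for (p in b$pops) {
        s <- s + pop_loglik(plan, st, p)
        if (!is.finite(s)) return(s)
      }
      for (bd in b$prior_dep_blocks %||% character())
        s <- s + plan$block_by_id[[bd]]$prior_logdens(st)
      s
    }
    for (rep in seq_len(b$ess_reps %||% 1L)) {
      mu <- b$prior_mean(st)
      nu <- b$prior_draw(st)
      up <- ess_update(st$theta[[bid]], mu, nu, lfun)
      st$theta[[bid]] <- up$x
    }
    for (i in b$coord_slice %||% integer()) {
      mu <- b$prior_mean(st)
      sd_v <- b$prior_sd(st)
      logf <- function(x) {
        v <- st$theta[[bid]]
        v[i] <- x
        stats::dnorm(x, mu[i], sd_v[i], log = TRUE) + lfun(v)
      }
      up <- slice_update(st$theta[[bid]][i], logf, w = sd_v[i])
      st$theta[[bid]][i] <- up$x
    }
    if (!is.null(b$shift)) asis_shift_update(plan, st, b)
    if (isTRUE(b$omega_trade)) {
      omega_trade_update(plan, st, b)
      trade_path_update(plan, st, b, 2L)
      trade_path_update(plan, st, b, 3L)
      path_mh_update(plan, st, b)
      path_mh_update(plan, st, b)
    }
  }
  for (s in plan$scalars) {
    sid <- s$id
    lik_fast <- if (s$affects_lik && !is.null(s$sigma_of) &&
                    plan$eta_mode == "linear") sigma_lik_fast(plan, st, s)
    lfun <- function(x) {
      st$sc[[sid]] <- x
      v <- s$logprior(x, st)
      if (!is.finite(v)) return(v)
      for (bd in s$dep_blocks) {
        v <- v + plan$block_by_id[[bd]]$prior_logdens(st)
        if (!is.finite(v)) return(v)
      }
      if (s$affects_lik) {
        if (!is.null(lik_fast)) return(v + lik_fast(x))
        for (p in s$lik_pops %||% plan$pops) {
          v <- v + pop_loglik(plan, st, p)
          if (!is.finite(v)) return(v)
        }
      }
      v
    }
    up <- slice_update(st$sc[[sid]], lfun, w = s$w, lo = s$lo, hi = s$hi)
    st$sc[[sid]] <- up$x
    if (!is.null(s$sigma_of)) {
      asis_rescale(plan, st, s)
      if (plan$eta_mode == "linear") {
        if (!is.null(s$lik_pops)) sigma_block_mh(plan, st, s)
        else if (!is.null(plan$joint)) sigma_joint_mh(plan, st, s)
      }
    }
    if (isTRUE(s$asis_kernel)) asis_kernel_update(plan, st, s)
    if (!is.null(s$dev)) asis_dev_update(plan, st, s)
    if (!is.null(s$dev_rw2)) asis_rw2dev_update(plan, st, s)
    if (!is.null(s$hier_dev)) asis_hier_dev_update(plan, st, s)
  }
  invisible(st)
}

# Exact 1-d Gibbs move for the logistic transition's reference level: the
# anchor level Omega and the reference-year deviation eps[t*] enter the path
# only through their sum, so shifting Omega by d while subtracting d from
# eps[t*] leaves the likelihood untouched; the conditional for d under the
# two Gaussian priors is itself Gaussian and is sampled directly.
omega_trade_update <- function(plan, st, b) {
  p <- b$pops[1]
  lay <- plan$logistic
  ui <- plan$u_idx[[p]]
  sig <- plan$pop_scale(st, p)
  if (!is.finite(sig) || sig <= 0) return(invisible(st))
  m <- length(ui)
  e_t <- numeric(m)
  e_t[plan$t_star[[p]]] <- 1
  L <- plan$gamma_chol_unit(st)
  v <- if (is.null(L)) e_t / sig else drop(forwardsolve(L, e_t)) / sig
  th <- st$theta[[b$id]]
  om0 <- th[lay$omega_idx]
  u0 <- th[ui]
  a <- b$prior_mean(st)[lay$omega_idx]
  s_h <- b$prior_sd(st)[lay$omega_idx]
  P <- 1 / s_h^2 + sum(v^2)
  mpost <- (-(om0 - a) / s_h^2 + sum(v * u0)) / P
  d <- stats::rnorm(1, mpost, 1 / sqrt(P))
  th[lay$omega_idx] <- om0 + d
  th[ui] <- u0 - v * d
  st$theta[[b$id]] <- th
  invisible(st)
}

# Taylor-expanded Metropolis-Hastings update of a logistic-transition
# population's whole latent path, in path (logit) space. The likelihood is
# Gaussian and diagonal in the path z; the non-centred deviations u(z)
# follow from inverting the recursion (unit Jacobian), and their standard
# normal log-density is expanded to second order through the banded
# derivative of the inversion. Proposals come from the resulting Gaussian,
# corrected by exact MH with the matched reverse expansion.
path_mh_update <- function(plan, st, b) {
  p <- b$pops[1]
  lay <- plan$logistic
  if (!isTRUE(lay$include_eps)) return(invisible(st))
  if (plan$dm$family != "logit_normal" || plan$transform$name != "logit")
    return(invisible(st))
  ob <- plan$obs_by_pop[[p]]
  ui <- plan$u_idx[[p]]
  sig <- plan$pop_scale(st, p)
  if (!is.finite(sig) || sig <= 0) return(invisible(st))
  L <- plan$gamma_chol_unit(st)
  th <- st$theta[[b$id]]
  P <- bounded_transform(th[lay$p_idx], 0.5, 1)
  om <- bounded_transform(th[lay$w_idx], 0.01, 0.5)
  Om <- th[lay$omega_idx]
  tstar <- plan$t_star[[p]]
  m <- length(ui)

  sd_i <- NULL
  if (length(ob$t)) {
    sd_i <- ob$sd
    if (any(ob$sd_missing)) {
      key <- if (plan$dm$variance == "global") rep("sd_global", sum(ob$sd_missing))
             else paste0("sd_src[", ob$source[ob$sd_missing], "]")
      sd_i[ob$sd_missing] <- st$sc[key]
    }
  }
  u_of_z <- function(z) {
    eps <- invert_logistic_path(z, Om, P, om, tstar)
    if (is.null(L)) eps / sig else drop(forwardsolve(L, eps)) / sig
  }
  # banded derivative of eps with respect to z, as a dense m x m matrix
  Jeps_of_z <- function(z) {
    J <- diag(m)
    x <- 1 / (1 + exp(-z))
    if (tstar < m) for (t in (tstar + 1):m) {
      xp <- x[t - 1]
      J[t, t - 1] <- if (xp < P) {
        r <- xp / P
        y <- P / (1 + exp(-(log(r) - log1p(-r) + om)))
        -(P - y) * (1 - xp) / ((1 - y) * (P - xp))
      } else -1
    }
    if (tstar > 1) for (t in (tstar - 1):1) {
      xn <- x[t + 1]
      J[t, t + 1] <- if (xn < P) {
        r <- xn / P
        y <- P / (1 + exp(-(log(r) - log1p(-r) - om)))
        -(P - y) * (1 - xn) / ((1 - y) * (P - xn))
      } else -1
    }
    J
  }
  target <- function(z, u) {
    v <- -0.5 * sum(u^2)
    if (length(ob$t)) v <- v + sum(stats::dnorm(ob$zy, z[ob$t], sd_i, log = TRUE))
    v
  }
  # Gaussian expansion of the target around a point: N(mu_q, Q^-1)
  expansion <- function(z, u) {
    Ju <- if (is.null(L)) Jeps_of_z(z) / sig
          else forwardsolve(L, Jeps_of_z(z)) / sig
    Q <- crossprod(Ju)
    rhs <- -drop(crossprod(Ju, u))
    if (length(ob$t)) {
      w <- 1 / sd_i^2
      for (i in seq_along(ob$t)) {
        tt <- ob$t[i]
        Q[tt, tt] <- Q[tt, tt] + w[i]
        rhs[tt] <- rhs[tt] + w[i] * (ob$zy[i] - z[tt])
      }
    }
    R <- tryCatch(chol(Q + diag(1e-10, m)), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    list(R = R, mu = z + backsolve(R, backsolve(R, rhs, transpose = TRUE)))
  }
  z0 <- stats::qlogis(pop_eta(plan, st, p))
  u0 <- th[ui]
  ex0 <- expansion(z0, u0)
  if (is.null(ex0)) return(invisible(st))
  z1 <- ex0$mu + backsolve(ex0$R, stats::rnorm(m))
  u1 <- u_of_z(z1)
  if (any(!is.finite(u1))) return(invisible(st))
  ex1 <- expansion(z1, u1)
  if (is.null(ex1)) return(invisible(st))
  logq <- function(ex, z) {
    v <- drop(ex$R %*% (z - ex$mu))
    sum(log(diag(ex$R))) - 0.5 * sum(v^2)
  }
  lacc <- target(z1, u1) - target(z0, u0) + logq(ex1, z0) - logq(ex0, z1)
  if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
    th[ui] <- u1
    st$theta[[b$id]] <- th
  }
  invisible(st)
}

# Exact path-preserving update of a logistic transition parameter (the
# asymptote or rate): holding the realized logit path fixed, the deviations
# that reproduce it under a candidate parameter value follow by inverting
# the recursion (a unit-Jacobian change of variables), so the conditional
# for the parameter is its prior times the standard-normal density of the
# implied non-centred deviations -- the likelihood never moves.
trade_path_update <- function(plan, st, b, coord) {
  p <- b$pops[1]
  lay <- plan$logistic
  if (!isTRUE(lay$include_eps)) return(invisible(st))
  ui <- plan$u_idx[[p]]
  sig <- plan$pop_scale(st, p)
  if (!is.finite(sig) || sig <= 0) return(invisible(st))
  L <- plan$gamma_chol_unit(st)
  th0 <- st$theta[[b$id]]
  z <- stats::qlogis(pop_eta(plan, st, p))
  mu <- b$prior_mean(st)
  sdv <- b$prior_sd(st)
  tstar <- plan$t_star[[p]]
  u_of <- function(x) {
    th <- th0
    th[coord] <- x
    eps <- invert_logistic_path(z, th[lay$omega_idx],
                                bounded_transform(th[lay$p_idx], 0.5, 1),
                                bounded_transform(th[lay$w_idx], 0.01, 0.5),
                                tstar)
    if (is.null(L)) eps / sig else drop(forwardsolve(L, eps)) / sig
  }
  logf <- function(x) {
    u <- u_of(x)
    if (any(!is.finite(u))) return(-Inf)
    stats::dnorm(x, mu[coord], sdv[coord], log = TRUE) - 0.5 * sum(u^2)
  }
  up <- slice_update(th0[coord], logf, w = sdv[coord])
  th0[coord] <- up$x
  th0[ui] <- u_of(up$x)
  st$theta[[b$id]] <- th0
  invisible(st)
}

# deviations reproducing a given logit path under the logistic recursion
invert_logistic_path <- function(z, Omega, P, om, tstar) {
  Tn <- length(z)
  eps <- numeric(Tn)
  eps[tstar] <- z[tstar] - Omega
  if (tstar < Tn) for (t in (tstar + 1):Tn) {
    zp <- z[t - 1]
    x <- 1 / (1 + exp(-zp))
    if (x < P) {
      r <- x / P
      zn <- P / (1 + exp(-(log(r) - log1p(-r) + om)))
      zp <- log(zn) - log1p(-zn)
    }
    eps[t] <- z[t] - zp
  }
  if (tstar > 1) for (t in (tstar - 1):1) {
    zn1 <- z[t + 1]
    x <- 1 / (1 + exp(-zn1))
    if (x < P) {
      r <- x / P
      zn <- P / (1 + exp(-(log(r) - log1p(-r) - om)))
      zn1 <- log(zn) - log1p(-zn)
    }
    eps[t] <- z[t] - zn1
  }
  eps
}

# Deviation-rescale interweaving for a location-hierarchy scale: holding the
# standardized deviations of the population-level values about their group
# means fixed, the scale's conditional is its prior plus the likelihood
# under the rescaled values.
asis_hier_dev_update <- function(plan, st, s) {
  hd <- s$hier_dev
  x0 <- st$sc[[s$id]]
  bids <- paste0("theta[", hd$pops, "]")
  parent_val <- vapply(hd$pops, function(p) st$theta[[hd$parent[[p]]]], 0)
  w0 <- vapply(seq_along(hd$pops), function(i)
    (st$theta[[bids[i]]][hd$coord] - parent_val[i]) / exp(x0), 0)
  logf <- function(x) {
    v <- s$logprior(x, st)
    if (!is.finite(v)) return(v)
    for (i in seq_along(hd$pops)) {
      st$theta[[bids[i]]][hd$coord] <- parent_val[i] + exp(x) * w0[i]
      v <- v + pop_loglik(plan, st, hd$pops[i])
      if (!is.finite(v)) return(v)
    }
    v
  }
  up <- slice_update(x0, logf, w = s$w)
  st$sc[[s$id]] <- up$x
  for (i in seq_along(hd$pops))
    st$theta[[bids[i]]][hd$coord] <- parent_val[i] + exp(up$x) * w0[i]
  invisible(st)
}

# Collapsed update of an RW(2) innovation scale: the mean paths are
# integrated out analytically. Each component's county means beta_g are
# exchangeable around the path mu with sd sigma_p, so the component average
# beta_bar has marginal covariance Sigma_rw2(sigma_mu) + (sigma_p^2 / G) I;
# the scale is sliced against that marginal and the mean block immediately
# redrawn from its exact conditional. Removes the funnel between the scale
# and the paths entirely.
asis_rw2dev_update <- function(plan, st, s) {
  dv <- s$dev_rw2
  b <- plan$block_by_id[[dv$block]]
  kids <- b$prior_dep_blocks %||% character()
  if (!length(kids)) return(invisible(st))
  Tn <- dv$Tn
  x0 <- st$sc[[s$id]]
  G <- length(kids)
  D2 <- difference_matrix(Tn, 2)
  DtD <- crossprod(D2)
  # per-component county-average and its noise variance
  csd_full <- plan$block_by_id[[kids[1]]]$prior_sd(st)
  beta_bar <- Reduce(`+`, lapply(kids, function(kb) st$theta[[kb]])) / G
  logf <- function(x) {
    v <- s$logprior(x, st)
    if (!is.finite(v)) return(v)
    prec0 <- DtD / exp(x)^2
    prec0[1, 1] <- prec0[1, 1] + 1 / 100
    prec0[2, 2] <- prec0[2, 2] + 1 / 100
    # eigen-space evaluation keeps the marginal stable across extreme scales
    ei <- eigen(prec0, symmetric = TRUE)
    lam <- pmax(ei$values, 1e-300)
    for (pcomp in seq_len(dv$P)) {
      idx <- (pcomp - 1) * Tn + seq_len(Tn)
      s2 <- csd_full[idx][1]^2 / G
      marg <- 1 / lam + s2
      z <- drop(crossprod(ei$vectors, beta_bar[idx]))
      v <- v - 0.5 * (Tn * log(2 * pi) + sum(log(marg)) + sum(z^2 / marg))
      if (!is.finite(v)) return(v)
    }
    v
  }
  up <- slice_update(x0, logf, w = s$w, lo = s$lo, hi = s$hi)
  st$sc[[s$id]] <- up$x
  # redraw the mean paths from their exact conditional under the new scale
  rw2_conjugate_update(plan, st, b)
  invisible(st)
}

# Joint Gaussianized independence-MH update over all coupled coefficient
# blocks: stacks every block into one vector, assembles the exact joint
# Gaussian prior precision (diagonal normal segments; cross terms for
# segments whose mean is another block; banded RW(2) pieces), adds the
# Gaussianized likelihood, and proposes from the resulting conditional.
# Returns "exact" when the working model is the exact likelihood, "approx"
# after an MH-corrected step.
joint_mh_update <- function(plan, st) {
  J <- plan$joint
  n <- J$total
  g <- joint_gauss_proposal(plan, st)
  if (is.null(g)) return(NULL)
  prop <- g$mu_post + backsolve(g$Rp, stats::rnorm(n))
  set_all <- function(x) {
    for (bid in J$ids)
      st$theta[[bid]] <- x[J$offsets[[bid]] + seq_len(J$dims[[bid]])]
  }
  x0 <- unlist(lapply(J$ids, function(bid) st$theta[[bid]]), use.names = FALSE)
  if (g$exact) {
    set_all(prop)
    return("exact")
  }
  logq <- function(x) {
    v <- drop(g$Rp %*% (x - g$mu_post))
    -0.5 * sum(v^2)
  }
  logp <- function(x) {
    set_all(x)
    s <- 0
    for (b in plan$blocks) s <- s + b$prior_logdens(st)
    for (p in plan$pops) {
      s <- s + pop_loglik(plan, st, p)
      if (!is.finite(s)) return(s)
    }
    s
  }
  lp0 <- logp(x0)
  lp1 <- logp(prop)
  acc <- is.finite(lp1) && log(stats::runif(1)) < (lp1 - lp0 + logq(x0) - logq(prop))
  set_all(if (acc) prop else x0)
  "approx"
}

# assemble the Gaussianized joint conditional over all coupled blocks
joint_gauss_proposal <- function(plan, st) {
  J <- plan$joint
  n <- J$total
  tr <- plan$transform
  prec <- matrix(0, n, n)
  rhs <- numeric(n)
  L <- plan$gamma_chol_unit(st)
  # prior assembly
  for (b in plan$blocks) {
    off <- J$offsets[[b$id]]
    pos <- 0L
    for (s in b$segments) {
      idx <- off + pos + seq_len(s$d)
      if (s$kind == "rw2") {
        Tn <- s$Tn
        D2 <- difference_matrix(Tn, 2)
        P0 <- crossprod(D2) / s$sd_fn(st)^2
        P0[1, 1] <- P0[1, 1] + 1 / 100
        P0[2, 2] <- P0[2, 2] + 1 / 100
        for (pcomp in seq_len(s$P)) {
          ii <- idx[(pcomp - 1) * Tn + seq_len(Tn)]
          prec[ii, ii] <- prec[ii, ii] + P0
        }
      } else if (!is.null(s$mean_block)) {
        Dv <- 1 / s$sd_fn(st)^2
        jj <- J$offsets[[s$mean_block]] + seq_len(s$d)
        prec[cbind(idx, idx)] <- prec[cbind(idx, idx)] + Dv
        prec[cbind(jj, jj)] <- prec[cbind(jj, jj)] + Dv
        prec[cbind(idx, jj)] <- prec[cbind(idx, jj)] - Dv
        prec[cbind(jj, idx)] <- prec[cbind(jj, idx)] - Dv
      } else {
        sdv <- s$sd_fn(st)
        muv <- s$mean_fn(st)
        prec[cbind(idx, idx)] <- prec[cbind(idx, idx)] + 1 / sdv^2
        rhs[idx] <- rhs[idx] + muv / sdv^2
      }
      pos <- pos + s$d
    }
  }
  # likelihood assembly
  exact <- tr$name == "identity" && plan$dm$family == "normal" ||
    tr$name == "logit" && plan$dm$family == "logit_normal"
  for (p in plan$pops) {
    ob <- plan$obs_by_pop[[p]]
    if (!length(ob$t)) next
    y <- ob$y
    dom <- tr$domain
    usable <- if (tr$name == "identity") rep(TRUE, length(y)) else
      y > dom[1] & y < dom[2]
    if (!all(usable)) exact <- FALSE
    if (!any(usable)) next
    w <- tr$forward(y[usable])
    dg <- switch(tr$name,
                 identity = rep(1, sum(usable)),
                 log = 1 / y[usable],
                 log10 = 1 / (y[usable] * log(10)),
                 logit = 1 / (y[usable] * (1 - y[usable])))
    sd_i <- ob$sd
    if (any(ob$sd_missing)) {
      key <- if (plan$dm$variance == "global") rep("sd_global", sum(ob$sd_missing))
             else paste0("sd_src[", ob$source[ob$sd_missing], "]")
      sd_i[ob$sd_missing] <- st$sc[key]
    }
    sdw <- if (plan$dm$family == "logit_normal") sd_i[usable] else sd_i[usable] * abs(dg)
    D <- matrix(0, sum(usable), n)
    for (bid in plan$pop_blocks[[p]]) {
      Mo <- plan$maps[[bid]][[p]][ob$t[usable], , drop = FALSE]
      ui <- plan$mh_info[[bid]][[p]]$u_cols %||% integer()
      if (length(ui)) {
        sig <- plan$pop_scale(st, p)
        Du <- Mo[, ui, drop = FALSE]
        Mo[, ui] <- if (is.null(L)) sig * Du else sig * (Du %*% L)
      }
      D[, J$offsets[[bid]] + seq_len(J$dims[[bid]])] <- Mo
    }
    r <- (w - plan$const[p, ob$t[usable]]) / sdw^2
    prec <- prec + crossprod(D / sdw)
    rhs <- rhs + drop(crossprod(D, r))
  }
  Rp <- tryCatch(chol(prec), error = function(e) NULL)
  if (is.null(Rp)) return(NULL)
  mu_post <- backsolve(Rp, backsolve(Rp, rhs, transpose = TRUE))
  list(Rp = Rp, mu_post = mu_post, exact = exact)
}

# Collapsed world-scale move through the joint proposal: propose the scale
# by a random walk, redraw every coupled coefficient block from the joint
# working-model conditional at the proposed scale, and accept jointly.
sigma_joint_mh <- function(plan, st, s, step = 0.5) {
  J <- plan$joint
  x0 <- st$sc[[s$id]]
  x1 <- x0 + stats::rnorm(1, 0, step)
  if (x1 <= s$lo || x1 >= s$hi) return(invisible(st))
  th0 <- lapply(J$ids, function(bid) st$theta[[bid]])
  names(th0) <- J$ids
  logp <- function() {
    v <- s$logprior(st$sc[[s$id]], st)
    for (b in plan$blocks) v <- v + b$prior_logdens(st)
    for (p in plan$pops) {
      v <- v + pop_loglik(plan, st, p)
      if (!is.finite(v)) return(v)
    }
    v
  }
  logq <- function(g, x) {
    v <- drop(g$Rp %*% (x - g$mu_post))
    sum(log(diag(g$Rp))) - 0.5 * sum(v^2)
  }
  lp0 <- logp()
  g0 <- joint_gauss_proposal(plan, st)
  if (is.null(g0)) return(invisible(st))
  x0vec <- unlist(th0, use.names = FALSE)
  st$sc[[s$id]] <- x1
  g1 <- joint_gauss_proposal(plan, st)
  if (is.null(g1)) { st$sc[[s$id]] <- x0; return(invisible(st)) }
  prop <- g1$mu_post + backsolve(g1$Rp, stats::rnorm(J$total))
  for (bid in J$ids)
    st$theta[[bid]] <- prop[J$offsets[[bid]] + seq_len(J$dims[[bid]])]
  lp1 <- logp()
  lacc <- lp1 - lp0 + logq(g0, x0vec) - logq(g1, prop)
  if (is.finite(lacc) && log(stats::runif(1)) < lacc) return(invisible(st))
  st$sc[[s$id]] <- x0
  for (bid in J$ids) st$theta[[bid]] <- th0[[bid]]
  invisible(st)
}

# Independence Metropolis-Hastings update of a linear coefficient block,
# proposing from the exact conjugate posterior of the Gaussianized working
# model g1(y) ~ N(z, (sd * g1'(y))^2) and correcting with the exact
# likelihood. For identity-transform normal and logit-transform logit-normal
# models the working model is exact and the proposal is always accepted.
# Returns FALSE (caller falls back to elliptical slice sampling) when a
# working response cannot be formed.
mh_gauss_update <- function(plan, st, b) {
  bid <- b$id
  x0 <- st$theta[[bid]]
  d <- b$dim
  g <- block_gauss_proposal(plan, st, b)
  if (is.null(g)) return(FALSE)
  zdraw <- stats::rnorm(d)
  prop <- g$mu_post + backsolve(g$Rp, zdraw)
  if (g$exact) {
    st$theta[[bid]] <- prop
    return("exact")
  }
  # MH correction: q has precision Rp'Rp
  logq <- function(x) {
    v <- drop(g$Rp %*% (x - g$mu_post))
    sum(log(diag(g$Rp))) - 0.5 * sum(v^2)
  }
  logp <- function(x) {
    st$theta[[bid]] <- x
    s <- b$prior_logdens(st)
    for (p in b$pops) {
      s <- s + pop_loglik(plan, st, p)
      if (!is.finite(s)) return(s)
    }
    s
  }
  lp0 <- logp(x0)
  lp1 <- logp(prop)
  acc <- is.finite(lp1) && log(stats::runif(1)) < (lp1 - lp0 + logq(x0) - logq(prop))
  st$theta[[bid]] <- if (acc) prop else x0
  "approx"
}

# Gaussianized working-model conditional for one coefficient block at the
# current state: returns the proposal mean, its upper Cholesky precision
# factor, and whether the working model is the exact likelihood.
block_gauss_proposal <- function(plan, st, b) {
  bid <- b$id
  info <- plan$mh_info[[bid]]
  d <- b$dim
  tr <- plan$transform
  prior_mu <- b$prior_mean(st)
  prior_sd <- b$prior_sd(st)
  prec <- diag(1 / prior_sd^2, d)
  rhs <- prior_mu / prior_sd^2
  exact <- tr$name == "identity" && plan$dm$family == "normal" ||
    tr$name == "logit" && plan$dm$family == "logit_normal"
  L <- plan$gamma_chol_unit(st)
  for (p in b$pops) {
    ob <- plan$obs_by_pop[[p]]
    if (!length(ob$t)) next
    y <- ob$y
    dom <- tr$domain
    usable <- y > dom[1] & y < dom[2]
    if (tr$name == "identity") usable <- rep(TRUE, length(y))
    if (!any(usable)) { if (!all(usable)) exact <- FALSE; next }
    if (!all(usable)) exact <- FALSE
    w <- tr$forward(y[usable])
    dg <- switch(tr$name,
                 identity = rep(1, sum(usable)),
                 log = 1 / y[usable],
                 log10 = 1 / (y[usable] * log(10)),
                 logit = 1 / (y[usable] * (1 - y[usable])))
    sd_i <- ob$sd
    if (any(ob$sd_missing)) {
      key <- if (plan$dm$variance == "global") rep("sd_global", sum(ob$sd_missing))
             else paste0("sd_src[", ob$source[ob$sd_missing], "]")
      sd_i[ob$sd_missing] <- st$sc[key]
    }
    sdw <- if (plan$dm$family == "logit_normal") sd_i[usable] else sd_i[usable] * abs(dg)
    ip <- info[[p]]
    D <- ip$M_obs[usable, , drop = FALSE]
    if (length(ip$u_cols)) {
      sig <- plan$pop_scale(st, p)
      Du <- D[, ip$u_cols, drop = FALSE]
      D[, ip$u_cols] <- if (is.null(L)) sig * Du else sig * (Du %*% L)
    }
    # residualize contributions of the other blocks and the constant
    z_oth <- plan$const[p, ob$t[usable]]
    for (bd in setdiff(plan$pop_blocks[[p]], bid)) {
      Mo <- plan$maps[[bd]][[p]]
      if (!is.null(Mo))
        z_oth <- z_oth + drop(Mo[ob$t[usable], , drop = FALSE] %*%
                                plan$coef_fns[[bd]](st, st$theta[[bd]]))
    }
    r <- (w - z_oth) / sdw^2
    prec <- prec + crossprod(D / sdw)
    rhs <- rhs + drop(crossprod(D, r))
  }
  Rp <- tryCatch(chol(prec), error = function(e) NULL)
  if (is.null(Rp)) return(NULL)
  mu_post <- backsolve(Rp, backsolve(Rp, rhs, transpose = TRUE))
  list(Rp = Rp, mu_post = mu_post, exact = exact)
}

# Collapsed scale move: propose the scale by a random walk, redraw the
# population's whole coefficient block from the working-model conditional at
# the proposed scale, and accept jointly. Removes the funnel between a
# smoothing scale and its coefficients that single-site updates cannot cross.
sigma_block_mh <- function(plan, st, s, step = 0.6) {
  p <- s$lik_pops
  if (is.null(p) || length(p) != 1) return(invisible(st))
  b <- plan$block_by_id[[paste0("theta[", p, "]")]]
  if (is.null(b) || is.null(plan$mh_info[[b$id]])) return(invisible(st))
  x0 <- st$sc[[s$id]]
  th0 <- st$theta[[b$id]]
  x1 <- x0 + stats::rnorm(1, 0, step)
  if (x1 <= s$lo || x1 >= s$hi) return(invisible(st))
  lp0 <- s$logprior(x0, st) + b$prior_logdens(st) + pop_loglik(plan, st, p)
  g0 <- block_gauss_proposal(plan, st, b)
  if (is.null(g0)) return(invisible(st))
  st$sc[[s$id]] <- x1
  g1 <- block_gauss_proposal(plan, st, b)
  if (is.null(g1)) { st$sc[[s$id]] <- x0; return(invisible(st)) }
  th1 <- g1$mu_post + backsolve(g1$Rp, stats::rnorm(b$dim))
  st$theta[[b$id]] <- th1
  lp1 <- s$logprior(x1, st) + b$prior_logdens(st) + pop_loglik(plan, st, p)
  logq <- function(g, x) {
    v <- drop(g$Rp %*% (x - g$mu_post))
    sum(log(diag(g$Rp))) - 0.5 * sum(v^2)
  }
  lacc <- lp1 - lp0 + logq(g0, th0) - logq(g1, th1)
  if (is.finite(lacc) && log(stats::runif(1)) < lacc) return(invisible(st))
  st$sc[[s$id]] <- x0
  st$theta[[b$id]] <- th0
  invisible(st)
}

# Exact Gibbs update of an RW(2)-prior mean block whose "children" are the
# coefficient blocks with independent normal priors centred on it: the full
# conditional is Gaussian with banded RW(2) precision plus the children's
# diagonal precision.
rw2_conjugate_update <- function(plan, st, b) {
  P <- b$conjugate_rw2$P
  Tn <- b$conjugate_rw2$Tn
  sd_mu <- b$segments[[1]]$sd_fn(st)
  kids <- b$prior_dep_blocks %||% character()
  D2 <- difference_matrix(Tn, 2)
  prec0 <- crossprod(D2) / sd_mu^2
  prec0[1, 1] <- prec0[1, 1] + 1 / 100
  prec0[2, 2] <- prec0[2, 2] + 1 / 100
  out <- numeric(P * Tn)
  for (pcomp in seq_len(P)) {
    idx <- (pcomp - 1) * Tn + seq_len(Tn)
    prec <- prec0
    rhs <- numeric(Tn)
    for (kb in kids) {
      child <- plan$block_by_id[[kb]]
      csd <- child$prior_sd(st)[idx]
      prec <- prec + diag(1 / csd^2)
      rhs <- rhs + st$theta[[kb]][idx] / csd^2
    }
    R <- chol(prec)
    mu_post <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    out[idx] <- mu_post + backsolve(R, stats::rnorm(Tn))
  }
  st$theta[[b$id]] <- out
  invisible(st)
}

# Fast likelihood closure for a smoothing-scale scalar under a linear mean
# structure: the transformed-scale mean is z0 + sigma(x) * v with z0 and v
# precomputed at the current state, so each slice evaluation costs one
# vector operation per population instead of full reassembly. Returns NULL
# when the scale does not enter linearly (e.g. no observations).
sigma_lik_fast <- function(plan, st, s) {
  ppops <- s$lik_pops %||% plan$pops
  x0 <- st$sc[[s$id]]
  pre <- list()
  for (p in ppops) {
    ob <- plan$obs_by_pop[[p]]
    if (!length(ob$t)) next
    bid <- paste0("theta[", p, "]")
    ui <- plan$u_idx[[p]]
    M <- plan$maps[[bid]][[p]]
    if (is.null(M) || is.null(ui)) return(NULL)
    L <- plan$gamma_chol_unit(st)
    u <- st$theta[[bid]][ui]
    gu <- if (is.null(L)) u else drop(L %*% u)
    v <- drop(M[ob$t, ui, drop = FALSE] %*% gu)
    z_full <- pop_z(plan, st, p)[ob$t]
    sig0 <- s$sigma_of(x0, st, p)
    sd_i <- ob$sd
    if (any(ob$sd_missing)) {
      key <- if (plan$dm$variance == "global") rep("sd_global", sum(ob$sd_missing))
             else paste0("sd_src[", ob$source[ob$sd_missing], "]")
      sd_i[ob$sd_missing] <- st$sc[key]
    }
    pre[[p]] <- list(z0 = z_full - sig0 * v, v = v, ob = ob, sd = sd_i)
  }
  logit_fam <- plan$dm$family == "logit_normal"
  function(x) {
    ll <- 0
    for (p in names(pre)) {
      q <- pre[[p]]
      sig <- s$sigma_of(x, st, p)
      if (sig < 0) return(-Inf)
      z <- q$z0 + sig * q$v
      ll <- ll + if (logit_fam) {
        sum(stats::dnorm(q$ob$zy, z, q$sd, log = TRUE)) - q$ob$jac
      } else {
        sum(stats::dnorm(q$ob$y, transform_invert(z, plan$transform), q$sd, log = TRUE))
      }
      if (!is.finite(ll)) return(ll)
    }
    ll
  }
}

# Interweaved (ASIS) update of a smoothing-scale scalar: holding the
# model-scale coefficients gamma = sigma * L u fixed, the scalar's centered
# full conditional is its prior plus the Gaussian density of gamma under the
# implied scale -- in terms of the stored u this is
#   logprior(x) - m * sum(log sigma_p(x)) - 0.5 * sum((sigma_p_old / sigma_p(x))^2 |u_p|^2)
# after which u is rescaled so the likelihood is untouched. Breaks the
# ridge between the scale and the non-centered coefficients.
asis_rescale <- function(plan, st, s) {
  sid <- s$id
  ppops <- if (identical(s$asis_pops, "all")) plan$pops else s$asis_pops
  x0 <- st$sc[[sid]]
  sig_old <- vapply(ppops, function(p) s$sigma_of(x0, st, p), 0)
  if (any(sig_old <= 0)) return(invisible(st))
  ssq <- vapply(ppops, function(p) {
    u <- st$theta[[paste0("theta[", p, "]")]][plan$u_idx[[p]]]
    sum(u^2)
  }, 0)
  m <- plan$smooth$m
  prior_fn <- s$asis_logprior %||% s$logprior
  logf <- function(x) {
    v <- prior_fn(x, st)
    if (!is.finite(v)) return(v)
    sig <- vapply(ppops, function(p) s$sigma_of(x, st, p), 0)
    if (any(sig <= 0)) return(-Inf)
    v - m * sum(log(sig)) - 0.5 * sum((sig_old / sig)^2 * ssq)
  }
  up <- slice_update(x0, logf, w = s$w, lo = s$lo, hi = s$hi)
  sig_new <- vapply(ppops, function(p) s$sigma_of(up$x, st, p), 0)
  st$sc[[sid]] <- up$x
  if (!is.null(s$asis_scalar_set)) {
    upd <- s$asis_scalar_set(up$x, x0, st)
    st$sc[names(upd)] <- upd
  }
  for (i in seq_along(ppops)) {
    p <- ppops[i]
    bid <- paste0("theta[", p, "]")
    st$theta[[bid]][plan$u_idx[[p]]] <-
      st$theta[[bid]][plan$u_idx[[p]]] * (sig_old[i] / sig_new[i])
  }
  invisible(st)
}

# Translation interweaving for a hierarchy location mean block: the mean and
# all its population-level children move together by a common shift (the
# children's prior terms are invariant), so the conditional for the shift is
# the mean's own prior plus the affected populations' likelihoods. Kills the
# ridge between a group mean and its children when the within-group scale is
# small.
asis_shift_update <- function(plan, st, b) {
  sh <- b$shift
  x0 <- st$theta[[b$id]]
  bids <- paste0("theta[", sh$pops, "]")
  th0 <- vapply(seq_along(sh$pops), function(i)
    st$theta[[bids[i]]][sh$coord], 0)
  logf <- function(d) {
    st$theta[[b$id]] <- x0 + d
    v <- b$prior_logdens(st)
    if (!is.finite(v)) return(v)
    for (i in seq_along(sh$pops)) {
      st$theta[[bids[i]]][sh$coord] <- th0[i] + d
      v <- v + pop_loglik(plan, st, sh$pops[i])
      if (!is.finite(v)) return(v)
    }
    v
  }
  up <- slice_update(0, logf, w = 1)
  st$theta[[b$id]] <- x0 + up$x
  for (i in seq_along(sh$pops))
    st$theta[[bids[i]]][sh$coord] <- th0[i] + up$x
  invisible(st)
}

# Deviation-rescale interweaving for a shrinkage scale: holding the
# standardized deviations (theta - mean) / sigma fixed, the scale's
# conditional is its prior plus the likelihood under the rescaled
# coefficients.
asis_dev_update <- function(plan, st, s) {
  dv <- s$dev
  x0 <- st$sc[[s$id]]
  sig0 <- exp(x0)
  mu <- st$theta[[dv$mean_block]][dv$sel]
  w0 <- lapply(dv$blocks, function(bid)
    (st$theta[[bid]][dv$sel] - mu) / sig0)
  pops <- unique(unlist(lapply(dv$blocks, function(bid)
    plan$block_by_id[[bid]]$pops)))
  logf <- function(x) {
    v <- s$logprior(x, st)
    if (!is.finite(v)) return(v)
    for (i in seq_along(dv$blocks))
      st$theta[[dv$blocks[i]]][dv$sel] <- mu + exp(x) * w0[[i]]
    for (p in pops) {
      v <- v + pop_loglik(plan, st, p)
      if (!is.finite(v)) return(v)
    }
    v
  }
  up <- slice_update(x0, logf, w = s$w)
  st$sc[[s$id]] <- up$x
  for (i in seq_along(dv$blocks))
    st$theta[[dv$blocks[i]]][dv$sel] <- mu + exp(up$x) * w0[[i]]
  invisible(st)
}

# Interweaved update of a kernel shape hyperparameter (rho, theta, ell):
# holding the model-scale differenced coefficients gamma = sigma_p L(x) u
# fixed (so the likelihood does not change), the shape's centered conditional
# is its prior plus the Gaussian density of gamma under the implied unit
# correlation; u is then back-transformed through the new factor.
asis_kernel_update <- function(plan, st, s) {
  if (is.null(plan$u_idx) || !length(plan$u_idx)) return(invisible(st))
  sid <- s$id
  x0 <- st$sc[[sid]]
  L0 <- plan$gamma_chol_unit(st)
  if (is.null(L0)) return(invisible(st))
  gam <- lapply(plan$pops, function(p) {
    u <- st$theta[[paste0("theta[", p, "]")]][plan$u_idx[[p]]]
    plan$pop_scale(st, p) * drop(L0 %*% u)
  })
  names(gam) <- plan$pops
  logf <- function(x) {
    v <- s$logprior(x, st)
    if (!is.finite(v)) return(v)
    st$sc[[sid]] <- x
    L <- tryCatch(plan$gamma_chol_unit(st), error = function(e) NULL)
    st$sc[[sid]] <- x0
    if (is.null(L)) return(-Inf)
    R <- t(L)   # upper factor of the unit-scale covariance
    for (p in plan$pops) {
      sig <- plan$pop_scale(st, p)
      v <- v + chol_logdens(gam[[p]] / sig, rep(0, nrow(L)), R) -
        length(gam[[p]]) * log(sig)
      if (!is.finite(v)) return(v)
    }
    v
  }
  up <- slice_update(x0, logf, w = s$w, lo = s$lo, hi = s$hi)
  st$sc[[sid]] <- up$x
  Lnew <- plan$gamma_chol_unit(st)
  for (p in plan$pops) {
    bid <- paste0("theta[", p, "]")
    st$theta[[bid]][plan$u_idx[[p]]] <-
      forwardsolve(Lnew, gam[[p]] / plan$pop_scale(st, p))
  }
  invisible(st)
}

#' @export
print.tmmp_posterior <- function(x, ...) {
  cat(sprintf("<tmmp_posterior> %d populations, %d x %d draws, %d parameters\n",
              length(x$pops), x$n_draws, x$chains, dim(x$draws$pars)[3]))
  if (!is.null(x$rhat_warning)) cat("  warning:", x$rhat_warning, "\n")
  invisible(x)
}

# draws as (iter, chain, parameter) array, including eta cells
posterior_array <- function(posterior, include_eta = TRUE) {
  pars <- posterior$draws$pars
  if (!include_eta) return(pars)
  eta <- posterior$draws$eta
  d <- dim(eta)
  eta_flat <- array(eta, c(d[1], d[2], d[3] * d[4]))
  dimnames(eta_flat)[[3]] <- as.vector(outer(dimnames(eta)[[3]], seq_len(d[4]),
                                             function(p, t) paste0("eta[", p, ",", t, "]")))
  arr <- array(NA_real_, c(d[1], d[2], dim(pars)[3] + d[3] * d[4]),
               dimnames = list(NULL, NULL, c(dimnames(pars)[[3]], dimnames(eta_flat)[[3]])))
  arr[, , seq_len(dim(pars)[3])] <- pars
  arr[, , dim(pars)[3] + seq_len(d[3] * d[4])] <- eta_flat
  arr
}

#' Posterior summary of the latent field
#'
#' @param posterior A `tmmp_posterior`.
#' @param probs Quantiles to report.
#' @return A data frame with population, time, year, mean and the requested
#'   quantiles of the latent indicator on its natural scale.
#' @export
eta_summary <- function(posterior, probs = c(0.025, 0.5, 0.975)) {
  eta <- posterior$draws$eta
  d <- dim(eta)
  flat <- array(eta, c(d[1] * d[2], d[3], d[4]))
  out <- expand.grid(time = seq_len(d[4]), population = dimnames(eta)[[3]],
                     stringsAsFactors = FALSE)[, 2:1]
  out$year <- posterior$grid$years[out$time]
  out$mean <- as.vector(t(apply(flat, c(2, 3), mean)))
  for (q in probs)
    out[[sprintf("q%g", 100 * q)]] <- as.vector(t(apply(flat, c(2, 3), stats::quantile, q)))
  out
}
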