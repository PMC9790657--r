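# Compile a tmmp_model + data into the internal sampling plan: a set of
# conditionally-Gaussian coefficient blocks (updated by elliptical slice
# sampling) and scalar hyperparameters (updated by slice sampling), plus
# closures that assemble the latent field and evaluate the likelihood
# population by population.
#
# Block interface:
#   id, pops, dim, labels, init,
#   prior_mean(state), prior_draw(state), prior_logdens(state)   [uses state]
#   maps: per-pop T_star x dim design matrix (linear mean models), or NULL
# Scalar interface:
#   id, init, lo, hi, w, affects_lik, logtarget(state, x)

new_state <- function(plan) {
  st <- new.env(parent = emptyenv())
  st$theta <- lapply(plan$blocks, function(b) b$init)
  names(st$theta) <- vapply(plan$blocks, `[[`, "", "id")
  sc <- vapply(plan$scalars, `[[`, 0, "init")
  names(sc) <- vapply(plan$scalars, `[[`, "", "id")
  st$sc <- sc
  st
}

# transformed-scale process mean for one population over 1..T_star.
# Smoothing coefficients are stored non-centered (standard normal u); each
# block's coef_fn maps the stored vector to the model-scale coefficients.
pop_z <- function(plan, st, c_id) {
  z <- plan$const[c_id, ]
  for (bid in plan$pop_blocks[[c_id]]) {
    M <- plan$maps[[bid]][[c_id]]
    if (!is.null(M)) z <- z + drop(M %*% plan$coef_fns[[bid]](st, st$theta[[bid]]))
  }
  z
}

pop_eta <- function(plan, st, c_id) {
  if (plan$eta_mode == "logistic") {
    bid <- paste0("theta[", c_id, "]")
    th <- plan$coef_fns[[bid]](st, st$theta[[bid]])
    lay <- plan$logistic
    eps <- drop(plan$smooth$BA %*% th[lay$delta_idx])
    logistic_path(Omega = th[lay$omega_idx],
                  P_tilde = bounded_transform(th[lay$p_idx], 0.5, 1),
                  omega = bounded_transform(th[lay$w_idx], 0.01, 0.5),
                  t_star = plan$t_star[[c_id]], eps = eps,
                  include_eps_in_recursion = plan$logistic$include_eps)
  } else {
    transform_invert(pop_z(plan, st, c_id), plan$transform)
  }
}

pop_loglik <- function(plan, st, c_id) {
  ob <- plan$obs_by_pop[[c_id]]
  if (is.null(ob) || length(ob$t) == 0) return(0)
  eta <- pop_eta(plan, st, c_id)
  eta_i <- eta[ob$t]
  dm <- plan$dm
  if (dm$family %in% c("normal", "logit_normal")) {
    sd_i <- ob$sd
    if (any(ob$sd_missing)) {
      key <- if (dm$variance == "global") rep("sd_global", sum(ob$sd_missing))
             else paste0("sd_src[", ob$source[ob$sd_missing], "]")
      sd_i[ob$sd_missing] <- st$sc[key]
    }
    if (dm$family == "logit_normal") {
      if (any(eta_i <= 0 | eta_i >= 1)) return(-Inf)
      return(sum(stats::dnorm(ob$zy, stats::qlogis(eta_i), sd_i, log = TRUE)) - ob$jac)
    }
    return(sum(stats::dnorm(ob$y, eta_i, sd_i, log = TRUE)))
  }
  if (dm$family == "binomial") {
    if (any(eta_i <= 0 | eta_i >= 1)) return(-Inf)
    return(sum(stats::dbinom(ob$y, ob$denom, eta_i, log = TRUE)))
  }
  if (any(eta_i <= 0)) return(-Inf)
  sum(stats::dnbinom(ob$y, size = plan$dm$phi, mu = ob$denom * eta_i, log = TRUE))
}

total_lik <- function(plan, st) {
  s <- 0
  for (c_id in plan$pops) s <- s + pop_loglik(plan, st, c_id)
  s
}

# total log-posterior (likelihood + block priors + scalar priors); used by
# the likelihood-consistency invariant test
total_logpost <- function(plan, st) {
  lp <- total_lik(plan, st)
  for (b in plan$blocks) lp <- lp + b$prior_logdens(st)
  for (s in plan$scalars) lp <- lp + s$logprior(st$sc[[s$id]], st)
  lp
}

default_prior <- function(priors, name, fallback) {
  p <- priors[[name]]
  if (is.null(p)) fallback else utils::modifyList(fallback, p)
}

# name of the kernel's scale hyperparameter
kernel_scale_name <- function(family) {
  if (family %in% c("ar1", "squared_exponential", "matern")) "kappa" else "sigma"
}

compile_model <- function(model, data, grid, covariates = NULL, offsets = NULL,
                          groupings = NULL) {
  pops <- sort(unique(data$population))
  if (!is.null(groupings)) pops <- sort(unique(c(pops, groupings$population)))
  if (!length(pops)) stop_tmmp("no populations found in the data")
  C <- length(pops)
  joint <- identical(model$projection$method, "joint")
  T_fit <- if (joint) grid$T_star else grid$T
  T_star <- grid$T_star
  tr <- transform_spec(model$transform)
  dm <- data_model_spec(model$data_model$family,
                        model$data_model$variance %||% "fixed",
                        phi = model$data_model$phi)

  # per-population observation bundles (times restricted to the fit window)
  obs_by_pop <- setNames(vector("list", C), pops)
  for (p in pops) {
    rows <- data[data$population == p & data$time <= T_fit, , drop = FALSE]
    if (!nrow(rows)) { obs_by_pop[[p]] <- list(t = integer()); next }
    sdm <- is.na(rows$sampling_sd)
    if (dm$variance == "fixed" && any(sdm) && dm$family %in% c("normal", "logit_normal"))
      stop_tmmp("variance mode 'fixed' but population '%s' has rows without sampling_sd", p)
    obs_by_pop[[p]] <- list(
      t = rows$time, y = rows$value,
      zy = if (dm$family == "logit_normal") stats::qlogis(rows$value) else NULL,
      jac = if (dm$family == "logit_normal") sum(log(rows$value * (1 - rows$value))) else 0,
      sd = rows$sampling_sd, sd_missing = sdm,
      source = rows$source, denom = rows$denominator)
  }

  # reference times t*_c: configured value, or mid observation period
  t_star_cfg <- model$systematic$t_star
  t_star <- setNames(vapply(pops, function(p) {
    if (!is.null(t_star_cfg)) return(as.integer(t_star_cfg))
    tt <- obs_by_pop[[p]]$t
    if (length(tt)) as.integer(round(mean(range(tt)))) else as.integer(round((1 + T_fit) / 2))
  }, 0L), pops)

  # constant (fixed) part of the transformed-scale mean over 1..T_star
  const <- matrix(0, C, T_star, dimnames = list(pops, NULL))
  if (!is.null(offsets)) {
    common <- intersect(rownames(offsets), pops)
    const[common, ] <- const[common, ] + offsets[common, seq_len(T_star), drop = FALSE]
  }

  cov_kind <- model$covariate$kind %||% "none"
  sys_kind <- model$systematic$kind %||% "none"
  priors <- model$priors %||% list()

  cov_mat <- function(col) {
    # population x T_star matrix of a covariate column
    if (is.null(covariates)) stop_tmmp("model uses covariates but none were supplied")
    if (!col %in% names(covariates)) stop_tmmp("covariate column '%s' is missing", col)
    M <- matrix(NA_real_, C, T_star, dimnames = list(pops, NULL))
    keep <- covariates$population %in% pops & covariates$time <= T_star
    M[cbind(match(covariates$population[keep], pops), covariates$time[keep])] <-
      covariates[[col]][keep]
    if (anyNA(M)) stop_tmmp("covariate '%s' incomplete over 1..%d", col, T_star)
    M
  }

  if (cov_kind == "gbd_nonlinear") {
    betas <- as.numeric(model$covariate$betas)
    const <- const + covariate_gbd(cov_mat("LDI"), cov_mat("EDU"), cov_mat("HIV"), betas)
  }
  if (sys_kind == "trapezoid") {
    pr <- model$systematic$parameters
    for (p in pops) {
      q <- pr[[p]] %||% pr
      const[p, ] <- const[p, ] + systematic_trapezoid(
        seq_len(T_star), q$xi, q$gamma0, q$lambda1, q$lambda2, q$lambda3)
    }
  }
  if (sys_kind == "linear_trend" && identical(model$systematic$strategy, "fixed")) {
    for (p in pops)
      const[p, ] <- const[p, ] + systematic_linear(
        seq_len(T_star), model$systematic$alpha0[[p]],
        model$systematic$alpha1[[p]], t_star[[p]])
  }

  # smoothing structure (shared across populations: common span 1..T_fit)
  sspec <- model_smoothing_spec(model)
  smooth <- smoothing_matrices(sspec, seq_len(T_fit))
  scale_name <- kernel_scale_name(model$smoothing$kernel$family)
  sigma_mode <- model$smoothing$sigma %||% "shared"
  estimate_extra <- setdiff(model$smoothing$estimate %||% character(), scale_name)

  blocks <- list()
  scalars <- list()
  maps <- list()
  coef_fns <- list()
  u_idx <- setNames(vector("list", C), pops)   # u_gamma positions in theta[p]
  pop_blocks <- setNames(rep(list(character()), C), pops)

  # dep = "all" (every block's prior depends on this scalar), "none", or a
  # character vector of block ids; lik_pops limits the likelihood term to a
  # subset of populations (NULL = all) when affects_lik is TRUE.
  # Scale-type scalars additionally declare sigma_of(x, st, p) -- the
  # smoothing scale they imply for population p -- enabling an interweaved
  # centered update (ASIS) that breaks the scale/coefficient ridge.
  add_scalar <- function(id, init, logprior, lo = -Inf, hi = Inf, w = 1,
                         affects_lik = FALSE, dep = "all", lik_pops = NULL,
                         sigma_of = NULL, asis_pops = NULL, asis_kernel = FALSE,
                         shift = NULL, dev = NULL, hier_dev = NULL) {
    scalars[[length(scalars) + 1L]] <<- list(
      id = id, init = init, lo = lo, hi = hi, w = w,
      affects_lik = affects_lik, dep = dep, lik_pops = lik_pops,
      sigma_of = sigma_of, asis_pops = asis_pops, asis_kernel = asis_kernel,
      shift = shift, dev = dev, hier_dev = hier_dev, logprior = logprior)
  }

  # ---- kernel hyperparameters -------------------------------------------
  # per-population kernel scale resolved through sigma_mode
  pop_scale <- switch(sigma_mode,
    fixed = {
      fixed_val <- model$smoothing$kernel[[scale_name]]
      function(st, p) fixed_val
    },
    shared = function(st, p) exp(st$sc[["log_sigma_delta"]]),
    hierarchical = function(st, p) exp(st$sc[[paste0("log_sigma_delta[", p, "]")]]),
    bmat_lambda = function(st, p) exp(st$sc[["log_sigma_delta_w"]]) *
      (1 + st$sc[[paste0("lambda[", p, "]")]]),
    per_age_group = {
      gmap <- unlist(model$smoothing$groups)
      function(st, p) exp(st$sc[[paste0("log_sigma_delta[", gmap[[p]], "]")]])
    },
    stop_tmmp("unknown smoothing sigma mode '%s'", sigma_mode))

  kernel_for <- function(st, p) {
    override <- setNames(list(pop_scale(st, p)), scale_name)
    for (nm in estimate_extra) override[[nm]] <- st$sc[[paste0("kernel_", nm)]]
    model_kernel(model, override)
  }

  # non-centered smoothing: the block stores u ~ N(0, I); gamma = sigma_c * L u
  # with L the (unit-scale) kernel correlation Cholesky factor, cached over
  # the shape hyperparameters
  corr_cache <- new.env(parent = emptyenv())
  gamma_chol_unit <- function(st) {
    if (model$smoothing$kernel$family == "iid") return(NULL)
    override <- setNames(list(1), scale_name)
    for (nm in estimate_extra) override[[nm]] <- st$sc[[paste0("kernel_", nm)]]
    kern <- model_kernel(model, override)
    key <- paste(format(unlist(kern[-1]), digits = 12), collapse = ",")
    if (is.null(corr_cache[[key]])) {
      S <- stats::toeplitz(autocovariance(kern, 0:(smooth$m - 1))) +
        diag(1e-10, smooth$m)
      corr_cache[[key]] <- t(chol(S))
    }
    corr_cache[[key]]
  }
  gamma_of_u <- function(st, p, u) {
    L <- gamma_chol_unit(st)
    if (is.null(L)) pop_scale(st, p) * u
    else pop_scale(st, p) * drop(L %*% u)
  }

  gamma_segment <- function(p) {
    list(kind = "norm", d = smooth$m,
         mean_fn = function(st) rep(0, smooth$m),
         sd_fn = function(st) rep(1, smooth$m))
  }

  # scalars for sigma_mode
  sig_prior <- default_prior(priors, "sigma_delta", list(dist = "halfnormal", sd = 5))
  halfnorm_log <- function(x, st) {
    # prior on sd, evaluated for log-sd parametrization (includes Jacobian)
    prior_logdens_sd(sig_prior, exp(x)) + x
  }
  if (sigma_mode == "shared") {
    add_scalar("log_sigma_delta", log(0.1), halfnorm_log, w = 0.7,
               affects_lik = TRUE, dep = "none",
               sigma_of = function(x, st, p) exp(x), asis_pops = pops)
  } else if (sigma_mode == "hierarchical") {
    for (p in pops)
      add_scalar(paste0("log_sigma_delta[", p, "]"), log(0.1),
                 function(x, st)
                   stats::dnorm(x, st$sc[["mu_log_sigma"]],
                                exp(st$sc[["log_s_log_sigma"]]), log = TRUE),
                 w = 0.7, dep = "none", affects_lik = TRUE, lik_pops = p,
                 sigma_of = function(x, st, p) exp(x), asis_pops = p)
    # weakly-informative world mean for log smoothing scales: a flat prior
    # on a log scale is improper-like, letting the whole hierarchy drift
    # into regions (sigma ~ e^-30) the likelihood cannot distinguish
    mu_pr <- default_prior(priors, "mu_log_sigma",
                           list(dist = "normal", mean = log(0.05), sd = 2))
    add_scalar("mu_log_sigma", log(0.1), function(x, st)
      stats::dnorm(x, mu_pr$mean, mu_pr$sd, log = TRUE) +
        sum(stats::dnorm(st$sc[paste0("log_sigma_delta[", pops, "]")], x,
                         exp(st$sc[["log_s_log_sigma"]]), log = TRUE)),
      w = 1, dep = "none",
      # translation interweave: move the hierarchy mean and every
      # population's log-scale together, rescaling u so the fit is unchanged
      sigma_of = function(x, st, p)
        exp(st$sc[[paste0("log_sigma_delta[", p, "]")]] + x - st$sc[["mu_log_sigma"]]),
      asis_pops = pops)
    scalars[[length(scalars)]]$asis_logprior <- local({ pr <- mu_pr
      function(x, st) stats::dnorm(x, pr$mean, pr$sd, log = TRUE) })
    lsd_ids <- paste0("log_sigma_delta[", pops, "]")
    scalars[[length(scalars)]]$asis_scalar_set <- local({ ids <- lsd_ids
      function(xnew, x0, st) setNames(st$sc[ids] + (xnew - x0), ids) })
    # the spread of log-scales is unitless; half-normal(1) is the
    # weakly-informative default at this level
    add_scalar("log_s_log_sigma", log(0.5), function(x, st)
      halfnorm_jac(exp(x), 1) + x +
        sum(stats::dnorm(st$sc[paste0("log_sigma_delta[", pops, "]")],
                         st$sc[["mu_log_sigma"]], exp(x), log = TRUE)),
      w = 0.7, dep = "none",
      # multiplicative repositioning interweave: rescale the spread of the
      # population log-scales about their mean, holding the coefficients
      # gamma fixed through a matching rescale of u
      sigma_of = function(x, st, p) {
        mu <- st$sc[["mu_log_sigma"]]
        exp(mu + exp(x - st$sc[["log_s_log_sigma"]]) *
              (st$sc[[paste0("log_sigma_delta[", p, "]")]] - mu))
      },
      asis_pops = pops)
    scalars[[length(scalars)]]$asis_logprior <-
      function(x, st) halfnorm_jac(exp(x), 1) + x
    scalars[[length(scalars)]]$asis_scalar_set <- local({ ids <- lsd_ids
      function(xnew, x0, st) {
        mu <- st$sc[["mu_log_sigma"]]
        setNames(mu + exp(xnew - x0) * (st$sc[ids] - mu), ids)
      } })
  } else if (sigma_mode == "bmat_lambda") {
    add_scalar("log_sigma_delta_w", log(0.1), function(x, st)
      halfnorm_jac(exp(x), 5) + x, w = 0.7, affects_lik = TRUE, dep = "none",
      sigma_of = function(x, st, p) exp(x) * (1 + st$sc[[paste0("lambda[", p, "]")]]),
      asis_pops = pops)
    for (p in pops)
      add_scalar(paste0("lambda[", p, "]"), 0,
                 function(x, st) {
                   s <- exp(st$sc[["log_s_lambda"]])
                   stats::dnorm(x, 0, s, log = TRUE) -
                     log(stats::pnorm(2, 0, s) - stats::pnorm(-1, 0, s))
                 }, lo = -1 + 1e-9, hi = 2 - 1e-9, w = 0.5, dep = "none",
                 affects_lik = TRUE, lik_pops = p,
                 sigma_of = function(x, st, p) exp(st$sc[["log_sigma_delta_w"]]) * (1 + x),
                 asis_pops = p)
    add_scalar("log_s_lambda", log(0.5), function(x, st) {
      s <- exp(x)
      lam <- st$sc[paste0("lambda[", pops, "]")]
      halfnorm_jac(s, 5) + x +
        sum(stats::dnorm(lam, 0, s, log = TRUE) -
              log(stats::pnorm(2, 0, s) - stats::pnorm(-1, 0, s)))
    }, w = 0.7, dep = "none")
  } else if (sigma_mode == "per_age_group") {
    gmap <- unlist(model$smoothing$groups)
    for (g in unique(gmap))
      add_scalar(paste0("log_sigma_delta[", g, "]"), log(0.1), halfnorm_log,
                 w = 0.7, affects_lik = TRUE, dep = "none",
                 lik_pops = names(gmap)[gmap == g],
                 sigma_of = function(x, st, p) exp(x),
                 asis_pops = names(gmap)[gmap == g])
  }
  for (nm in estimate_extra) {
    pr <- default_prior(priors, nm, switch(nm,
      rho = list(dist = "uniform", lo = 0, hi = 0.999),
      theta = list(dist = "uniform", lo = -1, hi = 0),
      ell = list(dist = "halfnormal", sd = 10),
      list(dist = "halfnormal", sd = 5)))
    add_scalar(paste0("kernel_", nm), switch(nm, rho = 0.5, theta = -0.1, 1),
               local({ prx <- pr; function(x, st) prior_logdens(prx, x) }),
               lo = pr$lo %||% 0, hi = pr$hi %||% Inf, w = 0.3,
               affects_lik = TRUE, dep = "none", asis_kernel = TRUE)
  }

  # ---- data-model variance scalars --------------------------------------
  any_sd_missing <- any(vapply(obs_by_pop, function(o)
    length(o$t) > 0 && any(o$sd_missing), TRUE))
  if (dm$family %in% c("normal", "logit_normal") && dm$variance != "fixed" &&
      any_sd_missing) {
    sd_pr <- default_prior(priors, "obs_sd", list(dist = "halfnormal", sd = 5))
    if (dm$variance == "global") {
      add_scalar("sd_global", 0.2, function(x, st)
        if (x <= 0) -Inf else prior_logdens_sd(sd_pr, x),
        lo = 1e-8, w = 0.3, affects_lik = TRUE, dep = "none")
    } else {
      srcs <- unique(unlist(lapply(obs_by_pop, function(o) o$source[o$sd_missing])))
      for (s in srcs)
        add_scalar(paste0("sd_src[", s, "]"), 0.2, function(x, st)
          if (x <= 0) -Inf else prior_logdens_sd(sd_pr, x),
          lo = 1e-8, w = 0.3, affects_lik = TRUE, dep = "none")
    }
  }

  # ---- coefficient blocks ------------------------------------------------
  eta_mode <- if (sys_kind == "logistic_transition") "logistic" else "linear"
  logistic <- NULL

  hier <- hierarchy_builder(model, pops, groupings, priors, env = environment())

  if (eta_mode == "logistic") {
    # theta_c = (Omega, Pstar, wstar, delta[1..m]); all conditionally Gaussian
    lay <- list(omega_idx = 1L, p_idx = 2L, w_idx = 3L,
                delta_idx = 3L + seq_len(smooth$m),
                include_eps = !isFALSE(model$systematic$include_eps_in_recursion))
    logistic <- lay
    hOmega <- hier$level_fns("Omega", levels = model$hierarchy$Omega$levels %||% 3L,
                             coord = 1L)
    hP <- hier$level_fns("Pstar", levels = model$hierarchy$Pstar$levels %||% 1L,
                         coord = 2L)
    hW <- hier$level_fns("wstar", levels = model$hierarchy$wstar$levels %||% 3L,
                         coord = 3L)
    for (p in pops) {
      segs <- list(hOmega$segment_for(p), hP$segment_for(p), hW$segment_for(p),
                   gamma_segment(p))
      init <- c(init_logistic_omega(obs_by_pop[[p]], t_star[[p]]), 0, 0,
                rep(0, smooth$m))
      bid <- paste0("theta[", p, "]")
      blocks[[length(blocks) + 1L]] <- make_block(
        bid, p,
        labels = c(paste0(c("Omega[", "Pstar[", "wstar["), p, "]"),
                   paste0("u_gamma[", p, ",", seq_len(smooth$m), "]")),
        segments = segs, init = init)
      # transition parameters benefit from coordinate-wise refreshes on top
      # of the joint elliptical update
      blocks[[length(blocks)]]$coord_slice <- 1:3
      blocks[[length(blocks)]]$omega_trade <- TRUE
      coef_fns[[bid]] <- local({ pp <- p; gi <- 3L + seq_len(smooth$m)
        function(st, x) { x[gi] <- gamma_of_u(st, pp, x[gi]); x } })
      u_idx[[p]] <- 3L + seq_len(smooth$m)
      pop_blocks[[p]] <- bid
    }
  } else {
    # linear mean structure: per-population block + optional shared blocks
    tseq <- seq_len(T_star)
    BA_full <- rbind(smooth$BA, matrix(0, T_star - T_fit, smooth$m))
    shared_cols <- NULL      # shared coefficient block (slopes)
    shared_labels <- character()
    shared_prior_sd <- numeric()
    shared_maps <- setNames(vector("list", C), pops)

    if (cov_kind == "linear" && !identical(model$covariate$strategy, "fixed")) {
      cols <- model$covariate$columns
      Xl <- lapply(cols, cov_mat)
      for (p in pops)
        shared_maps[[p]] <- cbind(shared_maps[[p]],
                                  sapply(Xl, function(M) M[p, ]))
      shared_labels <- c(shared_labels, paste0("beta[", cols, "]"))
      bpr <- default_prior(priors, "beta", list(dist = "normal", mean = 0, sd = 10))
      shared_prior_sd <- c(shared_prior_sd, rep(bpr$sd, length(cols)))
    }
    if (cov_kind == "linear" && identical(model$covariate$strategy, "fixed")) {
      cols <- model$covariate$columns
      bet <- as.numeric(model$covariate$betas)
      for (i in seq_along(cols)) const <- const + bet[i] * cov_mat(cols[i])
    }
    if (cov_kind == "piecewise_nmr") {
      U <- cov_mat(model$covariate$columns %||% "U5MR")
      b2 <- model$covariate$beta2
      W <- (log(U) - log(b2)) * (U > b2)
      if (identical(model$covariate$strategy, "fixed")) {
        const <- const + model$covariate$beta1 * W
      } else {
        for (p in pops) shared_maps[[p]] <- cbind(shared_maps[[p]], W[p, ])
        shared_labels <- c(shared_labels, "beta1")
        bpr <- default_prior(priors, "beta", list(dist = "normal", mean = 0, sd = 10))
        shared_prior_sd <- c(shared_prior_sd, bpr$sd)
      }
    }

    pca <- cov_kind == "pca_linear"
    pca_groups <- if (pca) unlist(model$covariate$groups) else NULL

    has_intercept_any <- cov_kind %in% c("linear", "piecewise_nmr") &&
      !identical(model$covariate$intercept, "none")
    beta0_coord <- (if (sys_kind == "linear_trend" &&
                        !identical(model$systematic$strategy, "fixed")) 2L else 0L) + 1L
    hB0 <- if (has_intercept_any)
      hier$level_fns("beta0", levels = model$hierarchy$beta0$levels %||% 1L,
                     coord = beta0_coord)

    for (p in pops) {
      d_lab <- character()
      M <- NULL
      segs <- list()
      if (sys_kind == "linear_trend" && !identical(model$systematic$strategy, "fixed")) {
        M <- cbind(M, 1, tseq - t_star[[p]])
        d_lab <- c(d_lab, paste0("alpha0[", p, "]"), paste0("alpha1[", p, "]"))
        apr0 <- default_prior(priors, "alpha0", list(dist = "normal", mean = 0, sd = 10))
        apr1 <- default_prior(priors, "alpha1", list(dist = "normal", mean = 0, sd = 10))
        segs <- c(segs, list(list(kind = "norm", d = 2L,
          mean_fn = function(st) c(apr0$mean, apr1$mean),
          sd_fn = function(st) c(apr0$sd, apr1$sd))))
      }
      if (has_intercept_any) {
        M <- cbind(M, rep(1, T_star))
        d_lab <- c(d_lab, paste0("beta0[", p, "]"))
        segs <- c(segs, list(hB0$segment_for(p)))
      }
      norm_d <- length(d_lab)
      segs <- c(segs, list(gamma_segment(p)))
      M <- cbind(M, BA_full)
      d_lab <- c(d_lab, paste0("u_gamma[", p, ",", seq_len(smooth$m), "]"))
      init <- init_linear(obs_by_pop[[p]], const[p, ], tr, t_star[[p]], norm_d,
                          has_alpha = sys_kind == "linear_trend" &&
                            !identical(model$systematic$strategy, "fixed"),
                          m = smooth$m)
      bid <- paste0("theta[", p, "]")
      blocks[[length(blocks) + 1L]] <- make_block(bid, p, labels = d_lab,
                                                  segments = segs, init = init)
      coef_fns[[bid]] <- local({ pp <- p; gi <- norm_d + seq_len(smooth$m)
        function(st, x) { x[gi] <- gamma_of_u(st, pp, x[gi]); x } })
      u_idx[[p]] <- norm_d + seq_len(smooth$m)
      maps[[bid]] <- setNames(list(M), p)
      pop_blocks[[p]] <- c(pop_blocks[[p]], bid)
    }

    if (length(shared_labels)) {
      segs <- list(list(kind = "norm", d = length(shared_labels),
                        mean_fn = function(st) rep(0, length(shared_labels)),
                        sd_fn = function(st) shared_prior_sd))
      blocks[[length(blocks) + 1L]] <- make_block("beta_shared", pops,
        labels = shared_labels, segments = segs,
        init = rep(0, length(shared_labels)))
      maps[["beta_shared"]] <- shared_maps
      coef_fns[["beta_shared"]] <- function(st, x) x
      for (p in pops) pop_blocks[[p]] <- c(pop_blocks[[p]], "beta_shared")
    }

    if (pca) {
      # per-coefficient-group (e.g. county) time-varying PC loadings with a
      # smoothly-evolving hierarchical mean per component
      cols <- model$covariate$columns
      P <- length(cols)
      cgroups <- unique(pca_groups[pops])
      # mean block mu[p, t] with RW(2) prior
      mu_lab <- as.vector(outer(seq_len(T_star), cols,
                                function(t, k) paste0("mu[", k, ",", t, "]")))
      blocks[[length(blocks) + 1L]] <- make_block("pca_mu", character(),
        labels = mu_lab,
        segments = list(list(kind = "rw2", d = P * T_star, P = P, Tn = T_star,
                             sd_fn = function(st) exp(st$sc[["log_sigma_mu"]]))),
        init = rep(0, P * T_star))
      blocks[[length(blocks)]]$conjugate_rw2 <- list(P = P, Tn = T_star)
      add_scalar("log_sigma_mu", log(0.1), function(x, st)
        halfnorm_jac(exp(x), 5) + x, w = 0.7, dep = "pca_mu")
      scalars[[length(scalars)]]$dev_rw2 <- list(block = "pca_mu", P = P, Tn = T_star)
      for (k in cols)
        add_scalar(paste0("log_sigma_pc[", k, "]"), log(0.5), function(x, st)
          halfnorm_jac(exp(x), 5) + x, w = 0.7)
      Xcols <- lapply(cols, cov_mat)
      coef_fns[["pca_mu"]] <- function(st, x) x
      for (g in cgroups) {
        gp <- pops[pca_groups[pops] == g]
        bid <- paste0("betapc[", g, "]")
        lab <- as.vector(outer(seq_len(T_star), cols,
                               function(t, k) paste0("beta[", g, ",", k, ",", t, "]")))
        blocks[[length(blocks) + 1L]] <- make_block(bid, gp, labels = lab,
          segments = list(list(kind = "norm", d = P * T_star,
            mean_block = "pca_mu",
            mean_fn = function(st) st$theta[["pca_mu"]],
            sd_fn = function(st)
              rep(exp(st$sc[paste0("log_sigma_pc[", cols, "]")]), each = T_star))),
          init = rep(0, P * T_star))
        mp <- setNames(vector("list", length(gp)), gp)
        for (p in gp) {
          # eta_{p,t} uses beta[g, k, t] * X_{p,k}; X constant over t per pop
          Mp <- matrix(0, T_star, P * T_star)
          for (k in seq_len(P))
            Mp[cbind(seq_len(T_star), (k - 1) * T_star + seq_len(T_star))] <-
              Xcols[[k]][p, 1]
          mp[[p]] <- Mp
        }
        maps[[bid]] <- mp
        coef_fns[[bid]] <- function(st, x) x
        for (p in gp) pop_blocks[[p]] <- c(pop_blocks[[p]], bid)
      }
      # the mean block's conditional includes the coefficient blocks' priors
      mu_pos <- which(vapply(blocks, `[[`, "", "id") == "pca_mu")
      blocks[[mu_pos]]$prior_dep_blocks <- paste0("betapc[", cgroups, "]")
      # deviation-rescale interweaving for the per-component shrinkage sds
      for (k in seq_along(cols)) {
        sidk <- paste0("log_sigma_pc[", cols[k], "]")
        spos <- which(vapply(scalars, `[[`, "", "id") == sidk)
        scalars[[spos]]$dev <- list(
          blocks = paste0("betapc[", cgroups, "]"),
          sel = (k - 1L) * T_star + seq_len(T_star),
          mean_block = "pca_mu")
      }
    }
  }

  scalars <- mark_scalar_deps(scalars, blocks)

  # Gaussianized independence-proposal info for coefficient blocks: valid for
  # linear mean structures under normal / logit-normal data models. The
  # proposal is the exact conjugate posterior of the working model
  # g1(y) ~ N(z, (sd * g1'(y))^2); the MH correction keeps the chain exact.
  mh_info <- list()
  if (eta_mode == "linear" && dm$family %in% c("normal", "logit_normal")) {
    for (b in blocks) {
      bid <- b$id
      if (is.null(maps[[bid]])) next
      only_norm <- all(vapply(b$segments, `[[`, "", "kind") == "norm")
      if (!only_norm) next
      per_pop <- list()
      ok <- TRUE
      for (p in b$pops) {
        ob <- obs_by_pop[[p]]
        M <- maps[[bid]][[p]]
        if (is.null(M)) { ok <- FALSE; break }
        ui <- if (bid == paste0("theta[", p, "]")) u_idx[[p]] else integer()
        per_pop[[p]] <- list(M_obs = M[ob$t, , drop = FALSE], u_cols = ui)
      }
      if (ok) mh_info[[bid]] <- per_pop
    }
  }

  # Joint update set: when coefficient blocks are coupled -- a shared block
  # spanning several populations, coefficients linked to a smoothed mean
  # block -- single-block updates mix along the coupling ridge only slowly,
  # so the Gaussianized proposal is formed jointly across all coupled blocks
  # with the exact joint prior (diagonal, linked-mean and RW(2) pieces).
  joint <- NULL
  if (eta_mode == "linear" && dm$family %in% c("normal", "logit_normal")) {
    ids <- vapply(blocks, `[[`, "", "id")
    linkable <- vapply(blocks, function(b)
      all(vapply(b$segments, `[[`, "", "kind") == "norm") ||
        (!is.null(b$conjugate_rw2) && length(b$segments) == 1L &&
           b$segments[[1]]$kind == "rw2"), TRUE)
    coupled <- any(vapply(blocks, function(b) length(b$pops) > 1, TRUE)) ||
      any(vapply(blocks, function(b)
        any(vapply(b$segments, function(s) !is.null(s$mean_block), TRUE)), TRUE))
    dims <- vapply(blocks, `[[`, 0, "dim")
    if (coupled && all(linkable) && sum(dims) <= 520) {
      offs <- cumsum(c(0, dims))
      joint <- list(ids = ids,
                    offsets = setNames(offs[-length(offs)], ids),
                    dims = setNames(dims, ids), total = sum(dims))
    }
  }

  plan <- list(model = model, grid = grid, pops = pops, C = C,
               T_fit = T_fit, T_star = T_star, transform = tr, dm = dm,
               obs_by_pop = obs_by_pop, t_star = t_star, const = const,
               smooth = smooth, sspec = sspec,
               blocks = blocks, scalars = scalars, maps = maps,
               coef_fns = coef_fns, u_idx = u_idx, mh_info = mh_info,
               joint = joint, gamma_chol_unit = gamma_chol_unit,
               block_by_id = setNames(blocks, vapply(blocks, `[[`, "", "id")),
               pop_blocks = pop_blocks, eta_mode = eta_mode,
               logistic = logistic, kernel_for = kernel_for,
               pop_scale = pop_scale, gamma_of_u = gamma_of_u)
  plan
}

# half-normal log-density for a scale parameter
halfnorm_jac <- function(s, sd) {
  if (s <= 0) return(-Inf)
  log(2) + stats::dnorm(s, 0, sd, log = TRUE)
}

prior_logdens_sd <- function(prior, s) {
  if (s <= 0) return(-Inf)
  if (identical(prior$dist, "halfnormal")) return(halfnorm_jac(s, prior$sd %||% 5))
  prior_logdens(prior, s)
}

init_logistic_omega <- function(ob, t_star) {
  if (!length(ob$t)) return(stats::qlogis(0.15))
  near <- order(abs(ob$t - t_star))[1]
  stats::qlogis(min(max(ob$y[near], 0.02), 0.95))
}

init_linear <- function(ob, const_row, tr, t_star, norm_d, has_alpha, m) {
  init <- rep(0, norm_d + m)
  if (length(ob$t) && norm_d) {
    z <- transform_apply(pmax(ob$y, 1e-8), tr) - const_row[ob$t]
    pos <- 1L
    if (has_alpha) {
      x <- ob$t - t_star
      sl <- if (length(unique(x)) > 1) stats::cov(x, z) / stats::var(x) else 0
      init[1] <- mean(z) ; init[2] <- sl
      pos <- 3L
    }
    if (pos <= norm_d) init[pos] <- mean(z) - init[1]
  }
  init
}

# Build a block from prior segments. Segment kinds:
#   norm      -- independent normals (mean_fn, sd_fn)
#   mvn       -- zero-mean MVN with Sigma_fn
#   rw2       -- P independent RW(2) paths of length Tn, innovation sd_fn,
#                vague N(0, 10) on the first two points of each path
#   pca_coef  -- N(mu_block values, per-component sd)
make_block <- function(id, pops, labels, segments, init) {
  d <- sum(vapply(segments, `[[`, 0, "d"))
  stopifnot(length(labels) == d, length(init) == d)
  offs <- cumsum(c(0, vapply(segments, `[[`, 0, "d")))
  seg_idx <- lapply(seq_along(segments), function(i) offs[i] + seq_len(segments[[i]]$d))

  prior_mean <- function(st) {
    out <- numeric(d)
    for (i in seq_along(segments)) {
      s <- segments[[i]]
      out[seg_idx[[i]]] <- switch(s$kind,
        norm = s$mean_fn(st),
        mvn = s$mean_fn(st),
        rw2 = 0)
    }
    out
  }
  prior_draw <- function(st) {
    out <- numeric(d)
    for (i in seq_along(segments)) {
      s <- segments[[i]]
      out[seg_idx[[i]]] <- switch(s$kind,
        norm = stats::rnorm(s$d, 0, s$sd_fn(st)),
        mvn = chol_draw(chol(s$Sigma_fn(st))),
        rw2 = rw2_draw(s$P, s$Tn, s$sd_fn(st)))
    }
    out
  }
  prior_logdens <- function(st) {
    x <- st$theta[[id]]
    ld <- 0
    for (i in seq_along(segments)) {
      s <- segments[[i]]
      xi <- x[seg_idx[[i]]]
      ld <- ld + switch(s$kind,
        norm = sum(stats::dnorm(xi, s$mean_fn(st), s$sd_fn(st), log = TRUE)),
        mvn = chol_logdens(xi, s$mean_fn(st), chol(s$Sigma_fn(st))),
        rw2 = rw2_logdens(xi, s$P, s$Tn, s$sd_fn(st)))
    }
    ld
  }
  prior_sd <- if (all(vapply(segments, `[[`, "", "kind") == "norm")) {
    function(st) {
      out <- numeric(d)
      for (i in seq_along(segments)) out[seg_idx[[i]]] <- segments[[i]]$sd_fn(st)
      out
    }
  }
  list(id = id, pops = pops, dim = d, labels = labels, init = init,
       segments = segments,
       prior_mean = prior_mean, prior_draw = prior_draw,
       prior_logdens = prior_logdens, prior_sd = prior_sd)
}

rw2_draw <- function(P, Tn, sd) {
  out <- numeric(P * Tn)
  for (p in seq_len(P)) {
    x <- numeric(Tn)
    x[1] <- stats::rnorm(1, 0, 10)
    if (Tn >= 2) x[2] <- stats::rnorm(1, 0, 10)
    if (Tn >= 3) for (t in 3:Tn) x[t] <- stats::rnorm(1, 2 * x[t - 1] - x[t - 2], sd)
    out[(p - 1) * Tn + seq_len(Tn)] <- x
  }
  out
}

rw2_logdens <- function(x, P, Tn, sd) {
  ld <- 0
  for (p in seq_len(P)) {
    xi <- x[(p - 1) * Tn + seq_len(Tn)]
    ld <- ld + stats::dnorm(xi[1], 0, 10, log = TRUE)
    if (Tn >= 2) ld <- ld + stats::dnorm(xi[2], 0, 10, log = TRUE)
    if (Tn >= 3) ld <- ld + sum(stats::dnorm(xi[3:Tn],
      2 * xi[2:(Tn - 1)] - xi[1:(Tn - 2)], sd, log = TRUE))
  }
  ld
}

# resolve each scalar's dep declaration into a concrete block-id vector
mark_scalar_deps <- function(scalars, blocks) {
  block_ids <- vapply(blocks, `[[`, "", "id")
  lapply(scalars, function(s) {
    s$dep_blocks <- if (identical(s$dep, "all")) block_ids
                    else if (identical(s$dep, "none")) character()
                    else intersect(s$dep, block_ids)
    s
  })
}

# Hierarchical machinery for location parameters held inside coefficient
# blocks. Group and world means become 1-dimensional blocks whose priors
# chain up the hierarchy (so they can join the joint coefficient update and
# are refreshed by elliptical slice sampling against their children's
# priors); per-level scales remain slice-sampled scalars. Translation
# interweaves (moving a mean together with its children) are attached to the
# innermost-level mean blocks.
hierarchy_builder <- function(model, pops, groupings, priors, env) {
  add_scalar <- get("add_scalar", envir = env)
  add_mean_block <- function(id, parent_id, sd_fn, dep_children, shift = NULL) {
    segs <- list(list(kind = "norm", d = 1L,
                      mean_block = parent_id,
                      mean_fn = if (is.null(parent_id)) function(st) 0
                                else function(st) st$theta[[parent_id]],
                      sd_fn = sd_fn))
    b <- make_block(id, character(), labels = id, segments = segs, init = 0)
    b$prior_dep_blocks <- dep_children
    b$shift <- shift
    env$blocks[[length(env$blocks) + 1L]] <- b
    env$coef_fns[[id]] <- function(st, x) x
  }
  gcols <- if (!is.null(groupings)) setdiff(names(groupings), "population") else character()
  list(level_fns = function(par, levels = 1L, coord = NULL) {
    strat <- model$hierarchy[[par]]$strategy %||% "hierarchical"
    if (identical(strat, "prior") || levels < 1) {
      pr <- default_prior(priors, par, list(dist = "normal", mean = 0, sd = 10))
      return(list(segment_for = function(p)
        list(kind = "norm", d = 1L,
             mean_fn = function(st) pr$mean %||% 0,
             sd_fn = function(st) pr$sd %||% 10)))
    }
    L <- min(levels, length(gcols) + 1L)
    wid <- paste0("mu_w[", par, "]")
    sids <- paste0("s[", par, ",", seq_len(L), "]")
    dep_pop_blocks <- paste0("theta[", pops, "]")
    sd_of <- function(sid) { force(sid); function(st) exp(st$sc[[sid]]) }
    if (L == 1) {
      add_mean_block(wid, NULL, function(st) 10, dep_pop_blocks,
                     shift = if (!is.null(coord)) list(pops = pops, coord = coord))
      add_scalar(sids[1], log(1), function(x, st) halfnorm_jac(exp(x), 1) + x,
                 w = 0.7, dep = dep_pop_blocks,
                 hier_dev = if (!is.null(coord))
                   list(pops = pops, coord = coord,
                        parent = setNames(rep(wid, length(pops)), pops)))
      return(list(segment_for = function(p)
        list(kind = "norm", d = 1L, mean_block = wid,
             mean_fn = function(st) st$theta[[wid]],
             sd_fn = sd_of(sids[1]))))
    }
    # level l = 1 groups the populations; level L - 1 is grouped by the world
    lvl_units <- lapply(seq_len(L - 1), function(l)
      unique(as.character(groupings[[gcols[l]]])))
    gm_id <- function(l, g) paste0("mu[", par, ",", g, "]")
    parent_of <- function(l, g) {
      if (l >= L - 1) return(wid)
      pg <- unique(as.character(groupings[[gcols[l + 1]]][groupings[[gcols[l]]] == g]))
      gm_id(l + 1, pg[1])
    }
    children_of <- function(l, g) {
      if (l == 1) return(paste0("theta[", pops[
        as.character(groupings[[gcols[1]]][match(pops, groupings$population)]) == g], "]"))
      kids <- unique(as.character(groupings[[gcols[l - 1]]][groupings[[gcols[l]]] == g]))
      vapply(kids, function(k) gm_id(l - 1, k), "")
    }
    add_mean_block(wid, NULL, function(st) 10,
                   vapply(lvl_units[[L - 1]], function(g) gm_id(L - 1, g), ""))
    for (l in rev(seq_len(L - 1))) {
      for (g in lvl_units[[l]]) {
        gpops <- if (l == 1) pops[
          as.character(groupings[[gcols[1]]][match(pops, groupings$population)]) == g]
        add_mean_block(gm_id(l, g), parent_of(l, g), sd_of(sids[l + 1]),
                       children_of(l, g),
                       shift = if (l == 1 && !is.null(coord))
                         list(pops = gpops, coord = coord))
      }
    }
    pop_parent_ids <- setNames(
      paste0("mu[", par, ",",
             as.character(groupings[[gcols[1]]][match(pops, groupings$population)]), "]"),
      pops)
    # per-level scales: scale l governs level (l-1) units around their
    # level-l parents (l = 1: populations around their groups)
    add_scalar(sids[1], log(1), function(x, st) halfnorm_jac(exp(x), 1) + x,
               w = 0.7, dep = dep_pop_blocks,
               hier_dev = if (!is.null(coord))
                 list(pops = pops, coord = coord, parent = pop_parent_ids))
    for (l in 2:L) {
      units_below <- vapply(lvl_units[[l - 1]], function(g) gm_id(l - 1, g), "")
      add_scalar(sids[l], log(1),
                 local({ ub <- units_below; function(x, st)
                   halfnorm_jac(exp(x), 1) + x }),
                 w = 0.7, dep = units_below)
    }
    pop_parent <- setNames(
      paste0("mu[", par, ",",
             as.character(groupings[[gcols[1]]][match(pops, groupings$population)]), "]"),
      pops)
    list(segment_for = function(p) {
      pid <- pop_parent[[p]]
      list(kind = "norm", d = 1L, mean_block = pid,
           mean_fn = function(st) st$theta[[pid]],
           sd_fn = sd_of(sids[1]))
    })
  })
}
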