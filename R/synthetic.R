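#' Missingness pattern for synthetic data
#'
#' Describes which population-years are observed and by which sources. The
#' default scenario mirrors the sparse, irregular, multi-source data the
#' model class targets: a fraction of population-years observed, two source
#' types with a 1:3 sampling-sd ratio, and one population with no
#' observations at all.
#'
#' @param populations Character vector of population ids.
#' @param grid A [time_grid()].
#' @param prop_observed Fraction of population-years carrying at least one
#'   observation.
#' @param sources Named numeric vector of per-source sampling sds (on the
#'   data model's observation scale).
#' @param unobserved Population ids left entirely without data.
#' @param seed Integer seed (pattern stream).
#' @return A data frame `population, time, source, sampling_sd` of class
#'   `tmmp_pattern`.
#' @export
missingness_pattern <- function(populations, grid,
                                prop_observed = 0.4,
                                sources = c(survey = 0.03, vr = 0.01),
                                unobserved = character(),
                                seed = 1L) {
  rows <- list()
  for (p in setdiff(populations, unobserved)) {
    set.seed(substream_seed(seed, "pattern", p))
    nt <- max(1L, round(prop_observed * grid$T))
    times <- sort(sample(seq_len(grid$T), nt))
    src <- names(sources)[sample(length(sources), nt, replace = TRUE)]
    rows[[p]] <- data.frame(population = p, time = times, source = src,
                            sampling_sd = unname(sources[src]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(population = character(), time = integer(),
               source = character(), sampling_sd = numeric())
  structure(out, class = c("tmmp_pattern", "data.frame"))
}

#' Generate observations from a fully specified model
#'
#' Draws the latent field through the process model with all parameters fixed
#' at supplied truth values, then draws observations through the data model at
#' the pattern's population-times. The generator samples the smoothing
#' coefficients directly from their kernel prior (per-population substreams,
#' so results are invariant to population order) and never calls the
#' posterior-sampling code path, keeping recovery experiments non-circular.
#'
#' @param model A [tmmp_model()].
#' @param truth Named list of true parameter values; structure-dependent:
#'   `alpha0`, `alpha1` (named per population), `beta0`, `betas`,
#'   `sigma_delta` (single value or named per population), `Omega`,
#'   `P_tilde`, `omega` (logistic transition), `phi`, per-source `sd`.
#' @param pattern A [missingness_pattern()] (or compatible data frame).
#' @param grid A [time_grid()].
#' @param covariates,offsets As in [fit_tmmp()].
#' @param relative_sd Logical: interpret the pattern's `sampling_sd` as a
#'   coefficient of variation, so each record's sampling sd is
#'   `sampling_sd * eta` at its population-time (design-based sampling
#'   errors typically scale with the level of the indicator). The recorded
#'   `sampling_sd` column holds the resulting absolute sds.
#' @param seed Master seed; split into truth and noise streams.
#' @return List with `observations` (a `tmmp_observations` table) and
#'   `truth` (class `tmmp_truth`: the realized `eta`, `eps`, `delta`,
#'   parameter values and seed).
#' @export
generate_tmmp <- function(model, truth, pattern, grid, covariates = NULL,
                          offsets = NULL, relative_sd = FALSE, seed = 1L) {
  pops <- sort(unique(c(pattern$population, names(truth$alpha0),
                        names(truth$Omega), truth$populations)))
  if (!length(pops)) stop_tmmp("cannot determine populations from pattern/truth")
  if (any(pattern$time > grid$T)) stop_tmmp("pattern time off the estimation grid")
  C <- length(pops)
  T_star <- grid$T_star
  tr <- transform_spec(model$transform)
  sspec <- model_smoothing_spec(model)
  # smoothing over the estimation period, extended into the projection period
  # by the same conditional law projections use (extra knots, joint kernel
  # covariance over all differenced coefficients)
  mats <- smoothing_matrices(sspec, seq_len(grid$T))
  Bout <- mats$B
  K_added <- 0L
  if (T_star > grid$T) {
    Bout <- extend_basis(mats$B, times = seq_len(T_star), to_time = T_star)
    K_added <- attr(Bout, "K_added")
  }

  sig_of <- function(p) {
    s <- truth$sigma_delta %||% model$smoothing$kernel[[kernel_scale_name(model$smoothing$kernel$family)]]
    if (!is.null(names(s))) unname(s[p]) else s
  }
  eps <- delta <- list()
  for (p in pops) {
    over <- setNames(list(sig_of(p)), kernel_scale_name(model$smoothing$kernel$family))
    for (nm in intersect(names(truth), c("rho", "theta", "ell", "nu")))
      over[[nm]] <- truth[[nm]]
    S <- build_covariance(model_kernel(model, over), mats$m + K_added)
    set.seed(substream_seed(seed, "truth", p))
    gam <- drop(crossprod(chol(S), stats::rnorm(mats$m + K_added)))
    d0 <- drop(mats$A %*% gam[seq_len(mats$m)])
    delta[[p]] <- if (K_added > 0)
      extend_levels(d0, mats$r, gam[mats$m + seq_len(K_added)]) else d0
    eps[[p]] <- drop(Bout %*% delta[[p]])
  }

  # transformed-scale mean components
  t_star_cfg <- model$systematic$t_star
  t_star <- setNames(vapply(pops, function(p) {
    if (!is.null(t_star_cfg)) return(as.integer(t_star_cfg))
    tt <- pattern$time[pattern$population == p]
    if (length(tt)) as.integer(round(mean(range(tt)))) else as.integer(round((1 + grid$T) / 2))
  }, 0L), pops)

  eta <- matrix(NA_real_, C, T_star, dimnames = list(pops, NULL))
  cov_kind <- model$covariate$kind %||% "none"
  covm <- function(col, p) {
    rows <- covariates$population == p
    covariates[[col]][rows][order(covariates$time[rows])]
  }
  for (p in pops) {
    z <- rep(0, T_star)
    if (!is.null(offsets) && p %in% rownames(offsets)) z <- z + offsets[p, ]
    if (cov_kind == "linear") {
      X <- sapply(model$covariate$columns, covm, p = p)
      b0 <- if (!is.null(truth$beta0)) unname(truth$beta0[p]) else 0
      z <- z + covariate_linear(X, b0, as.numeric(truth$betas))
    } else if (cov_kind == "gbd_nonlinear") {
      z <- z + covariate_gbd(covm("LDI", p), covm("EDU", p), covm("HIV", p),
                             as.numeric(truth$betas))
    } else if (cov_kind == "piecewise_nmr") {
      U <- covm(model$covariate$columns %||% "U5MR", p)
      z <- z + covariate_piecewise_nmr(U, unname(truth$beta0[p]),
                                       truth$beta1, truth$beta2)
    } else if (cov_kind == "pca_linear") {
      X <- sapply(model$covariate$columns, covm, p = p)
      z <- z + covariate_pca(X, rbind(truth$beta_pc[[p]]))
    }
    sys_kind <- model$systematic$kind %||% "none"
    if (sys_kind == "linear_trend") {
      z <- z + systematic_linear(seq_len(T_star), unname(truth$alpha0[p]),
                                 unname(truth$alpha1[p]), t_star[[p]])
    } else if (sys_kind == "trapezoid") {
      q <- truth$trapezoid[[p]] %||% truth$trapezoid
      z <- z + systematic_trapezoid(seq_len(T_star), q$xi, q$gamma0,
                                    q$lambda1, q$lambda2, q$lambda3)
    }
    if (sys_kind == "logistic_transition") {
      eta[p, ] <- logistic_path(unname(truth$Omega[p]), unname(truth$P_tilde[p]),
                                unname(truth$omega[p]), t_star[[p]],
                                eps = eps[[p]] + z)
    } else {
      eta[p, ] <- transform_invert(z + eps[[p]], tr)
    }
  }

  # observations through the data model
  obs <- as.data.frame(pattern)
  obs$value <- NA_real_
  if (relative_sd && !is.null(obs$sampling_sd))
    obs$sampling_sd <- obs$sampling_sd *
      eta[cbind(match(obs$population, rownames(eta)), obs$time)]
  dmf <- model$data_model$family
  for (i in seq_len(nrow(obs))) {
    p <- obs$population[i]
    set.seed(substream_seed(seed, "noise", p, obs$time[i], obs$source[i], i))
    e <- eta[p, obs$time[i]]
    obs$value[i] <- switch(dmf,
      normal = stats::rnorm(1, e, obs$sampling_sd[i]),
      logit_normal = stats::plogis(stats::rnorm(1, stats::qlogis(e), obs$sampling_sd[i])),
      binomial = stats::rbinom(1, obs$denominator[i], e),
      negative_binomial = stats::rnbinom(1, size = truth$phi %||% model$data_model$phi,
                                         mu = obs$denominator[i] * e))
  }
  if (!"sampling_sd" %in% names(obs)) obs$sampling_sd <- NA_real_
  if (!"denominator" %in% names(obs)) obs$denominator <- NA_integer_
  obs <- obs[, c("population", "time", "value", "sampling_sd", "source", "denominator")]
  class(obs) <- c("tmmp_observations", "data.frame")
  list(observations = obs,
       truth = structure(list(model = model, params = truth, eta = eta,
                              eps = do.call(rbind, eps), delta = delta,
                              t_star = t_star, seed = seed),
                         class = "tmmp_truth"))
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates data from known truth, fits the model, and scores
#' recovery: per-parameter bias, RMSE and empirical coverage of the central
#' 95% posterior intervals, with Monte-Carlo standard errors. Fits whose
#' maximum split-Rhat exceeds 1.1 are counted and flagged, never silently
#' dropped.
#'
#' @param model A [tmmp_model()].
#' @param truth True parameter values (see [generate_tmmp()]).
#' @param pattern A [missingness_pattern()].
#' @param grid A [time_grid()].
#' @param n_sims Number of simulation replicates.
#' @param seed Master seed; replicate `i` uses an independent substream.
#' @param relative_sd Passed to [generate_tmmp()]: interpret the pattern's
#'   sampling sds as coefficients of variation.
#' @param parameters Named list mapping report groups to label-extraction
#'   regexes over the flat parameter names, with matching truth accessors;
#'   by default scores `alpha0`, `alpha1` and `sigma_delta` when present.
#' @param ... Passed to [fit_tmmp()] (e.g. reduced `draws`).
#' @return A list of class `tmmp_recovery`: `summary` (per-group bias, RMSE,
#'   coverage with MC SEs), `per_sim` details and `n_bad_rhat`.
#' @export
recovery_experiment <- function(model, truth, pattern, grid, n_sims = 5,
                                seed = 1L, parameters = NULL,
                                relative_sd = FALSE, ...) {
  if (n_sims < 1) stop_tmmp("n_sims must be >= 1")
  truth_flat <- flatten_truth(truth)
  if (is.null(parameters))
    parameters <- intersect(c("alpha0", "alpha1", "sigma_delta", "beta0"),
                            sub("\\[.*", "", names(truth_flat)))
  rows <- list()
  n_bad <- 0L
  for (i in seq_len(n_sims)) {
    sim <- generate_tmmp(model, truth, pattern, grid, relative_sd = relative_sd,
                         seed = substream_seed(seed, "sim", i))
    fit <- suppressWarnings(
      fit_tmmp(model, sim$observations, grid, seed = substream_seed(seed, "fit", i), ...))
    if (!is.null(fit$rhat_warning)) n_bad <- n_bad + 1L
    flat <- flatten_draws(fit)
    for (grp in parameters) {
      ids <- grep(paste0("^", grp, "\\["), colnames(flat), value = TRUE)
      if (identical(grp, "sigma_delta"))
        ids <- grep("^sigma_delta\\[", colnames(flat), value = TRUE)
      for (id in ids) {
        tv <- truth_flat[[id]]
        if (is.null(tv)) next
        dr <- flat[, id]
        q <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sim = i, group = grp, parameter = id, truth = tv,
          post_mean = mean(dr), post_sd = stats::sd(dr),
          covered = tv >= q[1] & tv <= q[2])
      }
    }
  }
  per_sim <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_sim, per_sim$group), function(d) {
    n <- nrow(d)
    data.frame(group = d$group[1], n = n,
               bias = mean(d$post_mean - d$truth),
               bias_over_sd = mean((d$post_mean - d$truth)) / mean(d$post_sd),
               rmse = sqrt(mean((d$post_mean - d$truth)^2)),
               coverage = mean(d$covered),
               coverage_se = sqrt(mean(d$covered) * (1 - mean(d$covered)) / n))
  }))
  structure(list(summary = agg, per_sim = per_sim, n_bad_rhat = n_bad,
                 n_sims = n_sims),
            class = "tmmp_recovery")
}

flatten_truth <- function(truth) {
  out <- list()
  for (nm in c("alpha0", "alpha1", "beta0")) {
    v <- truth[[nm]]
    if (!is.null(v) && !is.null(names(v)))
      for (p in names(v)) out[[paste0(nm, "[", p, "]")]] <- unname(v[p])
  }
  sdl <- truth$sigma_delta
  if (!is.null(sdl) && !is.null(names(sdl)))
    for (p in names(sdl)) out[[paste0("sigma_delta[", p, "]")]] <- unname(sdl[p])
  out
}

# flat (total draws) x parameter matrix, with sigma_delta derived from its
# log-scale scalars when the model estimates it hierarchically
flatten_draws <- function(fit) {
  pars <- fit$draws$pars
  d <- dim(pars)
  flat <- matrix(pars, d[1] * d[2], d[3], dimnames = list(NULL, dimnames(pars)[[3]]))
  lg <- grep("^log_sigma_delta\\[", colnames(flat), value = TRUE)
  if (length(lg)) {
    sd_cols <- exp(flat[, lg, drop = FALSE])
    colnames(sd_cols) <- sub("^log_", "", lg)
    flat <- cbind(flat, sd_cols)
  }
  flat
}

#' @export
print.tmmp_recovery <- function(x, ...) {
  cat(sprintf("<tmmp_recovery> %d simulations (%d flagged rhat > 1.05)\n",
              x$n_sims, x$n_bad_rhat))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
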